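# Deterministic child-seed derivation and scoped RNG use.
#
# Every stratum draws from its own child stream seeded by a hash of
# (root seed, state code, age group), so the order in which states are
# processed cannot change any record, and adding a state leaves the
# others' records untouched.

# 31-ary string hash folded into [0, 2^31 - 2]; exact in double arithmetic
# because 31 * 2^31 + 255 < 2^53
.child_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "\x1f")
  h <- abs(as.numeric(seed)) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# evaluate `code` under set.seed(seed), then restore the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# short hex content fingerprint for CLI logging (same 31-ary fold)
.fingerprint <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
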