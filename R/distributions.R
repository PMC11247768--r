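#' Normalise category weights to a probability distribution
#'
#' Published percentage tables do not always sum to exactly 100 (the cystic
#' fibrosis sex row sums to 101), so all categorical inputs are rescaled
#' proportionally. Zero-total or negative inputs are rejected rather than
#' silently fixed.
#'
#' @param weights Named numeric vector of non-negative weights (any scale:
#'   percentages, counts, probabilities).
#' @return Named numeric vector of probabilities summing to 1, same names and
#'   order as \code{weights}.
#' @examples
#' normalize_categorical(c(male = 50, female = 50))
#' normalize_categorical(c(male = 51.7, female = 49.3))  # sums to 101
#' @export
normalize_categorical <- function(weights) {
  if (length(weights) == 0 || is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be a non-empty named vector", call. = FALSE)
  }
  w <- as.numeric(weights)
  if (anyNA(w) || any(w < 0)) {
    stop("invalid distribution: negative or missing weights", call. = FALSE)
  }
  total <- sum(w)
  if (total <= 0) {
    stop("invalid distribution: all weights are zero", call. = FALSE)
  }
  stats::setNames(w / total, names(weights))
}

# validates a normalised categorical distribution
.check_categorical <- function(probs, what = "distribution") {
  stopifnot(is.numeric(probs), !is.null(names(probs)))
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("%s is not a valid probability distribution", what), call. = FALSE)
  }
  invisible(probs)
}

#' Draw from a normal distribution truncated to a range
#'
#' Clinical parameters and diagnosis offsets are specified as a range
#' \code{[lower, upper]} plus a centre \code{mean} and scale \code{sd}
#' (the published "mu +/- spread"). Values are drawn from
#' N(\code{mean}, \code{sd}^2) restricted to the range by inverse-CDF
#' sampling, so every draw lies within \code{[lower, upper]} and no
#' rejection loop is needed. A symmetric truncation (\code{mean} centred in
#' the range) preserves the mean. \code{sd = 0} degenerates to the constant
#' \code{mean} (clamped into the range).
#'
#' @param n Number of draws.
#' @param mean,sd Centre and scale of the parent normal; \code{sd >= 0}.
#' @param lower,upper Truncation bounds, \code{lower <= upper}.
#' @return Numeric vector of \code{n} draws in \code{[lower, upper]}.
#' @examples
#' set.seed(1)
#' x <- rnorm_trunc(1000, mean = 8.5, sd = 2.5, lower = 6, upper = 11)
#' range(x)
#' @export
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(n >= 0, sd >= 0, lower <= upper)
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lower), upper)  # guard against qnorm round-off at the tails
}

# categorical draw: n labels sampled with the given probabilities
.sample_categorical <- function(n, probs) {
  .check_categorical(probs)
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# mixture of a disease-level and a population-level categorical distribution;
# blend = 1 means pure disease distribution
.blend_dists <- function(profile_dist, state_dist, blend) {
  if (length(blend) != 1 || is.na(blend) || blend < 0 || blend > 1) {
    stop("`blend` must be a single value in [0, 1]", call. = FALSE)
  }
  labels <- names(profile_dist)
  if (!setequal(labels, names(state_dist))) {
    stop("profile and state distributions must share the same categories", call. = FALSE)
  }
  mix <- blend * profile_dist + (1 - blend) * state_dist[labels]
  stats::setNames(as.numeric(mix), labels)
}
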