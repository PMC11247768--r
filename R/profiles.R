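#' @title Disease statistics profiles
#' @description A disease profile bundles the published aggregate statistics
#'   that parameterise cohort generation for one rare disease: prevalence
#'   (stored as the denominator N of 1/N to avoid precision drift), race and
#'   sex distributions, the initial-diagnosis offset distribution,
#'   age-group death rates per 100,000, and one or more clinical-parameter
#'   distributions. Profiles are stored as JSON; three curated profiles ship
#'   with the package (sickle cell disease, cystic fibrosis, Duchenne
#'   muscular dystrophy).
#' @name disease_profile
NULL

.race_labels <- c("African-American", "European-American", "Others")
.sex_labels <- c("male", "female")
.offset_units <- c("days", "months", "years")
.days_per_unit <- c(days = 1, months = 30.44, years = 365.25)

.schema_stop <- function(field, msg) {
  stop(errorCondition(
    sprintf("profile schema error in field `%s`: %s", field, msg),
    class = c("rd_schema_error", "error", "condition")
  ))
}

# validate a {unit?, low, high, mu, spread} range-distribution spec
.check_range_dist <- function(d, field) {
  for (k in c("low", "high", "mu", "spread")) {
    if (is.null(d[[k]]) || !is.numeric(d[[k]]) || is.na(d[[k]])) {
      .schema_stop(paste0(field, "$", k), "missing or non-numeric")
    }
  }
  if (d$low > d$high) .schema_stop(field, "low > high")
  if (d$mu < d$low || d$mu > d$high) .schema_stop(field, "mu outside [low, high]")
  if (d$spread <= 0) .schema_stop(field, "spread must be > 0")
  invisible(d)
}

.check_percent_block <- function(x, expected_labels, field) {
  if (is.null(x)) .schema_stop(field, "missing")
  x <- unlist(x)
  if (!setequal(names(x), expected_labels)) {
    .schema_stop(field, sprintf(
      "categories must be exactly {%s}", paste(expected_labels, collapse = ", ")
    ))
  }
  if (any(x < 0) || all(x == 0)) .schema_stop(field, "weights must be non-negative, not all zero")
  x[expected_labels]
}

# normalise a percent block, recording a note when it deviates from 100 by > 0.5
.normalise_percent <- function(x, field) {
  total <- sum(x)
  note <- NULL
  if (abs(total - 100) > 0.5) {
    note <- sprintf(
      "%s percentages sum to %.2f, not 100; rescaled proportionally", field, total
    )
    warning(warningCondition(
      note, class = c("rd_normalisation_warning", "warning", "condition")
    ))
  }
  list(probs = normalize_categorical(x), note = note)
}

.new_disease_profile <- function(name, orpha_code, prevalence_denominator,
                                 race_dist, sex_dist, diagnosis, death_rates,
                                 clinical_params, notes = character(0)) {
  structure(
    list(
      name = name, orpha_code = orpha_code,
      prevalence_denominator = prevalence_denominator,
      race_dist = race_dist, sex_dist = sex_dist,
      diagnosis = diagnosis, death_rates = death_rates,
      clinical_params = clinical_params, notes = notes
    ),
    class = "disease_profile"
  )
}

#' Load a disease statistics profile from JSON
#'
#' Reads and fully validates a profile file. Percentage blocks (race, sex)
#' are given on the 0-100 scale as published and are normalised to
#' probabilities on load; if a block deviates from a 100% total by more than
#' 0.5 a warning of class \code{rd_normalisation_warning} is signalled and
#' the note is kept in the profile's \code{notes} field. Schema violations
#' (missing fields, unknown age-group labels, negative rates) raise an error
#' of class \code{rd_schema_error} naming the offending field.
#'
#' @param path Path to a profile JSON file. See the package vignette for the
#'   schema; the packaged profiles under
#'   \code{system.file("extdata", "profiles", package = "rdcohort")} are
#'   complete examples.
#' @return A \code{disease_profile} object.
#' @seealso [builtin_profiles()], [write_profile()]
#' @export
load_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)

  for (k in c("name", "orpha_code", "prevalence_denominator", "race_percent",
              "sex_percent", "diagnosis", "death_rate_per_100k", "clinical_params")) {
    if (is.null(raw[[k]])) .schema_stop(k, "missing")
  }
  den <- raw$prevalence_denominator
  if (!is.numeric(den) || length(den) != 1 || is.na(den) || den < 1 || den != round(den)) {
    .schema_stop("prevalence_denominator", "must be a positive integer")
  }

  notes <- character(0)
  race_w <- .check_percent_block(raw$race_percent, .race_labels, "race_percent")
  race <- .normalise_percent(race_w, "race_percent")
  sex_w <- .check_percent_block(raw$sex_percent, .sex_labels, "sex_percent")
  sex <- .normalise_percent(sex_w, "sex_percent")
  notes <- c(notes, race$note, sex$note)

  diag <- raw$diagnosis
  if (is.null(diag$unit) || !diag$unit %in% .offset_units) {
    .schema_stop("diagnosis$unit", sprintf(
      "must be one of {%s}", paste(.offset_units, collapse = ", ")
    ))
  }
  .check_range_dist(diag, "diagnosis")
  diagnosis <- list(unit = diag$unit, low = as.numeric(diag$low),
                    high = as.numeric(diag$high), mu = as.numeric(diag$mu),
                    spread = as.numeric(diag$spread))

  dr <- unlist(raw$death_rate_per_100k)
  labels <- .age_group_labels()
  if (!setequal(names(dr), labels)) {
    .schema_stop("death_rate_per_100k", sprintf(
      "keys must be exactly the 7 age groups {%s}", paste(labels, collapse = ", ")
    ))
  }
  dr <- dr[labels]
  if (any(is.na(dr)) || any(dr < 0) || any(dr > 1e5)) {
    .schema_stop("death_rate_per_100k", "rates must lie in [0, 100000]")
  }

  cp_raw <- raw$clinical_params
  if (is.data.frame(cp_raw)) cp_raw <- split(cp_raw, seq_len(nrow(cp_raw)))
  if (length(cp_raw) == 0) .schema_stop("clinical_params", "must list at least one parameter")
  clinical <- lapply(cp_raw, function(p) {
    p <- as.list(p)
    if (is.null(p$name) || !nzchar(p$name)) .schema_stop("clinical_params$name", "missing")
    .check_range_dist(p, paste0("clinical_params[", p$name, "]"))
    list(name = p$name, unit = if (is.null(p$unit)) "" else p$unit,
         low = as.numeric(p$low), high = as.numeric(p$high),
         mu = as.numeric(p$mu), spread = as.numeric(p$spread))
  })
  names(clinical) <- vapply(clinical, `[[`, "", "name")

  .new_disease_profile(
    name = raw$name, orpha_code = as.character(raw$orpha_code),
    prevalence_denominator = as.integer(den),
    race_dist = race$probs, sex_dist = sex$probs,
    diagnosis = diagnosis, death_rates = dr,
    clinical_params = clinical, notes = notes
  )
}

#' Write a disease profile back to JSON
#'
#' Inverse of [load_profile()]: probabilities are written back on the 0-100
#' percent scale, so \code{load_profile(write_profile(p, f))} reproduces
#' \code{p} (normalisation of an already-normalised profile is the identity).
#'
#' @param profile A \code{disease_profile}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "disease_profile"))
  out <- list(
    name = profile$name,
    orpha_code = profile$orpha_code,
    prevalence_denominator = profile$prevalence_denominator,
    race_percent = as.list(profile$race_dist * 100),
    sex_percent = as.list(profile$sex_dist * 100),
    diagnosis = profile$diagnosis,
    death_rate_per_100k = as.list(profile$death_rates),
    clinical_params = unname(profile$clinical_params)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The three packaged disease profiles
#'
#' Returns the curated statistics profiles shipped with the package:
#' sickle cell disease (\code{SCD}, ORPHA 232, prevalence 1/3300), cystic
#' fibrosis (\code{CF}, ORPHA 586, 1/10311) and Duchenne muscular dystrophy
#' (\code{DMD}, ORPHA 98896, 1/6000). The CF sex percentages are published
#' as 51.7/49.3 (sum 101) and are proportionally normalised on load; that
#' adjustment is recorded in the profile's \code{notes}.
#'
#' @return Named list \code{list(SCD = , CF = , DMD = )} of
#'   \code{disease_profile} objects.
#' @examples
#' profiles <- builtin_profiles()
#' profiles$SCD$race_dist
#' @export
builtin_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "rdcohort")
  load_quiet <- function(f) {
    withCallingHandlers(
      load_profile(file.path(dir, f)),
      rd_normalisation_warning = function(w) invokeRestart("muffleWarning")
    )
  }
  list(
    SCD = load_quiet("scd.json"),
    CF = load_quiet("cf.json"),
    DMD = load_quiet("dmd.json")
  )
}

#' @export
print.disease_profile <- function(x, ...) {
  cat("Disease statistics profile:", x$name,
      sprintf("(ORPHA %s)\n", x$orpha_code))
  cat(sprintf("  prevalence: 1/%d\n", x$prevalence_denominator))
  cat("  race:", paste(sprintf("%s %.2f%%", names(x$race_dist), 100 * x$race_dist),
                       collapse = ", "), "\n")
  cat("  sex: ", paste(sprintf("%s %.2f%%", names(x$sex_dist), 100 * x$sex_dist),
                       collapse = ", "), "\n")
  d <- x$diagnosis
  cat(sprintf("  initial diagnosis: %g-%g %s after birth (mu %g, spread %g)\n",
              d$low, d$high, d$unit, d$mu, d$spread))
  cat("  death rate per 100,000 by age group:\n")
  print(x$death_rates)
  cat("  clinical parameters:\n")
  for (p in x$clinical_params) {
    cat(sprintf("    %s: %g-%g %s (mu %g, spread %g)\n",
                p$name, p$low, p$high, p$unit, p$mu, p$spread))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
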