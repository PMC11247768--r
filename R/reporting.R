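#' Write a cohort to CSV
#'
#' Columns are fixed: \code{patient_id, state, zip, sex, race, age_years,
#' date_of_birth, date_of_diagnosis, vital_status, date_of_death},
#' \code{diagnosis_clamped}, then one column per clinical parameter. Dates
#' are ISO 8601; a living patient's \code{date_of_death} is the empty
#' string. The round trip through [read_cohort()] is lossless.
#'
#' @param cohort An \code{rd_cohort} or a compatible records data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rec <- if (inherits(cohort, "rd_cohort")) cohort$records else cohort
  out <- rec
  for (col in c("date_of_birth", "date_of_diagnosis", "date_of_death")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], "%Y-%m-%d"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort records file
#'
#' Parses a CSV written by [write_cohort()] back into a typed records data
#' frame. Malformed rows (bad dates, unknown vital status, inconsistent
#' death dates) raise a parse error naming the first offending data row.
#'
#' @param path CSV path.
#' @return Records data frame with \code{Date}-typed date columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(zip = "character"))
  required <- c("patient_id", "state", "zip", "sex", "race", "age_years",
                "date_of_birth", "date_of_diagnosis", "vital_status",
                "date_of_death")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols)) {
    stop("parse error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop(sprintf("parse error in %s at data row %d: %s",
                   basename(path), which(!ok)[1], what), call. = FALSE)
    }
  }
  for (col in c("date_of_birth", "date_of_diagnosis", "date_of_death")) {
    raw <- as.character(rec[[col]])
    empty <- is.na(raw) | raw == ""
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    if (col == "date_of_death") {
      bad_row(empty | !is.na(parsed), paste("unparseable", col))
    } else {
      bad_row(!empty & !is.na(parsed), paste("missing or unparseable", col))
    }
    rec[[col]] <- parsed
  }
  bad_row(rec$vital_status %in% c("alive", "deceased"), "unknown vital_status")
  bad_row((rec$vital_status == "deceased") == !is.na(rec$date_of_death),
          "vital_status inconsistent with date_of_death")
  rec$diagnosis_clamped <- as.logical(rec$diagnosis_clamped)
  rec
}

#' Summarise a cohort against its sampling frame
#'
#' Computes the validation marginals of a generated dataset: total, male,
#' female and deceased counts, race percentages, female percentage, and a
#' per-age-group breakdown (stratum population from the demographics table,
#' observed patients and deceased). Counts are exact integers; percentages
#' are stored at full precision and only rounded for display.
#'
#' @param object An \code{rd_cohort}.
#' @param table The \code{demographics_table} the cohort was generated on.
#' @param ... Unused.
#' @return An \code{rd_cohort_summary} object.
#' @export
summary.rd_cohort <- function(object, table = NULL, ...) {
  rec <- object$records
  n <- nrow(rec)
  n_male <- sum(rec$sex == "male")
  n_dec <- sum(rec$vital_status == "deceased")
  race_pct <- if (n > 0) {
    100 * vapply(.race_labels, function(r) mean(rec$race == r), numeric(1))
  } else {
    stats::setNames(rep(NA_real_, 3), .race_labels)
  }
  grp <- factor(age_to_group(rec$age_years), levels = .age_group_labels())
  by_grp <- data.frame(
    age_group = .age_group_labels(),
    population = NA_real_,
    patients = tabulate(grp, nbins = 7),
    deceased = tabulate(grp[rec$vital_status == "deceased"], nbins = 7),
    stringsAsFactors = FALSE
  )
  if (!is.null(table)) {
    st <- strata(table)
    pop <- tapply(st$population, factor(st$age_group, levels = .age_group_labels()), sum)
    by_grp$population <- as.numeric(pop)
  }
  structure(
    list(disease = object$disease, n_total = n, n_male = n_male,
         n_female = n - n_male, n_deceased = n_dec,
         race_percent = race_pct,
         female_percent = if (n > 0) 100 * (n - n_male) / n else NA_real_,
         by_age_group = by_grp),
    class = "rd_cohort_summary"
  )
}

#' @export
print.rd_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %s\n", x$disease))
  cat(sprintf("  patients: %s (male %s, female %s), deceased %s\n",
              format(x$n_total, big.mark = ","), format(x$n_male, big.mark = ","),
              format(x$n_female, big.mark = ","), format(x$n_deceased, big.mark = ",")))
  cat(sprintf("  female: %.2f%%\n", x$female_percent))
  for (r in names(x$race_percent)) {
    cat(sprintf("  %s: %.2f%%\n", r, x$race_percent[[r]]))
  }
  cat("  by age group:\n")
  print(transform(x$by_age_group,
                  population = ifelse(is.na(population), NA,
                                      format(population, big.mark = ","))),
        row.names = FALSE)
  invisible(x)
}

#' Per-age-group breakdown of a cohort
#'
#' @param cohort An \code{rd_cohort}.
#' @param table The \code{demographics_table} used for generation.
#' @return Data frame with columns \code{age_group}, \code{population},
#'   \code{patients}, \code{deceased} (one row per harmonised group).
#' @export
age_group_breakdown <- function(cohort, table) {
  summary(cohort, table)$by_age_group
}

#' Compare observed cohort statistics with their expected values
#'
#' Builds the expected-versus-observed validation table: total patient
#' count (expected = sum over strata of round(population / prevalence
#' denominator)), female percentage, each race percentage, and the deceased
#' count (expected from the profile's death rates applied to the observed
#' group sizes). Default tolerances are 3 binomial standard errors at the
#' cohort's size, so a correctly parameterised generator passes with
#' probability ~99.7% per row while a distribution shifted by more than
#' sampling noise fails.
#'
#' @param report An \code{rd_cohort_summary}.
#' @param profile The generating \code{disease_profile} (must be the same
#'   disease as the report).
#' @param table The \code{demographics_table} used for generation.
#' @param tolerance_multiplier Number of binomial standard errors allowed
#'   (default 3).
#' @return Data frame of class \code{rd_comparison} with columns
#'   \code{metric}, \code{result}, \code{expected}, \code{abs_diff},
#'   \code{tolerance}, \code{pass}.
#' @export
compare_to_expected <- function(report, profile, table,
                                tolerance_multiplier = 3) {
  stopifnot(inherits(report, "rd_cohort_summary"),
            inherits(profile, "disease_profile"))
  if (!identical(report$disease, profile$name)) {
    stop("report and profile refer to different diseases", call. = FALSE)
  }
  n <- report$n_total
  den <- profile$prevalence_denominator
  st <- strata(table)

  rows <- list()
  add <- function(metric, result, expected, tolerance) {
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, result = result, expected = expected,
      abs_diff = abs(result - expected), tolerance = tolerance,
      pass = abs(result - expected) <= tolerance, stringsAsFactors = FALSE
    )
  }

  exp_total <- sum(round(st$population / den))
  p <- 1 / den
  add("total_patients", n, exp_total,
      tolerance_multiplier * sqrt(sum(st$population) * p * (1 - p)))

  pct_tol <- function(p_exp) {
    if (n == 0) return(Inf)
    tolerance_multiplier * 100 * sqrt(p_exp * (1 - p_exp) / n)
  }
  p_f <- profile$sex_dist[["female"]]
  add("female_percent", report$female_percent, 100 * p_f, pct_tol(p_f))
  for (r in .race_labels) {
    p_r <- profile$race_dist[[r]]
    add(paste0("race_percent_", r), report$race_percent[[r]], 100 * p_r, pct_tol(p_r))
  }

  grp <- report$by_age_group
  p_dec <- profile$death_rates[grp$age_group] / 1e5
  exp_dec <- sum(grp$patients * p_dec)
  add("deceased_patients", report$n_deceased, exp_dec,
      max(tolerance_multiplier * sqrt(sum(grp$patients * p_dec * (1 - p_dec))), 1))

  out <- do.call(rbind, rows)
  class(out) <- c("rd_comparison", class(out))
  out
}

#' @export
print.rd_comparison <- function(x, digits = 2, ...) {
  cat("Expected vs observed validation\n")
  shown <- x
  for (col in c("result", "expected", "abs_diff", "tolerance")) {
    shown[[col]] <- round(shown[[col]], digits)
  }
  print.data.frame(shown, row.names = FALSE)
  status <- if (all(x$pass)) "all checks pass" else
    sprintf("%d check(s) FAIL", sum(!x$pass))
  cat(status, "\n")
  invisible(x)
}
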