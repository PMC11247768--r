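#' Settings controlling a generation run
#'
#' @param seed Integer root seed; every stratum derives its own child stream
#'   from (seed, state, age group), so results do not depend on processing
#'   order.
#' @param reference_date Date at which living patients' ages are evaluated
#'   (default 2023-01-01).
#' @param count_mode How many patients each stratum contributes:
#'   \code{"binomial"} (default) draws Binomial(population, 1/denominator),
#'   so totals fluctuate around the expectation as in a real prevalence
#'   sample; \code{"rounded-expectation"} reproduces the expectation
#'   deterministically via running-remainder rounding across strata.
#' @param race_blend,sex_blend Mixture weight in \verb{[0,1]} on the disease
#'   distribution when drawing race/sex; the remainder falls on the state's
#'   census split. Default 1 (pure disease distribution).
#' @return A \code{generation_settings} list.
#' @export
generation_settings <- function(seed = 1L,
                                reference_date = as.Date("2023-01-01"),
                                count_mode = c("binomial", "rounded-expectation"),
                                race_blend = 1.0, sex_blend = 1.0) {
  count_mode <- match.arg(count_mode)
  if (race_blend < 0 || race_blend > 1 || sex_blend < 0 || sex_blend > 1) {
    stop("blend weights must lie in [0, 1]", call. = FALSE)
  }
  reference_date <- as.Date(reference_date)
  if (is.na(reference_date)) stop("invalid reference_date", call. = FALSE)
  structure(
    list(seed = as.integer(seed), reference_date = reference_date,
         count_mode = count_mode, race_blend = race_blend,
         sex_blend = sex_blend),
    class = "generation_settings"
  )
}

#' Number of patients contributed by one population stratum
#'
#' In \code{"binomial"} mode the count is a draw from
#' Binomial(\code{population}, 1/\code{prevalence_denominator}); in
#' \code{"rounded-expectation"} mode it is
#' \code{round(population / prevalence_denominator)}.
#'
#' @param population Stratum population (>= 0).
#' @param prevalence_denominator N of the 1/N disease prevalence.
#' @param mode \code{"binomial"} or \code{"rounded-expectation"}.
#' @return A single non-negative integer count.
#' @examples
#' draw_stratum_count(19392551, 10311, "rounded-expectation")  # 1881
#' @export
draw_stratum_count <- function(population, prevalence_denominator,
                               mode = c("binomial", "rounded-expectation")) {
  mode <- match.arg(mode)
  stopifnot(population >= 0, prevalence_denominator >= 1)
  if (mode == "binomial") {
    stats::rbinom(1, size = population, prob = 1 / prevalence_denominator)
  } else {
    as.integer(round(population / prevalence_denominator))
  }
}

#' Draw patient sex and race from a disease/census mixture
#'
#' Sex and race are drawn from the mixture
#' \code{blend * disease distribution + (1 - blend) * state census split}.
#' With \code{blend = 1} (the default generation setting) the draw follows
#' the disease distribution exactly, which is what makes national cohort
#' marginals converge to the published disease statistics.
#'
#' @param profile_dist Named probability vector from the disease profile.
#' @param state_dist Named probability vector from the state's census split
#'   (same categories).
#' @param blend Mixture weight in \verb{[0,1]} on the disease distribution.
#' @param n Number of draws.
#' @return Character vector of \code{n} category labels.
#' @export
sample_sex <- function(profile_dist, state_dist, blend = 1, n = 1) {
  .sample_categorical(n, .blend_dists(profile_dist, state_dist, blend))
}

#' @rdname sample_sex
#' @export
sample_race <- function(profile_dist, state_dist, blend = 1, n = 1) {
  .sample_categorical(n, .blend_dists(profile_dist, state_dist, blend))
}

#' Draw single-year ages within an age group
#'
#' Within a (state, age group) stratum, ages are drawn proportionally to the
#' state's single-year population counts for that group. The census "85+"
#' aggregate belongs to the \verb{>60} group; when it is drawn, a concrete
#' age is sampled uniformly from 85-99.
#'
#' @param group_label One of the 7 age-group labels.
#' @param pop_by_age The state's named population vector
#'   (\code{"0"}..\code{"84"}, \code{"85+"}).
#' @param n Number of draws.
#' @return Integer vector of \code{n} ages.
#' @export
sample_age <- function(group_label, pop_by_age, n = 1) {
  g <- age_groups()
  row <- match(group_label, g$label)
  if (is.na(row)) stop("unknown age group: ", group_label, call. = FALSE)
  lo <- g$lower[row]
  hi <- min(g$upper[row], 84)
  ages <- lo:hi
  keys <- as.character(ages)
  weights <- pop_by_age[keys]
  has_85 <- is.infinite(g$upper[row])
  if (has_85) {
    ages <- c(ages, 85L)
    weights <- c(weights, pop_by_age[["85+"]])
  }
  if (sum(weights) <= 0) {
    stop("age group ", group_label, " has no population in this state", call. = FALSE)
  }
  out <- ages[sample.int(length(ages), n, replace = TRUE, prob = weights)]
  if (has_85) {
    top <- out == 85L
    out[top] <- 85L + sample.int(15, sum(top), replace = TRUE) - 1L
  }
  as.integer(out)
}

#' Draw clinical parameter values
#'
#' Values come from a normal distribution with the published centre and
#' scale, truncated to the published plausible range (see [rnorm_trunc()]).
#'
#' @param spec One element of a profile's \code{clinical_params}: a list
#'   with \code{low}, \code{high}, \code{mu}, \code{spread}.
#' @param n Number of draws.
#' @return Numeric vector of \code{n} values in \code{[spec$low, spec$high]}.
#' @examples
#' scd <- builtin_profiles()$SCD
#' set.seed(1)
#' mean(sample_clinical(scd$clinical_params$complete_blood_count, n = 1000))
#' @export
sample_clinical <- function(spec, n = 1) {
  rnorm_trunc(n, mean = spec$mu, sd = spec$spread,
              lower = spec$low, upper = spec$high)
}

#' Draw raw diagnosis offsets after birth
#'
#' Offsets are drawn from the profile's truncated-normal diagnosis
#' distribution in its native unit (days, months or years), before any
#' conversion to calendar days or clamping to the reference date.
#'
#' @param spec A profile's \code{diagnosis} element.
#' @param n Number of draws.
#' @return Numeric vector of offsets in \code{spec$unit}.
#' @export
sample_diagnosis_offset <- function(spec, n = 1) {
  rnorm_trunc(n, mean = spec$mu, sd = spec$spread,
              lower = spec$low, upper = spec$high)
}

#' Assign vital status from an age-group death rate
#'
#' A patient in a group with death rate r per 100,000 is deceased with
#' probability r/100000 (per-patient Bernoulli reading of the published
#' mortality statistic).
#'
#' @param group_label Age-group label.
#' @param death_rates Named rate vector (per 100,000) from the profile.
#' @param n Number of draws.
#' @return Character vector of \code{"alive"} / \code{"deceased"}.
#' @export
assign_vital_status <- function(group_label, death_rates, n = 1) {
  rate <- unname(death_rates[group_label])
  if (length(rate) != 1 || is.na(rate)) {
    stop("no death rate defined for group ", group_label, call. = FALSE)
  }
  ifelse(stats::runif(n) < rate / 1e5, "deceased", "alive")
}

#' Compute diagnosis dates from birth dates
#'
#' The offset is drawn from the profile's diagnosis distribution, converted
#' to days (1 month = 30.44 days, 1 year = 365.25 days) and added to the
#' birth date; the result is clamped so it never exceeds the reference date
#' (nor the death date, when one is supplied). Clamped records are flagged.
#'
#' @param date_of_birth \code{Date} vector.
#' @param spec A profile's \code{diagnosis} element.
#' @param reference_date Latest admissible diagnosis date.
#' @param date_of_death Optional \code{Date} vector (NA where alive); when
#'   present, diagnosis is additionally clamped to it.
#' @return Data frame with columns \code{date_of_diagnosis} (\code{Date})
#'   and \code{clamped} (logical).
#' @export
diagnosis_date_for <- function(date_of_birth, spec,
                               reference_date = as.Date("2023-01-01"),
                               date_of_death = NULL) {
  n <- length(date_of_birth)
  offset_days <- round(sample_diagnosis_offset(spec, n) * .days_per_unit[[spec$unit]])
  raw <- as.Date(date_of_birth) + offset_days
  limit <- rep(as.Date(reference_date), n)
  if (!is.null(date_of_death)) {
    dd <- as.Date(date_of_death)
    limit[!is.na(dd)] <- pmin(limit[!is.na(dd)], dd[!is.na(dd)])
  }
  clamped <- raw > limit
  data.frame(date_of_diagnosis = pmin(raw, limit), clamped = clamped)
}

# records for one (state, age-group) stratum under its own child RNG stream
.generate_stratum <- function(profile, state, group_label, population, settings) {
  .with_seed(.child_seed(settings$seed, state$state_code, group_label), {
    n <- if (settings$count_mode == "binomial") {
      draw_stratum_count(population, profile$prevalence_denominator, "binomial")
    } else {
      attr(population, "n_override") %||% 0L  # filled in by caller for rounded mode
    }
    if (n == 0) return(NULL)

    zip <- zip_for_state(state, n)
    sex <- sample_sex(profile$sex_dist, state$sex_dist, settings$sex_blend, n)
    age <- sample_age(group_label, state$pop_by_age, n)
    race <- sample_race(profile$race_dist, state$race_dist, settings$race_blend, n)
    clinical <- lapply(profile$clinical_params, sample_clinical, n = n)
    vital <- assign_vital_status(group_label, profile$death_rates, n)

    dob <- birth_date_for(age, settings$reference_date)
    dod <- as.Date(rep(NA_character_, n))
    dead <- vital == "deceased"
    if (any(dead)) {
      dod[dead] <- death_date_for(dob[dead], age[dead], settings$reference_date)
    }
    dx <- diagnosis_date_for(dob, profile$diagnosis, settings$reference_date, dod)

    rec <- data.frame(
      state = state$state_code, zip = zip, sex = sex, race = race,
      age_years = age, date_of_birth = dob,
      date_of_diagnosis = dx$date_of_diagnosis,
      vital_status = vital, date_of_death = dod,
      diagnosis_clamped = dx$clamped,
      stringsAsFactors = FALSE
    )
    for (nm in names(clinical)) rec[[nm]] <- clinical[[nm]]
    rec
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic patient cohort
#'
#' Hierarchical record-by-record generation: for every (state, age group)
#' stratum a patient count is drawn from the disease prevalence, then each
#' record is filled in top-down — ZIP code within the state, sex, a
#' single-year age within the group, race, clinical parameter values, vital
#' status from the group's death rate, and finally consistent birth,
#' diagnosis and (for deceased patients) death dates. Identical inputs and
#' seed yield a bit-identical cohort.
#'
#' @param profile A \code{disease_profile}.
#' @param table A \code{demographics_table}.
#' @param settings A [generation_settings()] object.
#' @return An \code{rd_cohort} object: a list with \code{records} (data
#'   frame, one row per patient), \code{disease}, \code{profile} and
#'   \code{settings}. Deceased patients' \code{age_years} is their age at
#'   death.
#' @examples
#' tab <- make_toy_demographics(1, 200000, seed = 7)
#' coh <- generate_cohort(builtin_profiles()$SCD, tab, generation_settings(seed = 1))
#' coh
#' @export
generate_cohort <- function(profile, table, settings = generation_settings()) {
  stopifnot(inherits(profile, "disease_profile"),
            inherits(table, "demographics_table"),
            inherits(settings, "generation_settings"))
  st <- strata(table)

  if (settings$count_mode == "rounded-expectation") {
    # running-remainder rounding: per-stratum counts track round(pop/N) while
    # the cohort total conserves round(total population / N) exactly
    counts <- .cascade_round(st$population / profile$prevalence_denominator)
  }

  chunks <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    pop <- st$population[i]
    if (settings$count_mode == "rounded-expectation") {
      attr(pop, "n_override") <- counts[i]
    }
    chunks[[i]] <- .generate_stratum(
      profile, table$states[[st$state_code[i]]], st$age_group[i], pop, settings
    )
  }
  records <- do.call(rbind, chunks)
  if (is.null(records)) records <- .empty_records(profile)
  disease_code <- .disease_code(profile)
  records <- cbind(
    patient_id = sprintf("%s-%07d", disease_code, seq_len(nrow(records))),
    records, stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  structure(
    list(records = records, disease = profile$name,
         profile = profile, settings = settings),
    class = "rd_cohort"
  )
}

# short disease code for patient ids (initials of the profile name)
.disease_code <- function(profile) {
  words <- strsplit(profile$name, "[^A-Za-z]+")[[1]]
  toupper(paste(substr(words, 1, 1), collapse = ""))
}

.empty_records <- function(profile) {
  rec <- data.frame(
    state = character(0), zip = character(0), sex = character(0),
    race = character(0), age_years = integer(0),
    date_of_birth = as.Date(character(0)),
    date_of_diagnosis = as.Date(character(0)),
    vital_status = character(0), date_of_death = as.Date(character(0)),
    diagnosis_clamped = logical(0), stringsAsFactors = FALSE
  )
  for (nm in names(profile$clinical_params)) rec[[nm]] <- numeric(0)
  rec
}

#' @export
print.rd_cohort <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("Synthetic cohort: %s, %s patient record(s)\n",
              x$disease, format(n, big.mark = ",")))
  cat(sprintf("  seed %d, reference date %s, counts: %s, race/sex blend %.2f/%.2f\n",
              x$settings$seed, format(x$settings$reference_date),
              x$settings$count_mode, x$settings$race_blend, x$settings$sex_blend))
  if (n > 0) {
    cat(sprintf("  deceased: %s (%.2f%%)\n",
                format(sum(x$records$vital_status == "deceased"), big.mark = ","),
                100 * mean(x$records$vital_status == "deceased")))
  }
  invisible(x)
}

#' @export
as.data.frame.rd_cohort <- function(x, ...) x$records
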