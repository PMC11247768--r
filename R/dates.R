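# Calendar arithmetic for birth, diagnosis and death dates.
#
# Age is the "floor" age: completed years between birth and a given date.
# Feb-29 birthdays count their anniversary on Mar 1 in non-leap years.

# completed years between birth and `at` (both Date, vectorised)
.floor_age <- function(birth, at) {
  yb <- as.integer(format(birth, "%Y"))
  ya <- as.integer(format(at, "%Y"))
  ya - yb - (format(at, "%m%d") < format(birth, "%m%d"))
}

# the date k years after d with the same month-day (Feb 29 -> Mar 1)
.shift_years <- function(d, k) {
  y <- as.integer(format(d, "%Y")) + k
  md <- format(d, "-%m-%d")
  md[md == "-02-29"] <- "-03-01"
  as.Date(paste0(y, md))
}

# uniform draw of one integer offset in [0, width-1] per element
.runif_int <- function(width) {
  as.integer(floor(stats::runif(length(width)) * width))
}

#' Draw a birth date consistent with an age at a reference date
#'
#' Returns dates uniform over the window of all birth dates for which the
#' completed-years age at \code{reference_date} equals \code{age_years}:
#' the ~365-day interval ending on the age-th anniversary before the
#' reference date.
#'
#' @param age_years Vector of non-negative integer ages.
#' @param reference_date The date at which the age holds (a \code{Date}).
#' @return \code{Date} vector, one birth date per element of
#'   \code{age_years}.
#' @examples
#' set.seed(1)
#' birth_date_for(c(0, 10), as.Date("2023-01-01"))
#' @export
birth_date_for <- function(age_years, reference_date = as.Date("2023-01-01")) {
  if (length(age_years) == 0) return(as.Date(character(0)))
  stopifnot(all(age_years >= 0))
  reference_date <- as.Date(reference_date)
  hi <- .shift_years(rep(reference_date, length(age_years)), -age_years)
  lo <- .shift_years(rep(reference_date, length(age_years)), -(age_years + 1L)) + 1L
  lo + .runif_int(as.integer(hi - lo) + 1L)
}

#' Draw a death date consistent with an age at death
#'
#' Returns dates uniform over the days on which the patient's completed-years
#' age equals \code{age_at_death}, intersected with days not after
#' \code{reference_date}. An empty window (the patient could not have reached
#' that age by the reference date) is an error.
#'
#' @param date_of_birth \code{Date} vector of birth dates.
#' @param age_at_death Non-negative integer age(s) at death.
#' @param reference_date Latest admissible death date.
#' @return \code{Date} vector of death dates.
#' @export
death_date_for <- function(date_of_birth, age_at_death,
                           reference_date = as.Date("2023-01-01")) {
  if (length(date_of_birth) == 0) return(as.Date(character(0)))
  stopifnot(all(age_at_death >= 0))
  date_of_birth <- as.Date(date_of_birth)
  reference_date <- as.Date(reference_date)
  n <- max(length(date_of_birth), length(age_at_death))
  dob <- rep_len(date_of_birth, n)
  a <- rep_len(as.integer(age_at_death), n)
  lo <- .shift_years(dob, a)
  hi <- pmin(.shift_years(dob, a + 1L) - 1L, reference_date)
  if (any(hi < lo)) {
    stop("no admissible death date: age at death not reachable by the reference date",
         call. = FALSE)
  }
  lo + .runif_int(as.integer(hi - lo) + 1L)
}
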