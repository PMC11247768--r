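#' @title Population sampling frame
#' @description The generator draws patients from a state-by-age population
#'   frame: for every state a population count per single year of age 0-84
#'   plus an aggregated "85+" cell, a list of ZIP codes, and state-level sex
#'   and race splits. A frame can be loaded from a JSON file (for users who
#'   have real census extracts) or synthesised with
#'   [make_toy_demographics()], so the package never needs network access.
#' @name demographics
NULL

.pop_age_keys <- c(as.character(0:84), "85+")

.demo_stop <- function(msg) {
  stop(errorCondition(
    paste0("demographics schema error: ", msg),
    class = c("rd_schema_error", "error", "condition")
  ))
}

.check_state <- function(s) {
  s$state_code <- unlist(s$state_code)
  if (is.null(s$state_code) || nchar(s$state_code) != 2) .demo_stop("state_code must be 2 letters")
  code <- s$state_code
  s$zip_codes <- as.character(unlist(s$zip_codes))
  if (length(s$zip_codes) == 0) .demo_stop(paste0(code, ": empty zip_codes"))
  if (anyDuplicated(s$zip_codes)) .demo_stop(paste0(code, ": duplicate ZIP codes"))
  if (any(!grepl("^[0-9]{5}$", s$zip_codes))) .demo_stop(paste0(code, ": ZIPs must be 5 digits"))
  pop <- unlist(s$pop_by_age)
  if (!setequal(names(pop), .pop_age_keys)) {
    .demo_stop(paste0(code, ": pop_by_age must cover ages 0..84 and \"85+\""))
  }
  pop <- pop[.pop_age_keys]
  if (any(is.na(pop)) || any(pop < 0)) .demo_stop(paste0(code, ": negative population count"))
  if (sum(pop) <= 0) .demo_stop(paste0(code, ": total population must be > 0"))
  list(
    state_code = code,
    zip_codes = as.character(s$zip_codes),
    pop_by_age = stats::setNames(as.numeric(pop), .pop_age_keys),
    sex_dist = .check_categorical(
      normalize_categorical(.check_percent_block(s$sex_percent, .sex_labels,
                                                 paste0(code, "$sex_percent"))),
      paste0(code, " sex split")),
    race_dist = .check_categorical(
      normalize_categorical(.check_percent_block(s$race_percent, .race_labels,
                                                 paste0(code, "$race_percent"))),
      paste0(code, " race split"))
  )
}

.new_demographics <- function(states, reference_year) {
  codes <- vapply(states, `[[`, "", "state_code")
  if (anyDuplicated(codes)) .demo_stop("duplicate state codes")
  structure(
    list(states = stats::setNames(states, codes),
         reference_year = as.integer(reference_year)),
    class = "demographics_table"
  )
}

#' Load a demographics table from JSON
#'
#' The file holds one object with \code{reference_year} and a \code{states}
#' array; each state carries \code{state_code}, \code{zip_codes},
#' \code{pop_by_age} (keys \code{"0"}..\code{"84"} and \code{"85+"}) and
#' percent blocks \code{sex_percent} / \code{race_percent}. All invariants
#' (unique state codes and ZIPs, non-negative counts, positive totals) are
#' validated; violations raise an \code{rd_schema_error}.
#'
#' @param path Path to a demographics JSON file.
#' @return A \code{demographics_table} object.
#' @seealso [make_toy_demographics()], [write_demographics()]
#' @export
load_demographics <- function(path) {
  if (!file.exists(path)) stop("demographics file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$states)) .demo_stop("missing `states`")
  states_raw <- raw$states
  if (is.data.frame(states_raw)) states_raw <- split(states_raw, seq_len(nrow(states_raw)))
  states <- lapply(states_raw, function(s) .check_state(as.list(s)))
  year <- if (is.null(raw$reference_year)) 2020L else raw$reference_year
  .new_demographics(states, year)
}

#' Write a demographics table to JSON
#'
#' @param table A \code{demographics_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_demographics <- function(table, path) {
  stopifnot(inherits(table, "demographics_table"))
  out <- list(
    reference_year = table$reference_year,
    states = lapply(unname(table$states), function(s) {
      list(state_code = s$state_code,
           zip_codes = s$zip_codes,
           pop_by_age = as.list(s$pop_by_age),
           sex_percent = as.list(s$sex_dist * 100),
           race_percent = as.list(s$race_dist * 100))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# round a vector of non-negative expectations to integers whose sum is
# round(sum(x)): cascade / running-remainder rounding
.cascade_round <- function(x) {
  cs <- round(cumsum(x))
  as.integer(cs - c(0, cs[-length(cs)]))
}

# national age-group population shares (grouped shape of the US 2020 pyramid)
.default_group_shares <- function() {
  pop <- c(`<5` = 19392551, `5-14` = 42097211, `15-19` = 21546953,
           `20-24` = 21468520, `25-39` = 67927568, `40-60` = 88234779,
           `>60` = 70781388)
  pop / sum(pop)
}

#' Generate a synthetic demographics table
#'
#' Builds a small, fully synthetic population frame for tests, examples and
#' offline runs: \code{n_states} states whose populations sum exactly to
#' \code{total_population}, each with at least 5 unique ZIP codes, a single
#' year-of-age pyramid whose age-group shares default to the grouped shape
#' of the 2020 US pyramid, and sex/race splits jittered around typical US
#' state values. Output is deterministic for a fixed \code{seed}.
#'
#' @param n_states Number of states (>= 1).
#' @param total_population Total population across all states
#'   (>= \code{n_states}).
#' @param seed Integer seed; the function uses and then restores the global
#'   RNG state.
#' @param group_shares Optional named numeric vector of age-group population
#'   shares (names = the 7 group labels); normalised internally.
#' @return A \code{demographics_table}.
#' @examples
#' tab <- make_toy_demographics(2, 100000, seed = 7)
#' sum(sapply(tab$states, function(s) sum(s$pop_by_age)))
#' @export
make_toy_demographics <- function(n_states, total_population, seed,
                                  group_shares = NULL) {
  if (n_states < 1 || total_population < n_states) {
    stop("need n_states >= 1 and total_population >= n_states", call. = FALSE)
  }
  if (is.null(group_shares)) group_shares <- .default_group_shares()
  labels <- .age_group_labels()
  if (!setequal(names(group_shares), labels)) {
    stop("group_shares must be named by the 7 age-group labels", call. = FALSE)
  }
  group_shares <- normalize_categorical(group_shares)[labels]

  .with_seed(.child_seed(seed, "toy-demographics"), {
    codes <- paste0(LETTERS[((seq_len(n_states) - 1) %/% 26) %% 26 + 1],
                    LETTERS[(seq_len(n_states) - 1) %% 26 + 1])
    # state sizes: random positive shares, integerised to conserve the total
    shares <- stats::runif(n_states, 0.5, 1.5)
    state_pops <- .cascade_round(total_population * shares / sum(shares))
    state_pops <- pmax(state_pops, 0L)
    state_pops[n_states] <- state_pops[n_states] + (total_population - sum(state_pops))

    g <- age_groups()
    states <- lapply(seq_len(n_states), function(i) {
      # spread each group's mass uniformly over its single ages ("85+" is one cell)
      cells_per_group <- ifelse(is.finite(g$upper), g$upper - g$lower + 1,
                                84 - g$lower + 1 + 1)
      w <- rep(group_shares / cells_per_group, times = cells_per_group)
      pop <- .cascade_round(state_pops[i] * w / sum(w))
      pop[length(pop)] <- pop[length(pop)] + (state_pops[i] - sum(pop))
      zips <- sprintf("%05d", sample.int(99999, max(5, min(12, 5 + i)), replace = FALSE))
      male <- stats::runif(1, 48.2, 50.2)
      race <- normalize_categorical(c(
        `African-American` = stats::runif(1, 5, 25),
        `European-American` = stats::runif(1, 50, 75),
        Others = stats::runif(1, 15, 35)
      )) * 100
      .check_state(list(
        state_code = codes[i], zip_codes = zips,
        pop_by_age = stats::setNames(as.list(pop), .pop_age_keys),
        sex_percent = c(male = male, female = 100 - male),
        race_percent = race
      ))
    })
    .new_demographics(states, 2020L)
  })
}

#' Enumerate the (state, age group) strata of a demographics table
#'
#' One stratum per state and harmonised age group, in deterministic order
#' (state code, then age-group order). The "85+" census aggregate counts
#' toward the \verb{>60} group, so stratum populations within a state sum
#' exactly to the state total.
#'
#' @param table A \code{demographics_table}.
#' @return Data frame with columns \code{state_code}, \code{age_group},
#'   \code{population}.
#' @export
strata <- function(table) {
  stopifnot(inherits(table, "demographics_table"))
  g <- age_groups()
  codes <- sort(names(table$states))
  rows <- lapply(codes, function(code) {
    pop <- table$states[[code]]$pop_by_age
    ages <- c(0:84, 85)  # "85+" treated as the age-85 cell for binning
    grp <- age_to_group(ages)
    by_grp <- vapply(g$label, function(l) sum(pop[grp == l]), numeric(1))
    data.frame(state_code = code, age_group = g$label,
               population = as.numeric(by_grp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw ZIP codes for a state
#'
#' ZIPs are selected uniformly from the state's list, matching a residence
#' model in which the ZIP is chosen at random within the drawn state.
#'
#' @param state One element of \code{demographics_table$states}.
#' @param n Number of draws.
#' @return Character vector of \code{n} 5-digit ZIP codes.
#' @export
zip_for_state <- function(state, n = 1) {
  if (length(state$zip_codes) == 0) {
    stop("state has no ZIP codes configured", call. = FALSE)
  }
  state$zip_codes[sample.int(length(state$zip_codes), n, replace = TRUE)]
}

#' @export
print.demographics_table <- function(x, ...) {
  total <- sum(vapply(x$states, function(s) sum(s$pop_by_age), numeric(1)))
  cat(sprintf("Demographics table: %d state(s), total population %s (year %d)\n",
              length(x$states), format(total, big.mark = ","), x$reference_year))
  for (s in x$states) {
    cat(sprintf("  %s: population %s, %d ZIP codes\n", s$state_code,
                format(sum(s$pop_by_age), big.mark = ","), length(s$zip_codes)))
  }
  invisible(x)
}
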