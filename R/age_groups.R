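#' The seven harmonised age groups
#'
#' Rare-disease statistics in this package are harmonised to seven age
#' groups: \verb{<5}, \verb{5-14}, \verb{15-19}, \verb{20-24}, \verb{25-39},
#' \verb{40-60} and \verb{>60}. Bounds are inclusive integer years and the
#' groups partition ages 0, 1, 2, ... with no gap or overlap; \verb{>60} is
#' open-ended (census counts aggregated as "85+" belong to it).
#'
#' @return A data frame with columns \code{label}, \code{lower} and
#'   \code{upper} (years; \code{upper} is \code{Inf} for \verb{>60}), one row
#'   per group in increasing age order.
#' @examples
#' age_groups()
#' @export
age_groups <- function() {
  data.frame(
    label = c("<5", "5-14", "15-19", "20-24", "25-39", "40-60", ">60"),
    lower = c(0L, 5L, 15L, 20L, 25L, 40L, 61L),
    upper = c(4, 14, 19, 24, 39, 60, Inf),
    stringsAsFactors = FALSE
  )
}

# group labels in canonical order (used all over for named vectors)
.age_group_labels <- function() age_groups()$label

#' Assign ages to the harmonised age groups
#'
#' @param age Vector of non-negative integer ages in years.
#' @return Character vector of group labels, same length as \code{age}.
#' @examples
#' age_to_group(c(0, 14, 15, 61))
#' @export
age_to_group <- function(age) {
  if (length(age) == 0) return(character(0))
  if (anyNA(age) || any(age < 0)) {
    stop("`age` must be non-negative and non-missing", call. = FALSE)
  }
  g <- age_groups()
  idx <- findInterval(age, g$lower)
  g$label[idx]
}
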