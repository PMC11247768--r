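make_cohort <- function(disease = "SCD", seed = 13, pop = 500000, states = 2) {
  tab <- toy_table(states, pop, seed = 8)
  list(table = tab,
       cohort = generate_cohort(profiles[[disease]], tab,
                                generation_settings(seed = seed)))
}

test_that("cohorts round-trip losslessly through CSV", {
  x <- make_cohort("DMD", pop = 3000000)  # plenty of deceased records
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x$cohort, f)
  back <- read_cohort(f)
  expect_equal(back, x$cohort$records)
  # deceased rows carry a death date in the file, alive rows an empty field
  lines <- readLines(f)
  expect_gt(length(lines), 1)
  dead <- back$vital_status == "deceased"
  expect_true(any(dead))
  expect_true(all(!is.na(back$date_of_death[dead])))
  expect_true(all(is.na(back$date_of_death[!dead])))
  # persistence does not change statistics
  reread <- structure(list(records = back, disease = x$cohort$disease,
                           profile = x$cohort$profile, settings = NULL),
                      class = "rd_cohort")
  expect_equal(summary(reread, x$table), summary(x$cohort, x$table))
})

test_that("an empty cohort writes a header-only file", {
  tab <- single_age_table(30, 100)
  coh <- generate_cohort(profiles$CF, tab,
                         generation_settings(count_mode = "rounded-expectation"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  expect_length(readLines(f), 1)
  expect_equal(nrow(read_cohort(f)), 0)
})

test_that("malformed cohort files are rejected with a row reference", {
  x <- make_cohort(pop = 200000)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x$cohort, f)
  lines <- readLines(f)
  bad <- sub("alive", "zombie", lines[2], fixed = TRUE)
  writeLines(c(lines[1], bad, lines[-(1:2)]), f)
  expect_error(read_cohort(f), "row 1.*vital_status")
})

test_that("summary counts and percentages are exact", {
  x <- make_cohort(pop = 400000)
  rec4 <- x$cohort$records[1:4, ]
  rec4$sex <- c("male", "male", "male", "female")
  mini <- structure(list(records = rec4, disease = x$cohort$disease,
                         profile = x$cohort$profile, settings = NULL),
                    class = "rd_cohort")
  s <- summary(mini)
  expect_equal(s$n_total, 4)
  expect_equal(s$n_male, 3)
  expect_equal(s$female_percent, 25)
  expect_equal(sum(s$by_age_group$patients), 4)

  rec4$vital_status <- "deceased"
  s2 <- summary(structure(list(records = rec4, disease = x$cohort$disease),
                          class = "rd_cohort"))
  expect_equal(s2$n_deceased, s2$n_total)

  full <- summary(x$cohort, x$table)
  expect_equal(full$n_male + full$n_female, full$n_total)
  expect_equal(sum(full$race_percent), 100, tolerance = 0.01)
  expect_equal(sum(full$by_age_group$patients), full$n_total)
  expect_equal(full$by_age_group$population,
               tapply(strata(x$table)$population,
                      factor(strata(x$table)$age_group, levels = age_groups()$label),
                      sum) |> as.numeric())
})

test_that("expected-vs-observed comparison passes for faithful cohorts and is consistent", {
  x <- make_cohort(pop = 1000000)
  cmp <- compare_to_expected(summary(x$cohort, x$table), profiles$SCD, x$table)
  expect_true(all(cmp$pass))
  expect_equal(cmp$abs_diff, abs(cmp$result - cmp$expected))
  expect_equal(cmp$pass, cmp$abs_diff <= cmp$tolerance)
  expect_setequal(
    cmp$metric,
    c("total_patients", "female_percent", "deceased_patients",
      paste0("race_percent_", c("African-American", "European-American", "Others")))
  )
  # expected total is the rounded per-stratum expectation
  st <- strata(x$table)
  expect_equal(cmp$expected[cmp$metric == "total_patients"],
               sum(round(st$population / 3300)))
})

test_that("a tampered race distribution fails the comparison", {
  x <- make_cohort(pop = 3300 * 100000, states = 1)
  rec <- x$cohort$records
  set.seed(1)
  rec$race <- sample(c("African-American", "European-American", "Others"),
                     nrow(rec), replace = TRUE)  # uniform: ~33% each, not 73/3/24
  tampered <- structure(list(records = rec, disease = x$cohort$disease,
                             profile = x$cohort$profile, settings = NULL),
                        class = "rd_cohort")
  cmp <- compare_to_expected(summary(tampered, x$table), profiles$SCD, x$table)
  expect_false(all(cmp$pass))
  expect_false(cmp$pass[cmp$metric == "race_percent_African-American"])
})

test_that("comparison refuses a profile for a different disease", {
  x <- make_cohort(pop = 200000)
  expect_error(compare_to_expected(summary(x$cohort, x$table), profiles$CF, x$table),
               "different diseases")
})

test_that("age-group breakdown conserves patients and follows prevalence", {
  x <- make_cohort("CF", pop = 2000000)
  bd <- age_group_breakdown(x$cohort, x$table)
  expect_equal(sum(bd$patients), nrow(x$cohort$records))
  expect_equal(sum(bd$deceased),
               sum(x$cohort$records$vital_status == "deceased"))
  # all population concentrated in one group puts every patient there
  one <- single_age_table(30, 500000)
  coh <- generate_cohort(profiles$SCD, one, generation_settings(seed = 2))
  bd1 <- age_group_breakdown(coh, one)
  expect_equal(bd1$patients[bd1$age_group == "25-39"], nrow(coh$records))
  expect_equal(sum(bd1$patients), nrow(coh$records))
})
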