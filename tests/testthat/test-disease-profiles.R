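test_that("categorical weights are rescaled proportionally", {
  expect_equal(normalize_categorical(c(male = 50, female = 50)),
               c(male = 0.5, female = 0.5))
  expect_equal(normalize_categorical(c(a = 1)), c(a = 1))
  # published CF sex row sums to 101
  expect_equal(normalize_categorical(c(male = 51.7, female = 49.3)),
               c(male = 51.7 / 101, female = 49.3 / 101))
  expect_error(normalize_categorical(c(a = 0, b = 0)), "zero")
  expect_error(normalize_categorical(c(a = -1, b = 2)), "negative")
  expect_error(normalize_categorical(c(1, 2)), "named")
})

test_that("ages map onto the seven harmonised groups", {
  expect_equal(age_to_group(c(0, 4, 5, 14, 15, 19, 20, 24, 25, 39, 40, 60, 61)),
               c("<5", "<5", "5-14", "5-14", "15-19", "15-19", "20-24", "20-24",
                 "25-39", "25-39", "40-60", "40-60", ">60"))
  # total and surjective over 0..100, consistent with the group bounds
  grp <- age_to_group(0:100)
  expect_false(anyNA(grp))
  expect_setequal(unique(grp), age_groups()$label)
  g <- age_groups()
  for (i in seq_len(nrow(g))) {
    ages <- (0:100)[grp == g$label[i]]
    expect_true(all(ages >= g$lower[i] & ages <= g$upper[i]))
  }
  expect_error(age_to_group(-1), "non-negative")
})

test_that("packaged profiles carry the published statistics", {
  expect_equal(profiles$SCD$prevalence_denominator, 3300L)
  expect_equal(profiles$CF$prevalence_denominator, 10311L)
  expect_equal(profiles$DMD$prevalence_denominator, 6000L)

  expect_equal(unname(profiles$SCD$race_dist["African-American"]), 0.731)
  expect_equal(unname(profiles$SCD$sex_dist), c(0.5, 0.5))
  expect_equal(unname(profiles$CF$race_dist["European-American"]), 0.914)
  expect_equal(unname(profiles$DMD$race_dist["European-American"]), 0.43)

  expect_equal(unname(profiles$DMD$death_rates[">60"]), 99990)
  expect_equal(unname(profiles$SCD$death_rates["25-39"]), 2.75)

  expect_equal(profiles$CF$diagnosis$unit, "days")
  expect_equal(profiles$CF$diagnosis$mu, 2.5)
  expect_equal(profiles$SCD$diagnosis$unit, "months")
  expect_equal(profiles$DMD$diagnosis$unit, "years")

  cbc <- profiles$SCD$clinical_params$complete_blood_count
  expect_equal(c(cbc$low, cbc$high, cbc$mu, cbc$spread), c(6, 11, 8.5, 2.5))
  ck <- profiles$DMD$clinical_params$creatine_kinase
  expect_equal(c(ck$low, ck$high, ck$mu, ck$spread), c(350, 23200, 11775, 6475))
})

test_that("CF sex percentages (sum 101) are normalised and the fix recorded", {
  path <- system.file("extdata", "profiles", "cf.json", package = "rdcohort")
  expect_warning(cf <- load_profile(path), class = "rd_normalisation_warning")
  expect_equal(unname(cf$sex_dist["female"]), 49.3 / 101)
  expect_match(cf$notes, "sex_percent", all = FALSE)
  # all packaged distributions are exact probability distributions
  for (p in profiles) {
    expect_equal(sum(p$race_dist), 1, tolerance = 1e-12)
    expect_equal(sum(p$sex_dist), 1, tolerance = 1e-12)
  }
})

test_that("profile schema violations name the offending field", {
  path <- system.file("extdata", "profiles", "scd.json", package = "rdcohort")
  raw <- jsonlite::read_json(path)

  broken <- withr::local_tempfile(fileext = ".json")
  bad <- raw
  bad$death_rate_per_100k <- NULL
  jsonlite::write_json(bad, broken, auto_unbox = TRUE, digits = NA)
  expect_error(load_profile(broken), "death_rate_per_100k",
               class = "rd_schema_error")

  bad <- raw
  names(bad$death_rate_per_100k)[1] <- "0-4"
  jsonlite::write_json(bad, broken, auto_unbox = TRUE, digits = NA)
  expect_error(load_profile(broken), "age groups", class = "rd_schema_error")

  bad <- raw
  bad$death_rate_per_100k$`<5` <- -1
  jsonlite::write_json(bad, broken, auto_unbox = TRUE, digits = NA)
  expect_error(load_profile(broken), "\\[0, 100000\\]", class = "rd_schema_error")

  bad <- raw
  bad$prevalence_denominator <- 0
  jsonlite::write_json(bad, broken, auto_unbox = TRUE, digits = NA)
  expect_error(load_profile(broken), "positive integer", class = "rd_schema_error")
})

test_that("profiles survive a write/load round trip", {
  for (p in profiles) {
    f <- withr::local_tempfile(fileext = ".json")
    write_profile(p, f)
    q <- load_profile(f)  # already normalised, so no warning expected
    q$notes <- p$notes <- character(0)
    expect_equal(q, p, tolerance = 1e-12)
  }
})
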