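# Shared fixtures: profiles are loaded once; demographics tables are built
# in code so no binary test data is needed.

profiles <- builtin_profiles()

toy_table <- function(n_states = 2, total_population = 400000, seed = 7) {
  make_toy_demographics(n_states, total_population, seed)
}

# a 1-state table with all population at a single year of age (and one or
# more ZIPs), written through the JSON loader so the schema path is exercised
single_age_table <- function(age, population, zips = "12345", code = "ZZ") {
  pop <- as.list(stats::setNames(rep(0, 86), c(as.character(0:84), "85+")))
  pop[[as.character(age)]] <- population
  path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  jsonlite::write_json(
    list(reference_year = 2020,
         states = list(list(
           state_code = code, zip_codes = as.list(zips), pop_by_age = pop,
           sex_percent = list(male = 49, female = 51),
           race_percent = list(`African-American` = 13.6,
                               `European-American` = 61.0, Others = 25.4)))),
    path, auto_unbox = TRUE, digits = NA
  )
  load_demographics(path)
}

# date-consistency checks shared by generator and acceptance tests
expect_record_invariants <- function(records, table, reference_date) {
  expect_true(all(records$date_of_birth <= records$date_of_diagnosis))
  dead <- records$vital_status == "deceased"
  expect_identical(dead, !is.na(records$date_of_death))
  expect_true(all(records$date_of_diagnosis[dead] <= records$date_of_death[dead]))
  expect_true(all(records$date_of_death[dead] <= reference_date))
  expect_true(all(records$date_of_diagnosis <= reference_date))
  zip_ok <- mapply(
    function(z, s) z %in% table$states[[s]]$zip_codes,
    records$zip, records$state
  )
  expect_true(all(zip_ok))
  alive <- !dead
  expect_equal(records$age_years[alive],
               rdcohort:::.floor_age(records$date_of_birth[alive], reference_date))
  expect_equal(records$age_years[dead],
               rdcohort:::.floor_age(records$date_of_birth[dead],
                                     records$date_of_death[dead]))
}
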