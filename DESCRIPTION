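Package: rdcohort
Title: Synthetic Rare-Disease Patient Cohorts from Published Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates synthetic patient-level datasets for rare diseases
    from published aggregate statistics: disease prevalence, race and sex
    distributions, age-dependent death rates and clinical-parameter ranges,
    combined with a state-by-age population sampling frame. Ships curated
    statistics profiles for sickle cell disease, cystic fibrosis and
    Duchenne muscular dystrophy, a seeded synthetic-demographics generator
    for fully offline use, hierarchical record-by-record cohort generation,
    CSV persistence and expected-versus-observed validation reports.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
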