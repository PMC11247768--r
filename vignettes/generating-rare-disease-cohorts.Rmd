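---
title: "Generating synthetic rare-disease cohorts from aggregate statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic rare-disease cohorts from aggregate statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcohort)
```

## Why synthetic cohorts

Patient-level data on rare diseases is scarce and unusually privacy-sensitive:
each disease affects a small demographic, so even partially anonymised records
carry re-identification risk. Software that serves rare-disease research —
registries, biobank information systems, anonymisation pipelines — still needs
realistic test data. `rdcohort` fills that gap by generating patient-level
datasets *from published aggregate statistics only*: disease prevalence, race
and sex distributions, age-specific death rates, diagnostic-lag distributions
and clinical laboratory ranges. No real patient contributes to the output, yet
the marginal statistics of a generated cohort converge to the published
parameters, which is exactly the property a test dataset needs.

Three curated statistics profiles ship with the package: sickle cell disease
(SCD, ORPHA 232, prevalence 1/3300), cystic fibrosis (CF, ORPHA 586, 1/10311)
and Duchenne muscular dystrophy (DMD, ORPHA 98896, 1/6000). The profile schema
is generic JSON, so users can curate profiles for further diseases.

## The sampling model

Generation is hierarchical and stratified. The sampling frame is a
demographics table: for every state, a population count per single year of age
(0–84, with 85 and over aggregated), a ZIP code list, and state-level sex and
race splits. Ages are harmonised into seven groups — `<5`, `5-14`, `15-19`,
`20-24`, `25-39`, `40-60`, `>60` — read as the contiguous integer partition
0–4, 5–14, 15–19, 20–24, 25–39, 40–60, 61+ (the only gap-free reading of the
labels; the 85+ census aggregate belongs to `>60`).

For each (state, age-group) stratum with population $N_{s,g}$ and disease
prevalence $1/D$, the patient count is

$$ n_{s,g} \sim \mathrm{Binomial}(N_{s,g},\ 1/D) $$

in the default `binomial` count mode. Each of the $n_{s,g}$ records is then
filled in top-down, so attributes drawn at one level condition the next:

1. **ZIP code** — uniform over the state's ZIP list (the published procedure
   says "randomly selected from the set"; no population weighting is stated,
   so none is applied).
2. **Sex** and **race** — drawn from the mixture
   $\beta\,p_{\text{disease}} + (1-\beta)\,p_{\text{state}}$ with blend weight
   $\beta \in [0,1]$, default $\beta = 1$. The default is deliberate: the
   expected national marginals of a cohort should equal the disease
   distributions, which only holds at $\beta = 1$. Smaller blends let users
   re-introduce state-level census structure at the cost of biased national
   marginals.
3. **Age** — a single year of age within the stratum's group, weighted by the
   state's single-year counts. When the 85+ aggregate is drawn, a concrete age
   is sampled uniformly from 85–99 (no upper bound is published; 99 keeps
   ages plausible).
4. **Clinical parameters** — see the truncated normal below.
5. **Vital status** — deceased with probability $r_g/100{,}000$, where $r_g$
   is the age group's published death rate. This per-patient Bernoulli reading
   is the simplest interpretation of a "death rate per 100,000" applied to a
   prevalent cohort; cumulative-hazard readings were considered and rejected
   because the published per-group death statistics could not be reproduced
   under any of them either, and the Bernoulli reading keeps the published
   rate directly verifiable in the output.
6. **Dates** — see below.

### The truncated normal

Every continuous specification is published as a range plus a centre:
"low–high, $\mu \pm s$". We interpret $s$ as the standard deviation of a
normal distribution *truncated* to $[\text{low}, \text{high}]$, sampled by
inverse CDF. The untruncated reading is untenable: for every published
specification $\mu \pm s$ exactly spans the published range (e.g. haemoglobin
6–11 g/dL with $8.5 \pm 2.5$), so an untruncated normal would place ~32% of
draws outside its own plausible range. Because every published spec is
symmetric ($\mu$ centred in the range), truncation preserves the mean — the
acceptance checks rely on this. With $s \rightarrow 0$ the sampler degenerates
to the constant $\mu$.

### Dates

Age is the *completed-years* (floor) age. For a living patient of age $a$ the
date of birth is uniform over the $\sim$365-day window of dates whose floor
age at the reference date (default 2023-01-01, the date at which ages are
evaluated) equals $a$. Deceased patients' drawn age is their age at death:
their birth date is drawn from the same window, and the death date uniformly
over the days on which their floor age equals $a$, capped at the reference
date. Diagnosis dates are birth plus an offset drawn from the profile's
truncated normal in its native unit, converted at 30.44 days/month and 365.25
days/year and rounded to whole days. An offset that would pass the reference
date (or the death date) is clamped to it and the record is flagged in the
`diagnosis_clamped` column — newborns diagnosed "1–3 years after birth" are
the typical case. Feb-29 birthdays count their anniversary on Mar 1 in
non-leap years.

### Count modes and cascade rounding

`rounded-expectation` mode replaces the binomial draw with a deterministic
count. Rounding each stratum independently would lose mass — on a frame of
10,311 people with CF prevalence 1/10311 every stratum expectation rounds to
zero although the frame should contribute one patient. We therefore use
running-remainder (cascade) rounding across strata: stratum $i$ receives
$\mathrm{round}(\sum_{j \le i} E_j) - \mathrm{round}(\sum_{j < i} E_j)$, so
each count differs from $\mathrm{round}(E_i)$ by at most one while the cohort
total is exactly $\mathrm{round}(\sum_j E_j)$. The standalone
`draw_stratum_count()` keeps the plain per-stratum contract.

### Reproducibility

One root seed controls a run, but strata do not share a stream: each
(state, age group) derives a child seed from a 31-ary fold of
(seed, state code, group label), all below $2^{31}$. Consequently results are
bit-identical for identical inputs and seed, independent of the order in which
states are processed, and adding a state leaves every other state's records
untouched. Functions that seed internally save and restore the caller's RNG
state.

## The synthetic demographics generator

Real census retrieval is out of scope; `make_toy_demographics()` synthesises
a frame that is structurally faithful: state populations that sum exactly to
the requested total, an age pyramid whose default group shares follow the
grouped shape of the 2020 US pyramid (5.9% under 5, 12.7% 5–14, 6.5% 15–19,
6.5% 20–24, 20.5% 25–39, 26.6% 40–60, 21.4% over 60), uniform single-year
counts within each group, at least 5 unique ZIP codes per state, and sex/race
splits jittered around typical US state values. It does **not** emulate
real-data features the generator never consumes at national scale: true
geographic population ranking, race-by-state correlation, single-year pyramid
texture (baby booms), or time dynamics. Tests passing on this frame therefore
demonstrate the *sampling machinery* — conservation, stratification,
convergence of marginals to the disease profile — not geographic realism. A
user with a real census extract can supply it via `load_demographics()`.

## Validation reports

`summary()` on a cohort computes the marginals a registry would check: total,
male/female and deceased counts, race percentages and a per-age-group
breakdown (stratum population, patients, deceased). `compare_to_expected()`
turns these into expected-vs-observed rows. Expected values come from the
profile (and, for the total, from $\sum_g \mathrm{round}(N_g/D)$); the default
tolerance is 3 binomial standard errors at the cohort's size, since no
specific hypothesis test is prescribed for these checks — a correctly
parameterised generator passes each row with probability ≈ 99.7%, while a
distribution shifted by more than sampling noise fails. Tolerances are
configurable via `tolerance_multiplier`.

## Numerical and design choices

- Prevalence is stored as the integer denominator $D$ of $1/D$, avoiding
  float drift in expectations.
- Percentage blocks are proportionally renormalised on load; a deviation of
  the total from 100 by more than 0.5 is surfaced as a
  `rd_normalisation_warning` and kept in the profile's `notes` (the published
  CF sex row sums to 101%, and silently absorbing that would hide a data
  issue).
- Published DMD female share: the profile follows the primary statistics
  table (0.01%).
- Deceased patients keep their age at death in `age_years` and are counted in
  their at-death age group in summaries; "age as of reference date" applies
  to living patients only.
- Patient identifiers are disease-initial prefixes plus zero-padded sequence
  numbers; no names or free-text fields are generated.
- Display rounding (2 decimals in printed reports) never touches stored
  values.

## Problem sizes

The test suite generates cohorts of roughly 100,000 records for the
marginal-convergence checks (on single-state frames sized at
$D \times 101{,}000$ so the expected count exceeds 100,000), 10,000-record
cohorts for the structural date/ZIP invariants, and 100,000 draws per
continuous distribution; at these sizes each convergence tolerance sits at
3–5 standard errors, and a full run takes well under a minute. The
`scripts/acceptance.R` report uses the same sizes.

## Limitations

The generator produces cross-sectional snapshots, not longitudinal
trajectories, comorbidities or treatment events, and offers no formal privacy
guarantee beyond containing no real individual's data. Death dating ignores
within-group mortality gradients, and the published per-group deceased counts
for CF could not be reconciled with the published death rates under any
simple reading — the per-patient Bernoulli model is used and reported as-is.
Race/sex census splits are state-level, not state-by-age.
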