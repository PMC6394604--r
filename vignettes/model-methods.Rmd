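---
title: "A stage-stratified Markov costing model for epithelial ovarian cancer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eocburden)
```

## The model

`eocburden` estimates the economic burden of incident epithelial ovarian
cancer (EOC) from a societal perspective. The disease model is a
deterministic three-state Markov cohort model — *stable*,
*post-progression*, *dead* — evaluated separately for each FIGO stage at
diagnosis (I–IV) and each annual incident cohort. Stage is fixed at
diagnosis; progression is irreversible. The cycle length is 21 days (one
chemotherapy cycle), the horizon 10 years, and a reporting "year" is 18
cycles (`ceil(365.25/21)`), about 378 days; the small residual is absorbed
in the final reporting bucket of each cohort.

Per cycle, with `t = 21/365.25` years:

* `Ppss = 1 − exp(−λ t)`, `λ = ln 2 / me_PFS` — progression-free survival
  is exponential with the stage's median PFS. The 21-day discretization is
  exact for exponentials, which the tests exploit: cumulative progression
  in a mortality-free trace equals the closed-form CDF at every cycle
  boundary to 1e-9.
* `Pdss = Pnd = 1 − exp(−r(⌊age⌋) t)` — stable-state death is general
  female population mortality only, looked up at the integer part of the
  attained age (age at diagnosis plus elapsed cycles; ages beyond the
  life table clamp to the oldest rate). Disease-specific death before
  progression is not modelled, which follows from defining stable-state
  death as background mortality.
* `Pdps = min(1, 1 − exp(−λ′ t) + Pnd)`, `λ′ = ln 2 / (me_OS − me_PFS)` —
  post-progression survival is exponential with median `me_OS − me_PFS`,
  plus background mortality. The additive form can exceed 1 under extreme
  inputs; it is capped, and if `Pdss + Ppss` ever exceeds 1 the pair is
  renormalized with a warning.

The trace is an expected-value cohort evaluation: no random numbers are
used anywhere in the engine, and identical inputs give bit-identical
traces. No half-cycle correction is applied; state membership is
evaluated at cycle start for occupancy costing and events (progressions,
deaths) are discounted at cycle end. A half-cycle switch was considered
and left out: with 21-day cycles the correction is below the precision of
every other input.

Cohorts are the mean patient: the model tracks one mean age, weight and
height per stage rather than an age distribution. This mirrors the use of
stage-level means in the epidemiology table and keeps the human-capital
calculations closed-form, but it makes the indirect-cost zeros sharp
(e.g. a stage diagnosed at mean age 68.1 produces exactly zero
productivity losses, where a full age distribution would produce a small
positive tail).

## Incident cohorts

Year-1 ovarian-cancer incidence (default 3,497) with a configurable
linear annual increment (default 0) is multiplied by the epithelial
fraction (default 90%) and split over stages with an unchanged
distribution. Default year-1 stage counts are the packaged table
(1155/195/1116/681, summing to 3,147); later years use largest-remainder
rounding so integer stage counts always sum to the EOC total (fractional
counts are supported — costing is linear, so this only affects
reporting). A cohort entering model year *k* is simulated for
`11 − k` years, so every trace stops at the calendar end of the horizon.

## Costing engine

All costs are in 2016 euros. Unit costs carry a source year and a CPI
category — medicine (0.77%/yr) for healthcare tariffs, general (1.97%/yr)
for non-healthcare costs, `none` for tariffs already expressed in 2016
euros — and are compounded to the base year at load time. Every stream is
discounted at 3%/yr from model start at cycle resolution.

**Diagnosis-time streams** (entry cycle): the opportunistic screening
item plus the BRCA cascade patient side (20% tested × test + two
counselling visits); the cascade relatives side (5% positive × five
relatives × counselling + biannual transvaginal ultrasound and CA125 over
a 10-year surveillance window, accrued and discounted at the index
diagnosis — the within-stream discounting of the biannual tests is
deliberately ignored as second-order); the diagnostic work-up bundle; the
surgical bundle (per-procedure probabilities × procedure costs, for every
operated patient); up-front chemotherapy; and the one-off temporary-leave
productivity loss.

**Chemotherapy** comes in four categories. Neoadjuvant is 3 cycles of
paclitaxel–carboplatin before surgery plus 3 after, costed at entry for
the neoadjuvant mix fraction. Adjuvant (stages I–III, default 6 cycles)
is costed at entry for the surgery-plus-adjuvant fraction. The
post-progression category (stages I–II, default 6 cycles per line) and
the advanced category (post-progression state at stage III, both states
at stage IV) are tied to state occupancy: each progression cohort is
tracked by time since progression (an exact decomposition, since the
post-progression state only exits through death) and treated while within
the category's cycle cap. The advanced category's cap defaults to *none*:
advanced disease is treated in successive lines essentially while the
patient occupies an eligible state. A finite cap is a catalogue
parameter. At stage IV the stable-state stream covers the
chemotherapy-receiving mix fraction from diagnosis and no separate entry
regimen is booked, so nothing is double-counted. An earlier 12-cycle
default cap was rejected because it contradicts the description of the
advanced category (both states, no stated duration) and inverts the
expected stage III/IV cost ordering.

Doses follow the drug's rule: per m² via Du Bois
(`0.007184 · h^0.725 · w^0.425`), carboplatin via Calvert
(`AUC × (GFR + 25)`; GFR is a configurable constant, default 100 mL/min,
since no serum-creatinine source is specified), per kg, or flat. Each
administration is covered by whole vials with no sharing; the solver
finds the cheapest covering combination by exhaustive search with cost
pruning (ties broken by fewest vials) and is tested against full
enumeration. Vial prices are list prices minus the statutory deduction
(default 7.5%, the general rate, per-drug overridable; swept 0–6% in the
sensitivity suite) plus 4% VAT. Administration adds €0.32/min over the
infusion plus a 30-minute preparation. Market shares weight regimens
within a category and sum to 1.

**Occupancy streams**: follow-up visits/tests per state (an editable
annual schedule, less intensive while stable), and hospitalizations and
emergency attendance as the stage's semiannual expectation divided by the
cycles in six months, applied to all alive patients (the rates are not
split by state in the source table).

**Death-linked streams**: the palliative pathway (93.3% outpatient with
nurse follow-up — 7 visits by default, a documented assumption, roughly
weekly over the 48-day pathway, as no count is stated — versus 6.7%
home-care team with 9.5 home visits; four primary-care visits for all;
terminal phase 59.6% at home with twice-daily nurse visits over the last
3 days versus 40.4% in hospital; 14% sedation), and formal care over the
last 48 days (9.5% public at 1.5 h/day, 17.4% private at 8 h/day, at the
common €13.56/h caregiver wage).

**Informal care** is valued by the proxy-good method (93.4% cared for,
10.3 h/day, €13.56/h). Its default window is post-progression occupancy,
not the last 48 days: a 48-day window caps the per-death informal cost
near €6.7k, an order of magnitude below the published informal-care
magnitudes per patient-year, so the last-48-days wording cannot apply to
the informal component. The window is a config option
(`informal_care_window`: `post_progression` or `last_48_days`).

**Indirect costs** use the human-capital method with a synthetic
age-specific employment-and-wage schedule (employment 0 from 65), 1%/yr
productivity growth indexed from model start, and the same 3% discount
rate as all other streams (one model-wide rate; premature-mortality
streams have an undiscounted switch). Temporary leave is
`0.3 × 60 + 0.7 × 70 = 67` expected days once per employed patient
diagnosed before 65 ("over 70 days" is implemented as exactly 70, a
configurable lower bound). From progression, patients are on sick leave
until death or 65; the first year books to the temporary row and the
remainder to permanent disability. Premature mortality values the
discounted earnings stream from the age at death to 65. The sharp
consequences under the defaults — all three rows exactly zero at stage IV
(mean age 68.1) and permanent disability exactly zero at stage III (64.9:
retirement arrives within a year of any progression) — reproduce the
published zero cells and are asserted in the acceptance tests.

## Reporting

Discounted euros are bucketed into 18-cycle reporting years per cohort
and aggregated into a stage × category breakdown (15 item rows, DHC/DNHC/
IC subtotals, stage totals, grand total). The average annual cost per
patient divides each year's cost by the patients alive at the year start
plus that year's incident patients, and averages over the ten reporting
years. Internal arithmetic is full precision; display rounding (whole
euros, one decimal for millions and shares) happens only at output. The
packaged printed-results fixture is used purely to verify this
aggregation layer; item-level cells are whole-euro rounded, so re-derived
subtotals are compared within 5 euros. One fixture note: the stage IV
hospitalizations cell was printed with dot thousands separators and is
stored normalized (315441267), and the published stage II share (3.9%)
disagrees with its own cell ratio (116.6/3102.3 = 3.76%) — the fixture
reproduces the ratio.

## Sensitivity analysis

Ten one-way deterministic scenarios: genetic-counselling referral 35–70%
(the printed base is 20%; the inconsistency between base and scenario
range is preserved as printed), weight ±10%, productivity growth 0–2%,
manufacturer drug price −10%, drug deduction rate 0–6% ("discount drug
rate" is read as the statutory deduction; an alias can sweep the model
discount rate instead), test/visit prices at the regional minimum and
maximum (fixture columns), age at diagnosis ±10%, bevacizumab at
7.5 mg/kg, caregiver wage €7.5/h, informal-care hours ±30%. Scenario
application is pure (deep copy; the base registry is re-verified
bit-identical after the suite), wage and price scenarios scale exactly
the rows they touch, and tornado rows sort by total-burden range with an
alphabetical tie-break.

## The synthetic input tables

The unit-cost table, drug catalogue, life table and labour schedule that
the published analysis drew from unpublished supplementary tables are
generated here as clearly-labelled synthetic placeholders: deterministic
per seed, structured exactly as the costing engine requires (min/median/
max regional prices with source years and CPI categories; regimens with
market shares, dose rules, infusion times and vial options; Gompertz
female mortality `r(age) = a·e^{b·age}` with defaults giving ~0.0035 at
age 57 and ~0.012 at 70; employment and wages by age, zero from 65).
Magnitudes are field-plausible (e.g. a hospital stay around €4,200, an
oncology visit around €95, bevacizumab around €3/mg) and every generated
file carries a provenance header with generator version and seed.

What passing tests therefore show — and do not show: the engine's
structure, conservation laws, closed forms, linearity and the published
*qualitative* pattern (per-patient annual cost strictly increasing from
stage I to IV, indirect costs heaviest at stage I, DHC dominant,
chemotherapy the largest stage-IV DHC row) are all verified; the
published *absolute* euro outputs are not reproducible without the real
tariff tables and are deliberately not targeted. No attempt is made to
reverse-engineer the true unit costs from the printed results (the
system is under-determined).

## Numerical choices and degenerate inputs

* Probability rows are clamped to the simplex with a logged warning only
  in degenerate configurations; under the defaults no clamping fires.
* A zero-size cohort yields an all-zero trace; a zero patient denominator
  in the per-patient average is an error, not NaN.
* The stage III treatment mix prints as 99.9%; mixes within 0.5% of 1 are
  renormalized at load, anything further off is a validation error.
* Parameter serialization writes doubles at 17 significant digits so the
  save/load round trip is bit-exact.
* Synthetic generation draws from a private RNG stream and restores the
  caller's `.Random.seed`.

## Problem sizes

The default configuration — 4 stages × 10 annual cohorts × up to 180
cycles, with per-cycle costing and the time-since-progression
decomposition — runs in well under a second; the full ten-scenario
tornado re-runs the model ~18 times and completes in a few seconds. The
test suite's property checks (including 1,000 random vial-solver
instances against full enumeration) run in under a minute.

## Known limitations

Incidence-based only (prevalent patients at model start are excluded);
exponential survival throughout, parameterized solely by printed medians;
mean-age cohorts rather than age distributions; no stage migration, no
adverse-event costing, no QALYs, no probabilistic sensitivity analysis
(the underlying analysis is deterministic); vials are never shared, which
overstates drug cost relative to day-hospital practice; and the absolute
euro level of every output inherits the synthetic placeholder tariffs.
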