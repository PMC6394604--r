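Package: eocburden
Title: Economic Burden of Epithelial Ovarian Cancer: A Markov Cohort Costing Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic three-state (stable, post-progression, dead) Markov
    cohort model of incident epithelial ovarian cancer by FIGO stage, with an
    attached costing engine covering direct healthcare costs (screening, genetic
    counselling, diagnosis, follow-up, surgery, chemotherapy with body-surface-area
    and Calvert dose math, hospitalizations, emergencies, palliative care), direct
    non-healthcare costs (formal and informal care valued by the proxy-good
    method) and indirect costs (human-capital productivity losses), plus
    discounting, per-patient annual averaging, reporting in a stage-by-category
    breakdown, one-way deterministic sensitivity analysis, and a synthetic
    generator for the unit-cost, drug-catalogue, life-table and labour-market
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
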