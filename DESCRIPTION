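Package: mapcea
Title: Markov Cohort Cost-Effectiveness Model of MDMA-Assisted
    Psychotherapy for Chronic PTSD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model of MDMA-assisted
    psychotherapy (MAP) for chronic, treatment-resistant posttraumatic
    stress disorder, from the health-care payer's perspective. A cohort
    of 1,000 patients is followed through annual cycles over five
    CAPS-IV severity states plus death, accruing state-specific medical
    costs, utilities (QALYs) and relative-risk-scaled background
    mortality, with 3% annual discounting and a five-year phase-in of
    post-treatment cost reductions. Provides incremental
    cost-effectiveness outcomes (net cost, QALYs gained, deaths
    averted, ICER or dominance, break-even horizon), deterministic
    sensitivity analyses (one-way tornado, two-way grids, threshold
    search, disease-progression scenario), probabilistic sensitivity
    analysis by Monte Carlo simulation, and a synthetic patient-level
    CAPS cohort generator calibrated to published severity
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
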