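Package: egfrCEA
Title: Markov Cohort Cost-Effectiveness Analysis of First-Line Erlotinib
    versus Carboplatin-Gemcitabine in EGFR-Mutant NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trial-based health-economic decision model comparing first-line
    erlotinib monotherapy against carboplatin-gemcitabine (CG) doublet
    chemotherapy in advanced EGFR mutation-positive non-small-cell lung
    cancer, from the Chinese health-care-system perspective. Implements
    Weibull survival calibration to trial medians or Kaplan-Meier data, a
    three-state (progression-free, progressed, dead) cohort Markov model with
    3-week cycles over a 10-year horizon, cycle-indexed cost and utility
    accumulation with 3 percent annual discounting, incremental
    cost-effectiveness ratios, one-way (tornado) sensitivity analysis, and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. A synthetic-data module generates pseudo individual-patient
    progression-free-survival data so the survival machinery is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
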