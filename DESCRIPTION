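Package: zostercea
Title: Markov Cohort Cost-Effectiveness Model for Herpes Zoster Vaccination
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision tree-Markov cohort model comparing no vaccination,
    one-dose live attenuated zoster vaccine (ZVL) and two-dose recombinant
    subunit zoster vaccine (RZV) in adults aged 50 years and older. Runs
    annual-cycle cohort simulations over a 40-year horizon with age-band
    stratified herpes zoster incidence, postherpetic neuralgia and other
    complications, linearly waning vaccine efficacy, and societal-perspective
    costing. Reports incremental cost-effectiveness ratios, net monetary
    benefit and averted disease burden, with one-way (tornado) sensitivity
    analysis, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, two-dose compliance scenarios, and vaccine price
    threshold analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
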