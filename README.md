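# zostercea

A Markov cohort cost-effectiveness model for herpes zoster (shingles)
vaccination in adults aged 50 years and older, comparing three strategies:
no vaccination, one dose of live attenuated vaccine (ZVL), and two doses of
recombinant subunit vaccine (RZV). It is written for health economists and
epidemiologists evaluating zoster immunization policy — in particular for
settings like China, where both vaccines are sold out-of-pocket and the
willingness-to-pay threshold is set at one times GDP per capita.

## The model

A cohort enters Healthy at age 50, 60, 70 or 80 and cycles annually for 40
years through six states: Healthy, AcuteHZ, PHN (postherpetic neuralgia),
OtherComplication, HZResolved (exposed to recurrence), and Dead. Background
mortality q(a) at the attained age applies first each cycle; disease
transitions occur among survivors, e.g.

    P(Healthy -> AcuteHZ) = (1 - q(a)) * lambda_b(a) * (1 - VE(t))

where lambda_b(a) is the age-band zoster incidence and VE(t) the vaccine
efficacy t years after vaccination — a per-band *linear* waning curve fitted
through trial follow-up anchors and clamped to [0, 1]. Discounted (5%/year)
costs and QALYs accumulate from a societal perspective, and strategies are
compared by

    ICER = dCost / dQALY,    NMB = WTP * dQALY - dCost

with dominance classification, averted-burden percentages, an efficiency
frontier, one-way (tornado) sensitivity analysis, probabilistic sensitivity
analysis with cost-effectiveness acceptability curves, two-dose compliance
scenarios, and a ZVL price-threshold analysis. The methods vignette
(`vignettes/zoster-cea-model.Rmd`) describes every assumption.

## A worked example

```r
library(zostercea)

# Pure CEA arithmetic: published incremental results in, ICER out
compute_icer(108723, 31.72)$icer
#> 3427.6        # ~3428 USD/QALY, cost-effective at a WTP of 12,681

# Full model on the packaged base case
fit <- zoster_cea(default_parameters(), ages = 60)
fit
#> Herpes zoster vaccination cost-effectiveness analysis
#>   Strategies: NoVaccination, ZVL, RZV | WTP: 12,681 USD/QALY | ages: 60
#>  age      strategy cases phn_cases   cost qalys incr_cost incr_qalys   icer
#>   60 NoVaccination   211        58 121056 11943        NA         NA     NA
#>   60           ZVL   183        52 295459 11944    174403       1.12 155137
#>   60           RZV    77        23 949868 11946    828811       3.34 248400
```

Reading the table: per 1000 unvaccinated 60-year-olds the model expects 211
lifetime zoster episodes and 58 PHN cases, costing a discounted 121,056 USD
and yielding 11,943 discounted QALYs. A fully vaccinated RZV cohort averts
63% of episodes but pays both doses at the full per-dose list price
(2 x 453.55 USD + fees), so its incremental cost dwarfs the QALY gain and
the ICER (248,400 USD/QALY) sits far above the threshold. The epidemiology,
life table, disease costs and efficacy endpoints in `basecase.yaml` are
clearly labelled placeholders — replace them with your own source data
(`load_parameters()`, dotted-path overrides, CSV import) for a substantive
analysis; the vignette explains why published vaccine-favourable ICERs at
these list prices additionally imply coverage-weighted course pricing.

Sensitivity analyses follow the same pattern:

```r
p <- default_parameters()
one_way_tornado(p, "RZV", start_age = 60)      # top-6 tornado entries
psa <- run_psa(p, start_age = 60, n_draws = 1000, seed = 1)
psa_preference(psa, wtp = 12681)               # P(each strategy preferred)
compliance_scenario(p, ages = 60)              # 20-100% two-dose completion
```

A thin command-line wrapper is installed at
`inst/scripts/zoster-cea` (`zoster-cea basecase --config basecase.yaml
--ages 50,60,70,80 --out results/`).

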