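---
title: "The zoster vaccination cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The zoster vaccination cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zostercea)
```

## The decision problem

Herpes zoster (HZ, shingles) is a reactivation of latent varicella-zoster
virus whose burden — acute pain, postherpetic neuralgia (PHN), ocular and
neurological complications — concentrates in older adults. Two vaccines are
available to Chinese adults: a two-dose recombinant subunit vaccine (RZV)
with high but slowly waning efficacy, and a cheaper one-dose live attenuated
vaccine (ZVL) with lower efficacy that wanes within about a decade.
`zostercea` implements the standard decision-analytic machinery for choosing
between *no vaccination*, *ZVL* and *RZV* for cohorts entering at ages 50,
60, 70 and 80, from a societal perspective.

## Model structure

A Markov cohort model with annual cycles over a 40-year horizon tracks six
health states:

* **Healthy** — never had HZ (or fully susceptible);
* **AcuteHZ** — an incident zoster episode (one-cycle dwell);
* **PHN** — postherpetic neuralgia following an episode;
* **OtherComplication** — ocular/neurological/other complications;
* **HZResolved** — recovered; exposed to recurrence;
* **Dead** — absorbing.

Transitions are rebuilt every cycle at the cohort's *attained* age: all-cause
mortality comes from a single-year-of-age life table, and all HZ inputs
(incidence, conditional PHN and complication probabilities, case fatality)
from four attained-age bands (50–59, 60–69, 70–79, 80+), so a cohort
entering at 50 uses 60–69 inputs after ten cycles.

Competing risks are composed multiplicatively: background mortality
\(q(a)\) applies first, disease transitions occur among survivors. The
Healthy row, for example, is

\[
P(\text{Healthy}\to\text{AcuteHZ}) = (1-q)\,\lambda_b\,(1-VE(t)), \qquad
P(\text{Healthy}\to\text{Dead}) = q,
\]

with \(\lambda_b\) the band incidence and \(VE(t)\) the strategy's efficacy
\(t\) years after vaccination. Zoster-attributable death applies only during
AcuteHZ through the per-episode case fatality. Rows sum to one by
construction (asserted to \(10^{-12}\) in tests). Recurrence re-enters
AcuteHZ from HZResolved at an annual probability, also scaled by
\(1-VE(t)\).

## Vaccine efficacy waning

Protection is a per-vaccine, per-entry-age-band *linear* function of years
since vaccination, fitted by ordinary least squares through published trial
follow-up anchors and clamped to \([0,1]\) on evaluation — so beyond the
anchored follow-up the line extrapolates until it reaches zero and is held
there (no rebound). With partial two-dose compliance \(c\), the cohort-level
RZV efficacy is the mixture \(c\,VE_2(t) + (1-c)\,VE_1(t)\); the one-dose
curve \(VE_1\) is not identified by the anchor data and defaults to the
two-dose curve scaled by `efficacy.rzv_one_dose_factor = 0.9` — a prominent
assumption the user should override when one-dose evidence is available,
because compliance-scenario conclusions depend on it. Protection acts on
incidence only; PHN protection arises by preventing episodes (an optional
per-vaccine multiplier on \(P(\text{PHN}\mid\text{HZ})\) exists for
breakthrough cases, default 1).

## Costs, QALYs and accounting conventions

Costing is societal: per-episode direct medical, direct non-medical and
indirect (productivity) costs, plus per-cycle PHN and complication costs.
All amounts are 2023 USD internally; configs may declare `currency: CNY` and
are converted once at load (7.0467 CNY/USD). Vaccination is charged entirely
at cycle 0 — two RZV doses weighted by compliance (non-completers pay one),
one ZVL dose, each with a 4.24 USD administration fee.

The trace stores occupancy for cycles \(0..H\) and streams of the same
length: disease costs attach to the cycles in which AcuteHZ/PHN/complication
states are occupied; QALYs accrue for cycles \(0..H-1\) (40 years lived) as
occupancy-weighted utilities. Disease-state utilities (0.85 acute HZ, 0.74
PHN) are *capped at the attained-age background utility*: an absolute
disease utility can exceed an elderly background utility, and without the
cap preventing disease could spuriously lose QALYs. Costs and QALYs are
discounted at 5%/year (\(1/(1+r)^t\)); episode and PHN counts are reported
undiscounted. No half-cycle correction is applied by default
(`model.half_cycle_correction` enables it); dwell times for PHN and
complications default to one cycle with configurable per-cycle exit
probabilities for chronic pain scenarios. Everything is reported per 1000
cohort members; the engine itself runs a unit cohort, so the scaling is
exact.

## Decision metrics

For each vaccine versus no vaccination the package reports incremental cost
\(\Delta C\), incremental QALYs \(\Delta E\), the ICER
\(\Delta C/\Delta E\) with dominance markers for the off quadrants, net
monetary benefit \(\mathrm{NMB} = \lambda\,\Delta E - \Delta C\) at the
willingness-to-pay \(\lambda\) (12,681 USD/QALY, one times GDP per capita),
and averted-burden percentages. A full efficiency frontier (strict and
extended dominance, sequential ICERs) is also computed; its survivors are
tested against an exhaustive NMB-argmax oracle. Reported tables round ICERs
and percentages to integers with ties away from zero, costs to the USD,
QALYs to two decimals; unrounded values are retained.

## Sensitivity machinery

* **One-way (tornado)**: each `owsa_spec` parameter is set to its lower and
  upper bound with everything else at base; entries sort by the absolute
  ICER range. The top six are reported by default.
* **PSA**: each `psa_spec` target is drawn from its distribution — beta for
  probabilities/utilities/efficacy anchors, gamma for costs, uniform between
  one-way bounds, `point` for no uncertainty — with hyperparameters
  moment-matched from (base, low, high), treating \((high-low)/(2\times
  1.96)\) as a standard error. Draws are taken in sorted target-path order
  from a single seeded stream, so runs are bit-reproducible; all three
  strategies share each draw (common random numbers). Sets violating a
  cross-parameter invariant are redrawn wholesale (max 1000 tries) rather
  than clipped, to avoid mass at the bounds. The CEAC reports, at each
  willingness-to-pay on a grid (0 to 3\(\lambda\) in 101 steps), the share
  of draws in which each strategy attains the maximal NMB; ties go to the
  earlier strategy in the order none/ZVL/RZV.
* **Compliance scenarios**: the two-dose completion rate sweeps 20–100%;
  dose costs follow compliance.
* **ZVL price threshold**: NMB is affine in the ZVL dose price (charged
  once, undiscounted, at cycle 0), so the price equalizing ZVL's and RZV's
  NMB is solved in closed form from two model evaluations; a bisection root
  (`uniroot`, tolerance \(10^{-9}\)) confirms it to \(10^{-6}\) in tests.
  The contract requires RZV to carry the higher NMB at the base price; when
  no nonnegative price achieves the crossing, a "not achievable by price
  alone" marker is returned instead of a number.

## The packaged base case, and what it can and cannot show

`basecase.yaml` ships the published *point values* — vaccine prices (453.55
and 194.28 USD per dose), administration cost, acute-HZ/PHN utilities,
discount rate, horizon, willingness-to-pay, 30% coverage, and initial
efficacy anchors (RZV 96.6/97.4/91.3/89.1%; ZVL 62.7/64.4/18.6/18.6% by
band) — together with clearly labelled, literature-plausible *placeholders*
for everything a full input appendix would supply: band incidence
(6.0–10.0 per 1000 person-years, rising with age), conditional PHN
probability (0.14–0.36), complication probability, case fatality, a
Gompertz-type life table (\(q(50)=0.003\), doubling every 8 years), a
linearly declining background utility (0.90 at 50), disease costs, ten/
eleven-year efficacy endpoints, and ±20–25% sensitivity ranges. Replace
them with real source data for a substantive analysis.

Two structural choices matter when comparing output against published
cost-effectiveness tables:

1. **The vaccinated strategies model a fully vaccinated cohort.** The
   `economics.coverage` field (0.30) is carried as an optional
   population-scaling knob and is *not* blended into the per-1000 results;
   mixing covered and uncovered fractions inside one arm would make case
   reductions uninterpretable.
2. **Both RZV doses are costed in full at the printed per-dose price.** At
   907.10 USD per person plus fees, the incremental cost of RZV against no
   vaccination is on the order of 900k USD per 1000, so the base-case ICERs
   of a fully costed, fully vaccinated cohort sit far above the 12,681
   USD/QALY threshold for any plausible per-case QALY loss (of order
   0.02–0.05 per episode and 0.1–0.3 per PHN case). Published analyses that
   report vaccine-favourable ICERs at these list prices implicitly spread
   vaccine spending over partial coverage or price the full course rather
   than each dose; reproducing such tables therefore requires the analyst's
   complete input set, not just the printed point values. The package
   documents this rather than silently adopting either accounting.

Consequently the probabilistic analysis on the *placeholder* base case
prefers no vaccination at the 12,681 threshold; the acceptance suite keeps
the published-direction check in place and reports it as failing, which is
the honest outcome under this cost accounting.

## The synthetic-parameter generator

`make_synthetic_parameters()` emulates the statistical shape PSA assumes:
probabilities and utilities on \([0,1]\), positive right-skewed costs
(lognormal jitter), incidence and case fatality monotone in age band,
waning efficacy anchors, and a geometric life table. It does *not* emulate
correlation between inputs, secular incidence trends, sex-specific
utilities, or reporting artefacts of real surveillance data — so passing
property tests demonstrates engine correctness, not epidemiological realism.

## Numerical choices and problem sizes

Occupancy conservation is asserted to \(10^{-10}\) per cycle; the engine is
validated against an exhaustive path-enumeration oracle (all \(6^H\) state
sequences) to \(10^{-12}\) on horizons up to 4. Degenerate inputs are
handled explicitly: certain death collapses every row onto Dead, full
protection zeroes breakthrough incidence, an acute-phase split exceeding
probability one raises a named parameter error, and zero incremental QALYs
yield an `undefined` ICER marker rather than a division. The test-suite
and the bundled reproduction script use deliberately scaled problem sizes —
shortened horizons for oracle tests and a 1000-draw PSA — chosen so the
whole suite runs comfortably on a laptop while leaving Monte-Carlo error
far smaller than the decision margins involved.

## Known limitations

No herd immunity or transmission dynamics; no individual-level waning
heterogeneity; no revaccination or booster dosing; reactogenicity is not a
state (an optional one-off disutility/cost hook exists, default zero);
parameter correlations are not modelled in the PSA; and the placeholder
inputs are stand-ins, not estimates.
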