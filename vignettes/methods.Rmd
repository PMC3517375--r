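---
title: "Methods: trial-based cost-effectiveness analysis in netcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis in netcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcea)
```

`netcea` evaluates the incremental cost effectiveness of therapist-guided
Internet therapy (IT) against Internet self-help (IS) for harmful alcohol
use alongside a two-arm randomized trial: 68 participants per arm, outcomes
at baseline and 6 months, societal costing in 2010 euros. This vignette is
the package's own account of the models, parameters and numerical choices;
the README shows the user-facing workflow.

## Costing model

All costs accrue over the 0.5-year horizon and are expressed in euros of the
2010 reference year; historical amounts can be indexed with
`index_to_reference_year()` via HICP factors (a small bundled 2004-2010
table of stub values that users should override with exact historical
factors where available).

**Intervention costs.** IT therapist time is costed per chat session: 40
minutes of contact plus 10 minutes of supervision and administration, at
EUR 79.20 per hour. Fixed software-development, ICT-service and overhead
components (IT: 23.25 + 14.92 + 4.27; IS: 4.87 + 2.49 + 4.27 euros) are
charged to every randomized participant regardless of uptake, reflecting
intention-to-treat and the per-participant divisors used in the underlying
cost records. With the average IT uptake of 2.49 contact plus 0.55
administration hours this reconstructs EUR 283.21 per IT participant and
EUR 11.63 per IS participant. Note the printed mean administration time
(0.55 h) is not exactly 10 min x mean sessions; per-participant computation
from uptake is primary in this package, and the printed means serve as a
fixture for the arithmetic checks.

**Participant time** is valued as leisure time at EUR 9.18/h, on the
assumption that therapy happens outside office hours.

**Productivity costs** follow the human-capital approach. SF-HLQ
absenteeism and presenteeism hours are reported over a 2-week recall window
and extrapolated linearly to the horizon with factor
`horizon x 52 / recall_weeks` = 26/2 = 13 (the source analysis says
"extrapolated" without printing the factor; linearity is the natural
reading and the factor is configurable through `horizon`/`recall_weeks`).
Hours are valued at sex- and age-band gross wages (bundled 10-year-band
table bounded by the published range EUR 22.21-52.91/h; the table is config
data, not code) and multiplied by the labour-reserve elasticity 0.8.
Whether the elasticity also applies to presenteeism is not stated in the
source; the package applies it uniformly by default (conservative and
symmetric) and exposes `elasticity_absenteeism` / `elasticity_presenteeism`
switches. Participants without paid employment incur no productivity cost.

**Additional societal costs** (health-care resource use beyond the
intervention, law enforcement) are imputed from productivity costs by
global-burden cost shares: productivity accounts for 72.1% of overall
alcohol-attributable societal costs, additional health care for 12.8% and
law enforcement for 3.5%, giving the fixed ratio
`(0.128 + 0.035) / 0.721 = 0.2261`.

The societal total is the sum of these four blocks; the health-care
provider perspective keeps intervention costs only. Baseline-period costs
are computed for descriptive reporting, but the incremental analysis uses
follow-up costs alone, randomization having balanced the arms at baseline.

## Effect measures

**Composite treatment response**: last-7-day consumption within 14 standard
units for women or 21 for men — the boundary is inclusive ("no more than") —
and no deterioration of *more than* 10% relative to baseline on AUDIT or
BSI-GSI (higher is worse) or QOLS (higher is better); exactly 10% does not
preclude response. A zero baseline score makes any worsening count as
deterioration beyond the threshold (documented convention). Missing inputs
yield `NA`, never a silent non-response: imputation resolves them upstream.

**QALYs** use EQ-5D-3L states valued by the Dolan MVH-A1 UK tariff
(`dolan_tariff()`, shipped as a plain-text CSV so other national tariffs can
be substituted): utility = 1 minus 0.081 if any dimension is above level 1,
minus per-dimension decrements, minus 0.269 if any dimension is at level 3;
full health values at 1 and the worst state at -0.594. QALY accrual follows
the trial's endpoint arithmetic — follow-up utility times the 0.5-year
horizon, so the between-arm gain is the mean utility difference times 0.5
(e.g. 0.12 x 0.5 = 0.06) — rather than trapezoidal area under the curve; an
AUC option exists (`qaly(method = "auc")`) but is off by default because the
endpoint convention is what the evaluated analysis fixes. Note the arm
utilities print as 0.89 and 0.78 while the reported increment 0.12 is the
bootstrapped median difference; the package reports both the plain
difference and the bootstrapped median, labelled distinctly.

## Missing data

Missing follow-up observations are multiply imputed m = 5 times under a
joint multivariate-normal model over all numeric variables (no explicit
covariate list), by the bootstrap-EM scheme: for each imputation the rows
are resampled, EM fits the mean and covariance on the resample, and the
original missing cells are drawn from their conditional normal given the
observed values. Results pool by Rubin's rules for means
(`pool_means()`: total variance = within + (1 + 1/m) between) and by
appending draws for medians and curves (`pool_by_appending()`).

Numerical choices: EM convergence is declared when the relative
log-likelihood change falls below 1e-6 (configurable), with a 500-iteration
cap and a diagnostic error carrying the likelihood trace on
non-convergence; a ridge of 1e-4 times the mean diagonal stabilizes the
covariance; variables are standardized internally; binary fields are
imputed on the latent continuous scale and thresholded at 0.5; bounded
fields are clamped after the draw (hours to [0, 112], AUDIT to [0, 40],
QOLS to [16, 112], BSI-GSI to [0, 4], utilities to [-0.594, 1]). Costs are
never imputed as euro totals: hours and uptake are imputed and then
re-costed deterministically, so the cost identities hold exactly in every
completed dataset. One master seed spawns per-imputation streams, making
(m, seed) jointly determine the output.

Clamping bounded draws is a deliberate approximation: for variables piled
against a bound (utilities near 1, hours near 0) it induces a small
systematic shift in imputed means relative to the unbounded normal model.
The recovery tests therefore compare pooled means to pre-masking truth
within Monte-Carlo error rather than exactly; users needing strictly
unbiased bounded imputation should transform such variables first.

## Bootstrap, plane and acceptability curves

From each completed dataset, `bootstrap_cea()` draws B = 1000 nonparametric
resamples, stratified by arm (each arm resampled with replacement at its own
size, independent streams per imputation), and records the between-arm
differences of within-arm means for every cost component and both effect
measures; the appended 5 x 1000 draws form the working distribution. The
ICER is DeltaC/DeltaE; a zero incremental effect raises an explicit
undefined-ICER condition rather than returning an infinity, and zero-effect
draws are excluded from ratio medians with a logged count. Because raw
ratio medians are ill-defined when draws span plane quadrants, both the
all-draw median (the literal convention of the evaluated analysis) and a
northeast-quadrant-restricted median are emitted, explicitly labelled.
Plane quadrant proportions assign boundary ties (a delta exactly zero, a
measure-zero event possible with discrete effects) to the positive side and
count them. Acceptability curves use the net-monetary-benefit formulation —
the probability that `WTP x DeltaE - DeltaC > 0` — which handles draws in
every quadrant and has the exact identities CEAC(0) = P(DeltaC < 0) and
CEAC(infinity) = P(DeltaE > 0); the default WTP grid runs from 0 to 80,000
euros in 500-euro steps, covering the usual responder (4000/8000/12,000)
and QALY (10,000/20,000/40,000) read-out points. `wtp_at_probability()`
returns the smallest grid WTP reaching a target probability (a bootstrap
CEAC is a step function), with optional interpolation. Percentile 2.5/97.5%
intervals of the appended ratios are the only interval type produced; no
Fieller or other parametric ICER intervals are attempted.

## Scenario analysis

A scenario is a perspective plus positive multipliers on the two dominant
cost drivers. The productivity multiplier is applied before the macro
cost-share ratio, so additional societal costs scale coherently with
productivity; participant time belongs to neither driver by default (a
`time_scale` knob exists). Scenarios are evaluated as algebraic
reweightings of the component-level deltas recorded per bootstrap draw, so
all scenarios share identical resampling: the identity scenario equals the
base case exactly, and scenario differences are purely scenario-driven
(common random numbers). The default set covers the provider perspective
and +/-40% as well as +/-60% driver adjustments.

## The synthetic trial generator

`generate_trial()` emulates the study conditions so every downstream stage
is testable without any external data: 68 participants per arm, 51% women,
age with mean 41.5 and SD 9.83 years (drawn from a scaled beta on [18, 65]
so the configured mean and SD are exact under the bounded support), AUDIT
around 19 (SD 5, integer-rounded, truncated to [0, 40]), weekly drinks with
mean 44 and SD 25 (lognormal with exactly those moments — positive and
right-skewed, as consumption data are), arm-wise employment rates 0.85/0.82,
EQ-5D baseline means 0.79/0.80 and follow-up means 0.89/0.78, response
probabilities 0.53/0.29, and roughly 40% follow-up attrition.

Design features worth knowing:

- **EQ-5D as states, not utilities.** Five dimensions are drawn
  independently with level-2/3 probabilities calibrated by closed-form
  expectation and root-finding so the arm's expected tariff utility equals
  the configured target; this exercises the tariff code path. A
  `eq5d_direct` switch draws utilities directly (truncated normal whose
  truncated mean is solved to equal the target) for unit tests of
  downstream stages.
- **Response is generated jointly with its components.** Responder status
  is drawn first at the configured probability; drinks and the three
  instrument scores are then drawn consistently with it (violations fall
  back to the drinking limit when score clamping could erase an instrument
  deterioration), so the composite definition applied downstream reproduces
  the configured rates by construction.
- **Productivity hours are zero-inflated lognormal.** Point-mass
  probabilities reproduce the trial's low reporter counts (absenteeism 8/68
  and 12/68 at baseline dropping to 5/68 and 2/68; presenteeism 21/68 and
  15/68 dropping to 7/68 and 5/68); severity is lognormal (sdlog 1, capped
  at 112 h per 2-week window, with the location solved so the capped mean is
  exact). Mean 2-week hours among reporters were back-calculated once from
  the published 6-month cost levels, the extrapolation factor 13, the
  cohort's expected wage and the employment rates, and are exposed in
  `default_hours_params()` rather than hard-coded. This reproduces cost
  data whose SDs far exceed their means.
- **Attrition is missing at random by construction.** A logistic model on
  standardized baseline AUDIT (coefficient 0.4, marginal rate 0.4) masks
  the entire 6-month assessment; masking happens after generation, so the
  underlying values are unchanged — the basis of the mask-then-impute
  recovery oracles. Interpreting the per-arm figures 41/68 and 39/68 as
  6-month completers (their ratio 1.05 being the reported relative
  attrition), the generator exposes the attrition rate as a parameter
  rather than fixing either reading.
- **Not generated**: the excluded waiting-list arm, the screening funnel,
  and 3-month interim assessments (the economic evaluation uses only
  baseline and 6 months). QOLS and BSI-GSI baseline distributions are not
  published; defaults (QOLS ~ N(75, 12) on 16-112, BSI-GSI ~ N(0.9, 0.5) on
  [0, 4]) are field-typical choices and only feed the 10% deterioration
  clause. Participant time investment is drawn as gamma (shape 2) around
  the published arm means 10.33/2.43 h, separate from chat uptake, because
  the published time investment is not exactly recoverable from session
  counts.

What passing tests on this generator do and do not show: they verify the
pipeline's arithmetic, invariances and statistical calibration under a
correctly specified, independently drawn cohort; they cannot certify
behaviour under real-data features the generator omits — correlated
outcomes and costs, informative missingness, digit preferences, or
clustered reporting.

## Problem sizes and test design

The test suite checks moment recovery at 20,000 participants per arm,
response-rate calibration pooled over 200 seeded trials of 68 per arm,
mask-then-impute recovery on single trials (within 4 pooled standard
errors) and across 20 replicates, bootstrap consistency at B = 10,000
against sample arm means, and mean-ICER recovery over 60 replicated trials
of a configuration whose incremental cost (845 euros) and response (0.24)
are fixed analytically, with a delta-method Monte-Carlo tolerance. These
sizes were chosen so each stochastic check has comfortably more resolution
than the property it verifies.

## Known limitations

- The multivariate-normal imputation model is misspecified for bounded and
  zero-inflated variables; clamping keeps completed datasets logically
  valid but slightly biases imputed means near bounds (see above).
- Ratio medians across quadrants remain a reporting convention, not a
  well-defined estimand; prefer the net-benefit CEAC for decisions.
- Incremental costs of a 68-per-arm trial with rare, large productivity
  reporters are heavy-tailed: single-trial stochastic summaries (median
  DeltaC, median ICER) vary widely across seeds even though their expected
  values are calibrated.
- No MNAR sensitivity analysis, no friction-cost valuation, no currency
  conversion, and no probabilistic sensitivity analysis over unit costs:
  scenario scaling is deterministic by design.
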