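---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trialcea` implements a within-trial economic evaluation comparing
nutritional counseling plus oral nutritional supplements (ONS) against
counseling alone in head-and-neck cancer patients undergoing
radiotherapy, and generalises the machinery so that each stage can be
reused and validated on synthetic data. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic generator does and does not emulate.

## Health outcomes: utilities and QALYs

Health-related quality of life enters as a utility weight in $[0, 1]$
per patient and visit, assessed at months 0 (baseline), 2 (end of
radiotherapy), 3 and 5. Where only EORTC QLQ-C30 scale scores are
available, `map_scores_to_utility()` applies a user-supplied published
mapping (`mapping_spec()`: intercept, named scale coefficients,
identity or inverse-logit link, clamped to $[0,1]$). The package ships
no mapping coefficients of its own because such mappings are estimated
on external datasets; the hook accepts any published set.

Missing utilities are handled in two layers:

1. **Rule-based dropout utilities** (`assign_dropout_utility()`).
   Patients who leave the utility assessment because of hospitalization
   or the need for artificial nutrition receive literature-based
   utilities at their unobserved visits: 0.35 at visits up to the end
   of radiotherapy and 0.30 afterwards. Both values are arguments, not
   constants. Decedents receive utility 0 from the death time to the
   end of the horizon. The source analysis computes QALYs for decedents
   without stating the terminal rule; zero-after-death is the standard
   QALY convention and is what we implement. Observed values are never
   overwritten.
2. **Chained multiple imputation** (`impute_chained()`) for the
   remaining missingness (loss to follow-up, withdrawal, sporadic
   single missing questionnaires). Each visit with missing values is
   regressed on the baseline covariates (age, gender, malnutrition at
   inclusion, tumor site and stage, handgrip strength, phase angle)
   plus the current completed utilities at the other visits, and
   missing entries are filled by predictive mean matching: a Bayesian
   draw of the regression parameters, then one of the `donors = 5`
   observed values with closest predicted mean. Defaults are $m = 20$
   imputations and 10 chained iterations; none of these constants is
   dictated by the source analysis, so we chose the values common in
   applied imputation practice. Because donors are observed utilities,
   imputations respect the $[0,1]$ bounds by construction. The chained
   sampler is implemented in the package (a dedicated imputation
   package is not among its dependencies); it follows the standard
   PMM-within-chained-equations recipe.

Per-patient QALYs are the trapezoidal ("interpolated") area under the
utility-versus-month curve divided by 12, giving years; over the
5-month schedule the ceiling is $5/12 \approx 0.417$. Downstream
analyses use the per-patient QALY averaged across imputations - a
deliberate simplification (the bootstrap resamples average QALYs rather
than re-imputing within each replicate), which understates
between-imputation variance slightly; `pool_rubin()` is provided for
proper Rubin pooling of scalar estimates. Utility profiles are compared
with a random-intercept linear mixed model
(`fit_random_intercept_lmm()`, REML, visit as a categorical factor)
whose arm-by-visit interaction is tested by a likelihood-ratio test
between maximum-likelihood fits; Satterthwaite small-sample corrections
are intentionally out of scope, the LRT being the supported test. With
exactly noise-free data the mixed model is degenerate and the function
falls back to the equivalent zero-variance OLS fit.

## Costs

Only direct medical costs from the payer perspective are counted.
`default_unit_costs()` carries the unit costs (euro) per resource
category - ONS bottles and delivery service, first/follow-up medical
visits, enteral and parenteral nutrition days, severe mucositis
episodes, hospital admissions - each with its price year. Older unit
costs (mucositis 2008, hospitalization 2004) can be brought to the
2017 target year through a user-supplied index series (`inflate()`:
`amount * index(to) / index(from)`); the source analysis names no index,
so the default is an identity index with a logged notice. Costing is
arm-agnostic: ONS prescribed to control-arm patients is priced at the
control ONS unit cost. Amounts are plain euro doubles; rounding to
cents happens only at display, so totals are exactly the sums of their
categories. `cost_table()` reports per-arm category means with Welch
t-tests (the pooled-variance variant is not offered; the source table
does not say which was used and unequal variances are the safer
default) and a stratified bootstrap percentile p-value
$2\min\{P(\Delta^* \le 0), P(\Delta^* \ge 0)\}$ for the heavy-tailed
total.

## Decision analysis

`bootstrap_pairs()` resamples patients with replacement *within* arm
(B = 1000 by default), preserving arm sizes, and records the
treatment-minus-control mean differences $(\Delta C, \Delta E)$. The
source text does not state whether its bootstrap was stratified;
stratification is the design choice here because it conditions on the
realised randomisation ratio. All decision-analytic outputs are pure
functions of this pair cloud:

- **ICER**: $\Delta C / \Delta E$ with a cost-effectiveness-plane
  quadrant label; the point estimate uses the original-sample means,
  not bootstrap means, and a zero effect difference yields an
  undefined-ratio flag rather than an error.
- **CEAC**: the fraction of pairs with positive incremental net
  benefit $k\Delta E - \Delta C$ over a willingness-to-pay grid
  (default 0-50,000 euro/QALY in steps of 100, a resolution chosen to
  keep the sweep cheap while resolving the curve).
- **EIB**: $k \cdot \overline{\Delta E} - \overline{\Delta C}$ with a
  percentile interval of per-pair net benefits.
- **EVPI** per patient:
  $\mathbb{E}[\max(0, INB)] - \max(0, \mathbb{E}[INB])$, the two-
  strategy form of the value of perfect information; it is zero
  exactly when all pairs favour the same decision.
- **Population EVPI**: the per-patient EVPI scaled by the yearly
  eligible population over a 10-year horizon at a 3.5% discount rate,
  discounting every year $t = 1, \dots, T$ (no undiscounted year 0);
  this convention reproduces the published headline figure where a
  year-0-undiscounted variant would not. The default eligible
  population is 60% of 9,300 yearly diagnoses = 5,580 radiotherapy
  candidates.

## Probabilistic sensitivity analysis

`fit_best_distribution()` fits normal, Gamma, Weibull and log-normal
families by maximum likelihood (via `fitdistrplus`) and selects by AIC,
breaking ties towards fewer parameters and then alphabetically. Two
numerical choices matter:

- Samples are fitted after division by their mean. A common scale
  factor shifts every family's log-likelihood by the same $-n\log s$,
  so the AIC ranking is unchanged while the optimiser works near unit
  scale; parameters and log-likelihoods are mapped back exactly.
- Exact zeros (patients who consumed nothing) are outside the support
  of the positive families, so zero-inflated samples are modelled as a
  point mass at zero plus a continuous positive part. The zero
  probability adds one parameter to *every* candidate's AIC so the
  comparison stays fair.

QALYs are bounded above and left-skewed, so the complement to the
ceiling $5/12$ is fitted instead (`transform_qaly_complement()`);
exact-zero complements are shifted by half the smallest positive
complement to keep likelihoods finite, and back-transformed samples
are clamped to $[0, 5/12]$. `sample_psa()` draws costs and effects
independently within arm - the source analysis describes no
correlation structure, and this independence is a documented
limitation, since it ignores any within-arm cost-effect dependence.

## Long-term survival

`km_fit()` is a self-contained product-limit estimator (events before
censorings at tied times, Greenwood variance) exposing the at-risk
table that the downstream statistics need; it is cross-checked in the
test suite against brute-force enumeration and against an independent
reference implementation. Follow-up is summarised by the reverse
Kaplan-Meier median (censoring treated as the event) with a
log(-log)-inverted confidence interval.

Restricted mean survival time (`rmst()`) integrates the step function
to the horizon $\tau$ and converts days to years at 365.25 days/year;
the variance is the integrated-Greenwood form
$\sum_i A_i^2 \, d_i / (n_i(n_i - d_i))$ with $A_i$ the residual area
from event time $i$ to $\tau$. Differences are tested with a normal
z-test. `discounted_lyg_icer()` builds the cost-per-life-year table:
the incremental area accrued during year $t$ is discounted by
$(1+r)^{-(t-1)}$ - the first year undiscounted, which is the convention
consistent with a first-year ratio computed directly from undiscounted
quantities - and the trial-period incremental cost is carried over
unchanged, under the stated assumption that post-trial costs are
arm-independent.

Non-proportional hazards are addressed with the Fleming-Harrington
family (`weighted_logrank()`): weights $S(t^-)^p (1-S(t^-))^q$ on the
pooled left-continuous Kaplan-Meier estimate, with the hypergeometric
variance. `maxcombo()` combines the log-rank $(0,0)$, early-emphasis
$(1,0)$ and late-emphasis $(0,2)$ statistics by taking the maximum
$|z|$, and obtains its reference p-value by permutation of arm labels
(default 10,000 permutations) rather than a Gaussian-copula
approximation: the permutation reference is assumption-free and
directly testable. The permutation loop exploits the fact that pooled
event counts, at-risk counts and weights are invariant under
relabelling, so each permutation costs two cumulative sums.

## The synthetic trial generator

`generate_trial()` emulates the data structure the analysis assumes,
with `true_values()` returning the analytic estimands so every stage
can be tested for parameter recovery:

- **Arms and schedule**: 78 treatment / 81 control patients, utility
  visits at months 0, 2, 3, 5, accrual uniform over July 2012 to April
  2016, administrative censoring on 2020-01-02.
- **Utilities**: per-visit arm means plus a patient-level random
  intercept (SD 0.18) and residual noise (SD 0.07), clamped to
  $[0,1]$. The source reports only QALY summaries (0.2911 +/- 0.0870
  vs 0.2883 +/- 0.0866), not per-visit means, so the default visit
  means (0.76, 0.66, 0.68, 0.73 and 0.753, 0.653, 0.673, 0.723) were
  chosen once as a dip-and-partial-recovery shape whose trapezoid
  reproduces those QALY means and difference; the variance split
  between intercept and residual is likewise a calibration choice.
  Because clamping truncates the normal model, `true_values()` uses
  the censored-normal closed form for the mean utility, keeping
  recovery tests exact.
- **Dropout**: death is derived from the survival model (so on-trial
  deaths and the long-term curves are mutually consistent - for this
  reason the death hazard is not a separate dropout parameter);
  hospitalization, artificial-nutrition and loss-to-follow-up dropout
  are competing exponential hazards per month, with defaults giving
  realistic single-digit counts per arm. The earliest cause within the
  window is recorded; a later in-window death after a non-death
  dropout keeps the earlier dropout label, a simplification that
  affects a negligible fraction of patients. A small MCAR rate
  (default 1.5%) emulates sporadic single missing questionnaires.
- **Costs**: zero-inflated Gamma resource counts per category,
  calibrated so per-category mean euro costs reproduce the published
  cost structure - near-equal totals (~988 vs ~996 euro) with the
  treatment arm dominated by ONS and the control arm by sparse, large
  parenteral-nutrition and hospitalization episodes, hence a much
  heavier right tail (low Gamma shapes, 0.5-0.8, in the control arm's
  heavy categories). Counts are continuous rather than integer, which
  keeps the configured means exactly recoverable.
- **Survival**: piecewise-exponential with one changepoint at day 365;
  arms share the early hazard (6.4e-4/day) and the treatment late
  hazard is roughly halved (2.9e-4/day), so early-weighted tests have
  little power while late-weighted tests do - the pattern the analysis
  is designed to detect - with medians near 1949 vs 1085 days.
- **Seeds**: one master seed with named substreams
  (`substream_seed()`) per stage, so a stage's draws do not depend on
  how many random numbers earlier stages consumed.

What the generator does *not* emulate: item-level EORTC QLQ-C30 scores
(synthesis happens at the utility scale), correlation between resource
categories within a patient (e.g. hospitalization dropout and
hospitalization cost are independent draws), informative censoring,
and covariate effects on utilities, costs or survival (covariates are
generated as plausible but inert imputation predictors). Passing
recovery tests on this generator therefore validates the estimators
under the stated generative assumptions, not the clinical realism of
any particular dataset.

## Problem sizes used in validation

The test suite exercises the estimators at sizes chosen to make
Monte-Carlo bands tight while keeping the default run quick: parameter
recovery of distribution selection at $n = 5000$; convergence of
empirical means to `true_values()` at 5,000 patients/arm; KM
consistency at 6,000; RMST closed-form checks at $n = 2000$; max-combo
null calibration over 500 replicates of 40 + 40 patients with 2,000
permutations each; and the end-to-end pipeline at the study's own 78 +
81. The acceptance script runs the full pipeline once at study size
with B = 1000 bootstrap replicates, m = 20 imputations and 10,000
permutations.

## Known limitations

- The bootstrap operates on imputation-averaged QALYs (see above).
- PSA costs and effects are independent within arm.
- No EVPPI/EVSI, no more-than-two-strategy comparisons, no
  covariate-adjusted survival models, no societal costs - all outside
  the scope of the analysis this package implements.
- The discrete WTP grid resolves the CEAC to 100 euro/QALY; exact
  pair-specific breakpoints between grid points are not reported.
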