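---
title: "Results-adjusted lung cancer risk prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Results-adjusted lung cancer risk prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungscreenrisk)
```

## The problem

Risk models such as PLCOm2012 select ever-smokers for annual low-dose CT
screening, but once someone is *in* a screening program, their accumulated
screening results are themselves informative: three consecutive negative
Lung-RADS results mark a substantially lower-risk person than the baseline
model suggests, while repeated positives mark a much higher-risk one. This
package implements a model that updates a baseline risk estimate with the
results of the three annual screens, and turns the update into an explicit
rule for deciding whether the next annual screen can be omitted.

## The model and its assumptions

Screens are dichotomized on the Lung-RADS scale (1–2 negative; 3, 4A, 4B,
4X positive) and the eight possible three-screen histories are collapsed
into four groups by number and recency of positives: all negative; one
positive with the last negative; two positives with last negative or only
the last positive; and at least two positives with the last one positive.
The collapse assumes patterns within a group carry similar risk — the
8-level and 4-level models performed near-identically in development,
which is what justifies it.

For a 6-year base risk $q$, the model predicts 3-year risk

$$\mathrm{logit}(\pi) = \beta_0 + \beta_{g} +
  \beta_{fp}\left[(q/2)^{-0.5} - c\right]$$

with the all-negative group as reference ($\beta_1 = 0$). Key assumptions
and consequences:

* **Scale conversion by halving.** The 6-year base risk is divided by two
  to match the 3-year follow-up window, not converted via
  $1-(1-q)^{1/2}$. The fitted coefficients assume the halving, so
  substituting the "more correct" conversion would *mis*-calibrate the
  model. The output is symmetrically reported as a 6-year-equivalent,
  $\min(1, 2\pi)$.
* **The power $-0.5$** comes from fractional-polynomial selection during
  development and makes the transformed risk decreasing; combined with the
  negative $\beta_{fp}$, predicted risk is strictly increasing in base
  risk. The transform is undefined at zero, so base risks of exactly 0
  (and 1) are rejected rather than clamped.
* **The centering constant** $c = 7.045149954$ is a development-dataset
  constant (the mean of the transformed predictor). It only shifts the
  intercept; it is carried so the printed intercept reproduces exactly.
* **Known overestimation region.** External validation showed
  overestimation above roughly 12% predicted 3-year risk. Predictions
  beyond it trigger a warning, not a correction — the region is far above
  any screening-eligibility threshold.

## Ceiling probabilities and the screening decision

For an eligibility threshold $t$ (on the 6-year scale), the *ceiling
probability* is the smallest base risk $q$ whose all-negative prediction
still satisfies $2\pi \ge t$. Because the all-negative equation is
strictly monotone in $q$, the inverse is closed-form:

$$q = 2\left[\frac{\mathrm{logit}(t/2) - \beta_0}{\beta_{fp}} + c\right]^{-2}$$

`ceiling_probability()` uses this inversion and falls back to bracketed
root finding (relative tolerance $10^{-10}$) for coefficient sets without
an analytic inverse (e.g. a log transform). The model's all-negative
predictions are bounded above (about 10% 6-year-equivalent under the
published coefficients), so sufficiently large thresholds are *unreachable*
and fail explicitly rather than returning a boundary value.

The decision rule in `eligibility_decision()` is deliberately conservative:
any positive screen means "continue annual screening"; among all-negative
histories, only those with base risk below the ceiling are flagged as
candidates for omitting the next screen. Ties at the ceiling count as
reached.

An open question in the source material is whether the published ceilings
were derived from baseline or baseline-updated risks; direct inversion of
the printed coefficients reproduces both published values (2.6% and 3.4%)
to their printed precision, so that is what is implemented.

## Baseline updating

Age, smoking duration (current smokers) and quit time (former smokers) are
advanced by the elapsed time between the baseline questionnaire and the
start of follow-up (3 years here). Status changes in the interim are not
modelled: sensitivity analyses with updated smoking data did not improve
prediction, and modelling them would require transition assumptions the
data do not support. The update is additive, so updating by $a$ then $b$
equals updating by $a+b$ — a property the tests exercise.

The base model itself (PLCOm2012) is *data, not code*: its coefficients
are distributed with the original publication and are consumed here
through a declarative JSON spec (`base_model_spec()`) with a small
transform vocabulary (identity, power with 0 = log, indicator, each with
optional centering). The shipped `base_model_synthetic.json` is a clearly
labelled synthetic stand-in used for schema demonstrations and tests.

## Fractional-polynomial fitting

`select_fp()` reproduces the development procedure for one continuous
predictor: each candidate power in $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$
(0 = log) is fitted by maximum likelihood, and the Royston–Altman closed
test is applied at $\alpha = 0.05$: best FP vs the model omitting the
predictor (2 df per degree), then best FP vs linear (1 df). Degree 1 is
the default — the published model uses a single power — with degree-2
pairs supported. Deviance ties break toward the linear model. The
selection $\alpha$ was not stated in the source; 0.05 follows the cited
methodology and is configurable.

Numerical choices: IRLS convergence is a relative deviance change below
$10^{-8}$ with at most 100 iterations; constant non-intercept columns are
rejected; complete separation (every case outranking every control with a
diverging linear predictor) fails loudly, since no finite MLE exists.
Centering uses the sample mean of the transformed predictor and only
shifts the intercept, so it is applied algebraically after the fit rather
than by refitting — fitted probabilities are unchanged, which the tests
assert.

## Validation metrics

* **Brier score**: mean squared error of predictions; 0.25 corresponds to
  an uninformative 0.5 prediction.
* **AUC**: the Mann–Whitney form computed from ranks, with ties counted
  one half; a brute-force pair enumeration serves as the testing oracle.
* **Spiegelhalter z**: standardized sum of $(y-p)(1-2p)$; undefined when
  every prediction is 0.5 (zero variance), which is rejected.
* **Calibration-error percentiles**: the observed outcome is smoothed
  against the prediction by local linear regression (loess, span 0.75,
  degree 1) and the 50th/90th percentiles of
  $|\hat{y}_{smooth} - p|$ are reported. The exact smoother behind the
  published percentiles is not specified in the source; loess with these
  settings is this package's documented choice, and a minimum event count
  (default 10) guards against vacuous smooths.
* **Bootstrap CIs**: "bias-corrected percentile" is read as BC, not BCa —
  acceleration is omitted, matching the phrase. Resamples draw records
  with replacement; a statistic that fails on a resample (e.g. a
  single-class AUC draw) causes a logged redraw with a bounded retry
  budget. A fixed seed makes intervals bit-for-bit reproducible, and the
  caller's RNG state is restored afterwards.
* **Net benefit**: $TP/n - (FP/n)\,t/(1-t)$ with treat-all and treat-none
  references; thresholds of 1 are rejected (undefined odds). Ties at a
  threshold classify positive, consistent with "risk of at least $t$".
* **Rates and proportions**: person-time rates use the exact Poisson
  (chi-square) interval by default — it reproduces published rate CIs to
  the printed integer, where the log-scale test-based interval differs by
  ~2 per 100 000 in the lower bound — with the test-based interval
  available as an option. Proportions use the Wilson score interval.

## Competing-risks cumulative incidence

Deaths from causes other than lung cancer preclude observing a lung cancer
event and are treated as competing events, not censorings: the cumulative
incidence function is the Aalen–Johansen estimator (via the survival
package's multi-state machinery), which reduces to $1 - KM$ when no
competing events occur. Follow-up is truncated at the horizon (3 years by
default); events recorded later are censored at the horizon. Ties at a
time point process events before censorings. Subdistribution-hazard
*regression* is out of scope — only the nonparametric estimate is needed
here.

## The synthetic cohort

`generate_cohort()` states one synthetic world and keeps it fixed:

* base 6-year risks are log-normal with median 1.5% — the canonical
  screening-eligibility threshold, putting half the cohort on each side of
  the decision boundary — and `sdlog` 0.8, a spread wide enough to span
  the 0.1%–30% truncation range without piling mass at the bounds;
* screening groups are drawn with the development-set frequencies
  80.7/13.4/4.1/1.8%, and 8-level patterns within groups follow the
  development-set proportions (1565:463, 125:496, 147:91:42);
* outcomes are Bernoulli draws from the model's own predictions, so the
  cohort is calibrated by construction;
* competing death is a constant 0.0112/year hazard, matching the reported
  ~735 deaths per 22 229 over three years; survivors are censored
  administratively at the horizon.

Group assignment is independent of base risk by default. In real cohorts
the two are mildly positively associated (adjustment attenuated the group
odds ratios), and a `group_risk_cor` knob exists to tilt group odds with
base risk, but no value is claimed as realistic. The binary `outcome`
column deliberately ignores competing-death preemption — it is the
logistic-regression target under the complete-follow-up design — while the
`time`/`event_type` columns give the survival view in which deaths can
preempt cancers.

What a green test on this cohort does establish: the fitting machinery
recovers the generating transform and coefficients at realistic sample
sizes; the metrics behave correctly under known calibration and known
miscalibration; the decision rules are internally consistent. What it does
not establish: real-data discrimination or calibration (the published
AUCs of 0.77/0.76 depend on the real joint distribution of risk factors
and screening results, which is not emulated), demographic structure, or
any joint dependence of base risk and screening results.

## Known limitations

* The model predicts incidence, not mortality, and contains no
  nodule-level features.
* The synthetic cohort's event rate (~0.7%) is below the real cohort's
  1.3% because the stated base-risk median of 1.5% sits below the real
  screened population's; this affects power in recovery tests, not
  correctness.
* Non-integer baseline-update intervals are accepted (the update is
  additive) but only the 3-year value has any empirical backing.
* The calibration-error percentiles depend on the chosen smoother; values
  are comparable within this package, not with other implementations.
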