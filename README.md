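# lungscreenrisk

Risk-based decision support for lung cancer screening: what does a person's
risk look like *after* three annual low-dose CT (LDCT) screens, and should
they be offered the next annual screen?

Annual LDCT screening of high-risk ever-smokers reduces lung cancer
mortality, but many screens are unproductive. Screening results themselves
carry prognostic information: consecutive negative Lung-RADS results lower
subsequent risk, while positive results raise it sharply. `lungscreenrisk`
implements a results-adjusted risk model (the PLCO2012results model) that
combines a PLCOm2012 6-year base risk with the dichotomized Lung-RADS
results of the three annual screens (T0/T1/T2), predicting lung cancer in
the following three years (T3–T6).

## The model

Screens are dichotomized (Lung-RADS 1–2 negative, 3/4A/4B/4X positive) and
the three-screen history is grouped:

| group | patterns (T0 T1 T2) | meaning |
|---|---|---|
| 1 | `− − −` | all negative |
| 2 | `+ − −`, `− + −` | one positive, last negative |
| 3 | `+ + −`, `− − +` | two positives last negative, or only the last positive |
| 4 | `+ − +`, `− + +`, `+ + +` | ≥2 positives with last positive |

With the 6-year base risk halved to the 3-year scale
(p = PLCOm2012/2), the predicted 3-year risk is

```
logit(risk) = β₀ + β_g + β_fp · (p^−0.5 − c)
```

with β₀ = −4.4353800, β_fp = −0.2713125, c = 7.045149954, and group log
odds ratios β₂ = 0.6554117, β₃ = 0.9798233, β₄ = 2.1940610 (odds ratios
1.93, 2.66, 8.97). Model output is reported on both the 3-year scale and a
6-year-equivalent scale (2 × 3-year risk).

The **ceiling probability** for an eligibility threshold t is the base risk
above which even three negative screens cannot drag the results-adjusted
6-year-equivalent risk below t — people at or above it should simply stay
on annual screening. The package solves it in closed form: 2.6% for a 1.5%
threshold, 3.4% for 2.0%.

Around this core the package provides the full development/validation
toolchain: fractional-polynomial logistic fitting with closed-test power
selection (`select_fp`), discrimination/calibration metrics with
bias-corrected bootstrap CIs (`validation_report`), decision-curve net
benefit (`net_benefit`), person-time rates and competing-risks cumulative
incidence (`incidence_rate`, `cumulative_incidence`), and a synthetic
NLST-like cohort generator (`generate_cohort`) so everything is testable
without trial data.

## Worked example

A person with a PLCOm2012 6-year risk of 3% whose screens were `+ − +`
(group 4):

```r
library(lungscreenrisk)
predict_results_risk(0.03, group_history("+", "-", "+"))
#>        base_risk_6yr base_risk_3yr group   risk_3yr risk_6yr_equivalent
#> group4          0.03         0.015     4 0.07275373           0.1455075
```

Their screening results have quintupled the 6-year-equivalent risk estimate
to about 15% — clearly continue annual screening. The decision rule with
the ceiling probabilities:

```r
ceiling_probability(c(0.015, 0.020))
#> [1] 0.02640203 0.03431904
eligibility_decision(c(0.030, 0.016), "-", "-", "-", threshold_6yr = 0.015)
#> [1] continue_annual    consider_omit_next
```

At a 1.5% eligibility threshold, an all-negative screener with 3% base risk
is above the 2.64% ceiling and continues; one at 1.6% has dropped below the
threshold after three negative screens and may consider omitting the next
screen.

Validating the model on a synthetic cohort generated from it (so calibrated
by construction):

```r
coh <- generate_cohort(cohort_config(n = 20000), seed = 8)
validation_report(prediction_set(coh$risk_3yr, coh$outcome),
                  n_resamples = 200, seed = 8)
#> Model validation report
#>   n = 20000, events = 128 (0.64%)
#>   Brier score: 0.0063 (95% CI 0.0052-0.0073)
#>   ROC AUC:     0.803 (95% CI 0.768-0.835)
#>   Spiegelhalter z = -0.78, p = 0.44
#>   mean predicted / observed: 0.0069 / 0.0064
#>   50th, 90th percentile absolute error: 0.0005, 0.0010
```

The small Brier score reflects the rarity of events; the non-significant
Spiegelhalter statistic confirms the by-construction calibration; the AUC
shows the discrimination attainable in this synthetic world (real-cohort
discrimination depends on the real joint risk distribution).

## Command line

A thin CLI ships in `inst/exec/lungscreenrisk`:

```sh
Rscript inst/exec/lungscreenrisk ceiling --threshold 0.015
Rscript inst/exec/lungscreenrisk simulate --n 10000 --seed 1 --output cohort.csv
Rscript inst/exec/lungscreenrisk score --input cohort.csv --threshold 0.015 --output scored.csv
Rscript inst/exec/lungscreenrisk fit --input cohort.csv --output coef.json
Rscript inst/exec/lungscreenrisk validate --input cohort.csv --seed 2 --output report.csv
Rscript inst/exec/lungscreenrisk incidence --input cohort.csv --output cif.csv
```

`score` reads a delimited table with columns `id, plco6, s0, s1, s2`
(Lung-RADS categories or `+`/`−`; percent strings like `2.6%` are accepted)
and appends group, risks and the screening decision. Fitted coefficients
travel as JSON configs (`inst/extdata/plco2012results.json` carries the
published model).

## Acceptance script

`scripts/acceptance.R` recomputes, from the published coefficients alone,
the two ceiling probabilities (1.5% and 2.0% thresholds, as one-decimal
percents) and the group-4 worked example (nearest percent), writing them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
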