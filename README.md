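# ipfclaims

Comparative treatment-pattern and cost analysis for antifibrotic therapy in
idiopathic pulmonary fibrosis (IPF), built for administrative claims data.

Pirfenidone and nintedanib are the two approved antifibrotics for IPF.
Observational comparisons between them must be built from pharmacy and
medical claims: who starts which drug (a new-user design anchored on the
first antifibrotic fill), how long they stay on it, whether they take it as
prescribed, and what their care costs — with the two cohorts made comparable
by propensity-score weighting. `ipfclaims` implements that pipeline end to
end for analysts working with claims extracts, together with a synthetic
claims generator with known ground truth so every stage can be validated.

## The methods at its core

* **Adherence** — proportion of days covered over follow-up,
  `PDC = (covered days) / (follow-up days)`, truncated at 1.0, from
  days'-supply fields with overlap appending and a +7-day titration
  adjustment for first pirfenidone fills (unless the fill is the 207-pill /
  30-day titration pack). Adherent means PDC > 0.8 (configurable to ≥).
* **Persistence** — time from index to the earliest of discontinuation
  (first gap of ≥ 60 uncovered days, dated to the last covered day; a lung
  transplant before the gap completes cancels it), switch to the alternate
  antifibrotic, transplant, or end of follow-up. Re-initiation is the first
  index-drug fill after the gap completes (so its minimum is 61 days).
* **Weighting** — logistic propensity model on age group, sex, region,
  Charlson index without COPD codes, COPD, stroke, recent pneumonia and
  ILD-center care; ATE weights `1/p̂` and `1/(1-p̂)`; balance judged by
  standardized mean differences with the |SMD| ≤ 0.1 rule.
* **Outcomes** — IPTW-weighted logistic (odds of adherence), Cox with
  Kaplan–Meier curves (time to discontinuation/switch, Efron ties, robust
  variance), and gamma GLM with log link for per-patient-per-month and
  per-year costs in 2017 CPI-adjusted dollars, summarised by recycled
  prediction with percentile-bootstrap confidence intervals.

## Worked example

Simulate a cohort at the default study conditions (1455 patients, a COPD
confounder shifting treatment assignment and discontinuation, true
discontinuation hazard ratio 0.8, true cost ratio 0.85), then run the whole
pipeline:

```r
library(ipfclaims)
library(dplyr)

tabs <- simulate_claims(claims_config(n_patients = 1455, seed = 2024))

analysis <- prepare_analysis(tabs) |> add_iptw()
analysis |> count(index_drug)
#>   index_drug      n
#> 1 nintedanib    650
#> 2 pirfenidone   805

balance <- balance_table(analysis, analysis$iptw)
max(abs(balance$smd_unweighted))   # 0.225  (COPD imbalanced before weighting)
attr(balance, "max_smd_weighted")  # 0.052  (balanced after: all |SMD| <= 0.1)

cox <- fit_weighted_cox(analysis, weights = analysis$iptw,
                        covariates = propensity_covariates())
glance(cox)
#>   estimand     estimate conf.low conf.high p.value     n
#> 1 hazard_ratio    0.831    0.731     0.945 0.00484  1455
```

The weighted hazard ratio 0.83 (95% CI 0.73–0.94) recovers the generator's
true value of 0.8: pirfenidone initiators stay on therapy longer. Costs
while persistent, adjusted by recycled prediction:

```r
med <- classify_claims(tabs$medical, type = "medical")
rx  <- classify_claims(tabs$pharmacy, type = "pharmacy")
win <- analysis |>
  transmute(patient_id, start = index_date,
            end = index_date + persistence_end)
costs <- aggregate_costs(med, rx, win)

d <- analysis |>
  left_join(costs |> select(patient_id, all_cause_pppm), by = "patient_id")
cost_fit <- fit_cost_glm(d, "all_cause_pppm", weights = d$iptw,
                         covariates = propensity_covariates())
recycled_prediction(cost_fit)
#>   arm         predicted_mean
#> 1 pirfenidone         11116.
#> 2 comparator          13385.
glance(cost_fit)$estimate   # 0.831 — adjusted monthly cost ratio (truth 0.85)
```

Adjusted mean all-cause costs are about $11,100 vs $13,400 per patient per
month, an adjusted ratio of 0.83 against the generator truth of 0.85.
`bootstrap_ci()` wraps any such statistic in a patient-level resampling loop
(weights re-estimated per replicate) for percentile confidence intervals,
and `autoplot()` draws the balance (love) plot and the weighted
Kaplan–Meier curves.

Real extracts enter the same way through `read_claims()` (CSV tables:
enrollment, pharmacy, medical) with study code sets supplied via
`default_code_config()` or a YAML file through `read_code_config()`.

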