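---
title: "Methods: adherence, persistence, weighting and cost models for antifibrotic claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adherence, persistence, weighting and cost models for antifibrotic claims cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfclaims)
library(dplyr)
```

## What the package does

`ipfclaims` implements a claims-based comparative study of the two approved
antifibrotic therapies for idiopathic pulmonary fibrosis (IPF), pirfenidone
and nintedanib, from raw administrative-claims tables to weighted effect
estimates:

1. **Cohort construction** — a new-user design: the index date is the first
   antifibrotic pharmacy claim; patients must be at least 40 at index, have
   12 months of continuous pre-index enrollment, carry an IPF diagnosis on a
   non-diagnostic claim, and have no competing interstitial lung disease
   diagnosis after index.
2. **Treatment patterns** — medication coverage timelines from days'-supply
   fields, proportion of days covered (PDC), 60-day-gap discontinuation,
   switching, persistence and re-initiation.
3. **Confounding control** — a logistic treatment-assignment model on eight
   baseline covariates, inverse-probability-of-treatment (IPTW) weights, and
   standardized-mean-difference balance diagnostics.
4. **Outcomes** — weighted logistic regression for adherence (odds ratio),
   weighted Cox regression with Kaplan–Meier curves for time to
   discontinuation or switch (hazard ratio), and gamma GLMs with a log link
   for costs, summarised by recycled prediction with bootstrap confidence
   intervals.

Because real commercial claims extracts are proprietary, the package ships a
synthetic claims generator with known ground truth; all validation is done
against that generator and against brute-force oracles.

## The episode algorithm in detail

**Day conventions.** All computations run on integer day offsets with the
index date at 0. A fill on day $d$ with adjusted supply $s$ covers days
$[d, d+s-1]$ inclusive; window lengths count both endpoints. These
conventions make the minimum observable time from discontinuation to
re-initiation exactly 61 days: coverage through day 29, a 60-day gap over
days 30–89, and the earliest post-gap fill on day 90.

**Titration adjustment.** Pirfenidone is up-titrated over the first two
weeks. A first pirfenidone fill therefore stretches beyond its nominal
days'-supply, and 7 days are added to it — unless the fill is the dedicated
titration pack (207 pills for 30 days), which is dispensed exactly as
labelled. Nintedanib fills are never adjusted.

**Overlap appending.** An early refill's supply is appended after current
coverage rather than discarded, so no dispensed supply is lost. The
implementation uses the closed form
$e_k = D_k + \max_{j \le k}(s_j - D_{j-1}) - 1$ for the coverage end after
fill $k$ (with $D_k$ the cumulative supply), which a property-style test
checks against a literal day-by-day pill-bank simulation on 1000 random fill
patterns.

**PDC.** Covered days inside the follow-up window divided by the window
length, truncated at 1.0. The adherence flag defaults to PDC **strictly
greater than** 0.8; both the strict and the non-strict convention circulate
in adherence research, so the comparison rule is a single explicit argument
(`adherence_rule = "gt"` or `"ge"`) rather than a hidden constant.

**Discontinuation.** The first run of at least 60 uncovered days — strictly
between covered intervals, or trailing from the end of coverage to the end
of follow-up — marks discontinuation, dated to the last covered day before
the run. Only uncovered days observed during follow-up can complete the run:
a gap whose 60th uncovered day falls after the follow-up end does not count.
A lung transplant before the run's 60th uncovered day
(`transplant < discontinuation + 60`) cancels the discontinuation, since
stopping therapy for a transplant is not treatment abandonment.

**Persistence and tie-breaking.** Persistence ends at the earliest of
discontinuation, transplant, switch, or end of follow-up. On same-day ties
the priority is transplant > switch > discontinuation: the first two are
directly observed events, discontinuation is inferred. Same-day duplicate
fills of the index drug are summed into one fill.

**Re-initiation.** The first index-drug fill strictly after
`discontinuation + 60`; its distance from the discontinuation date is
therefore at least 61 days by construction.

**Composite event time.** For the Cox endpoint, the event is the earlier of
discontinuation and switch; censoring is at transplant or end of follow-up.
A switch that occurs after a completed discontinuation gap still counts as a
switch descriptively, but the composite event time is the minimum of the two
dates.

## Weighting choices

The assignment model is a maximum-likelihood logistic regression of
treatment on age group (40–44, 45–54, 55–64, 65–74, 75–79, 80+), sex,
region, the Charlson index excluding COPD codes (continuous), and the COPD,
stroke, recent-pneumonia and ILD-center flags. Weights follow the **ATE
convention** (`1/p` for the treated arm, `1/(1-p)` for the comparator),
unstabilized and untruncated by default — the plainest reading of "inverse
probability of treatment weights"; stabilization and percentile truncation
are deliberate options rather than silent defaults.
Scores numerically at 0 or 1 (separation) raise an error instead of
producing infinite weights.

Balance is reported per covariate level as
$\mathrm{SMD} = (m_T - m_C)/\sqrt{(v_T + v_C)/2}$ with weighted means and
variances, binary terms using the proportion variance $p(1-p)$; the
conventional adequacy rule is max |SMD| ≤ 0.1 after weighting.

## Cost conventions

- **Classification.** A medical claim is respiratory-related when its
  *first-position* diagnosis matches the respiratory code set; a pharmacy
  claim when its drug is a respiratory therapy (antifibrotics,
  corticosteroids, pneumonia/ARI antibiotics, azathioprine,
  N-acetylcysteine, mycophenolate mofetil). Index-drug-related means an
  antifibrotic fill.
- **Normalization.** PPPM divides window totals by `window_days / 30.4375`
  (average Gregorian month); PPPY divides by `window_days / 365`. The PPPM
  window is the persistence period `[index, persistence_end]` inclusive; the
  PPPY window is the fixed 365-day post-index year.
- **Transplant admissions** are always excluded from inpatient counts.
  Their *dollars* are excluded too by default
  (`exclude_transplant_costs = TRUE`) — excluding the admission while
  keeping its cost is defensible too, so the choice is explicit and
  reversible.
- **Inflation.** All paid amounts are restated in 2017 dollars using the
  medical-care CPI as `amount * index(2017) / index(service_year)`; missing
  years are an error, never silently extrapolated.
- **Zero costs.** The gamma/log cost model requires strictly positive
  costs. Cohort members always have at least one index-drug fill, so
  analysis totals are structurally positive; degenerate inputs raise an
  error pointing at the zero-cost policy (drop rows or add a small offset
  upstream).

## Outcome models

All comparative models are weighted by IPTW and adjust for the same eight
covariates as the assignment model. The logistic and gamma models report
HC0 sandwich (weight-aware) standard errors; the Cox model uses Efron tie
handling with the robust variance that `survival::coxph()` produces for
weighted fits. Recycled prediction sets every patient's treatment to each
arm in turn, predicts on the response scale, and takes the weighted mean —
the covariate-standardized mean cost per arm. Bootstrap confidence
intervals (defaults: B = 1000, percentile, patient-level resampling)
re-estimate the weights inside every replicate so design uncertainty
propagates; replicates whose statistic fails are dropped and counted, and
more than 10% failures abort.

## The synthetic generator

The generator emulates a US commercial/Medicare-supplemental claims
extract: enrollment spans,
pharmacy claims, and medical claims for a two-arm cohort whose defaults
describe a realistic US antifibrotic study population — 1455 patients
indexing between October 2014 and mid-2017, baseline prevalences typical of
IPF cohorts (e.g. COPD 47.6%, female 31.3%, oxygen 59.7%), a COPD
confounder that shifts assignment log-odds by +0.5 and the discontinuation
hazard by +30%, a true discontinuation hazard ratio of 0.8 (drug A vs drug
B), and a true all-cause monthly cost ratio of 0.85 on a base of $11,000
(2017 dollars) with gamma shape 1.5.

Key mechanisms:

- **Assignment** is Bernoulli with logistic probabilities on the same
  design matrix the downstream propensity model uses, so coefficient
  recovery is well-posed and the stored propensity is the model truth.
- **Refills** have fixed 30-day supply with small integer jitter (a few
  days early or late, capped well below the 60-day gap). After each fill
  the patient stops with per-cycle probability
  $q_i = 1 - \exp(-30\,\lambda_i)$, where
  $\lambda_i = \lambda_0 \cdot \mathrm{HR}^{A_i} \cdot 1.3^{\mathrm{COPD}_i}$
  — the complementary log-log calibration that makes the proportional-
  hazards structure exact on the stopping process. The true stop day (last
  covered day) is stored in the ground truth and is recovered exactly by
  the episode algorithm on patients without transplant or re-initiation
  noise.
- **Costs** are gamma draws per 30-day month with log-linear arm and COPD
  effects; a configurable share (default 65%) rides on the index-drug fill
  and the remainder on medical claims (office visit with a respiratory
  primary diagnosis, a non-respiratory outpatient claim, stochastic ED
  visits and admissions). A final partial month accrues cost pro-rata —
  without this, short follow-up windows inflate per-month costs, and they
  do so differentially by arm because the arms persist for different
  times. Claims are written in nominal service-year dollars (deflated by
  the same CPI series the analysis inflates with), so the inflation step is
  exercised end to end.
- **Events.** Configurable fractions of patients receive alternate-drug
  fills (switch), transplant admissions, inpatient deaths, and
  post-discontinuation refills placed at least 61 days after the stop day
  (re-initiators). Exclusion testers (under-age, short enrollment, missing
  IPF evidence, other-ILD diagnoses) default to zero and exist to exercise
  the attrition cascade.
- **Determinism.** All draws come from stage-specific RNG streams derived
  from the single config seed; a fixed config reproduces every table
  byte-for-byte, which the test suite checks via file checksums.

**What the generator does not emulate** — and hence what green tests do not
establish about real data: adjudication lag, plan/capitation structure, the
real ICD code universe and coding noise, dose titration beyond the
first-fill rule, informative censoring (disenrollment is independent of
health state), multi-drug concurrent therapy, and cost seasonality. Code
sets shipped in `default_code_config()` are deliberately small illustrative
stand-ins, not authoritative mappings; the same is true of the Charlson map.

## Numerical choices and degenerate inputs

- Age is computed from birth year only (claims convention), then binned.
- Continuous enrollment allows a configurable gap tolerance, 0 days by
  default; overlapping spans are a data-quality error, not silently merged.
- The baseline window is days `[index-365, index-1]`; recent pneumonia uses
  `[index-90, index-1]`. Claims on the index date itself are post-baseline.
- Constant covariates are dropped from model design matrices so degenerate
  fixtures degrade to intercept-only fits instead of erroring.
- `smd()` defines zero pooled variance with equal means as 0, and errors
  when the means differ.
- Bootstrap intervals are percentile intervals; the replicate index matrix
  is drawn once up front from the supplied seed, so intervals are exactly
  reproducible.

## Problem sizes used by the test suite

Validation runs at sizes chosen to give tight Monte-Carlo error while
keeping the suite quick: balance is checked on 100 generator seeds at
n = 2000; hazard-ratio and cost-ratio recovery on 50 seeds at n = 4000
(median estimates within ±0.1 and ±0.05 of truth); propensity-coefficient
recovery at n = 5000 (within 3 SE); the null-effect adherence check on 40
seeds at n = 1500; oracle equivalence on 1000 random fill patterns; and
type-I error of the robust tests on 1000 direct-simulation replicates.

## Known limitations

- The weighted Cox estimate carries a small attenuation from the monthly
  observation grid (events are only visible at refill resolution); at the
  default conditions the median recovered hazard ratio sits within ±0.05 of
  the generator truth, inside the documented tolerance but not unbiased.
- HC0 sandwich errors are mildly liberal in small samples; the bootstrap is
  the authoritative interval for cost contrasts.
- The package models a single paid amount per claim; payer/patient cost
  sharing, claim-line deduplication and competing-risks refinements are out
  of scope.
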