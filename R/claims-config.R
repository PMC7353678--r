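#' Configuration for the synthetic claims generator
#'
#' Bundles every parameter of the synthetic administrative-claims simulation
#' with known ground truth. Defaults describe a realistic two-arm
#' antifibrotic cohort as observed in US commercial/Medicare-supplemental
#' claims: 1455 patients indexing between October 2014 and mid 2017, a COPD
#' prevalence near 48% that shifts treatment assignment (log-odds +0.5) and
#' the discontinuation hazard (+30%), a drug-A vs drug-B discontinuation
#' hazard ratio of 0.8, and a total-cost ratio of 0.85 on a mean monthly cost
#' of $11,000 (2017 dollars).
#'
#' @param n_patients Number of patients (>= 2).
#' @param seed Integer seed; fixed seed gives byte-identical output. Each
#'   output table draws from its own RNG stream derived from this seed.
#' @param study_start,index_end,data_end_date,claims_end_date,fixed_index_end
#'   Calendar anchors: index dates are drawn uniformly on
#'   `[study_start, index_end]`; claims stop at `data_end_date`;
#'   `claims_end_date` bounds the variable-length cost dataset and
#'   `fixed_index_end` the fixed 12-month dataset (see [assign_followup()]).
#' @param enrollment_months_pre Minimum months of pre-index enrollment
#'   (>= 12); actual pre-index enrollment is this floor plus a random extent.
#' @param treatment_assignment_coefs Named numeric vector of log-odds
#'   coefficients on the propensity design matrix (see [fit_propensity()]).
#'   Names are matched to design columns; bare flag names such as `"copd"`
#'   match their `TRUE` dummy. Unnamed terms are zero.
#' @param true_discontinuation_hr Hazard ratio (drug A vs drug B) for the
#'   >= 60-day refill-gap event; must be > 0.
#' @param baseline_gap_hazard Per-day baseline hazard of stopping therapy for
#'   a drug-B patient without COPD. The default `log(2)/180` puts median
#'   persistence near 6 months.
#' @param copd_discontinuation_hr Multiplier on the stopping hazard for COPD
#'   patients (the confounder's outcome effect).
#' @param true_cost_ratio Ratio of arm-A to arm-B mean monthly all-cause cost.
#' @param cost_shape Gamma shape for monthly cost draws.
#' @param monthly_cost_base Mean monthly all-cause cost (2017 USD) for a
#'   drug-B patient without COPD.
#' @param copd_cost_ratio Multiplier on mean monthly cost for COPD patients.
#' @param drug_cost_share Fraction of monthly cost carried on the index-drug
#'   pharmacy claim; the remainder is spread over medical claims.
#' @param days_supply Days' supply per fill (fixed refill cycle length).
#' @param covariate_prevalences Named list of baseline covariate parameters:
#'   scalar prevalences (`female`, `copd`, `stroke`, `recent_pneumonia`,
#'   `ild_center_visit`, `oxygen`, `dyspnea`, `opioid`, `cardiovascular`,
#'   `cancer`, `lung_cancer`), the categorical tables `age_probs` and
#'   `region_probs`, and `comorbidity_probs` (independent prevalences of
#'   additional Charlson conditions).
#' @param switch_frac,transplant_frac,reinit_frac,death_frac Fractions of
#'   patients given, respectively, an alternate-antifibrotic fill, a
#'   lung-transplant admission, a post-discontinuation index-drug refill, and
#'   an inpatient death.
#' @param nonstandard_titration_frac Fraction of drug-A patients whose first
#'   fill is 90 pills/30 days (triggering the +7-day titration adjustment)
#'   rather than the recommended 207 pills/30 days.
#' @param other_ild_frac,no_ipf_frac,underage_frac,short_enrollment_frac
#'   Fractions of patients seeded with, respectively, a post-index other-ILD
#'   diagnosis, no IPF diagnosis claim, an index age under 40, and under 12
#'   months of pre-index enrollment. All default to 0; they exist to exercise
#'   the exclusion cascade.
#' @return An object of class `claims_config` (a validated named list).
#' @seealso [simulate_claims()]
#' @export
claims_config <- function(n_patients = 1455,
                          seed = 1L,
                          study_start = as.Date("2014-10-01"),
                          index_end = as.Date("2017-06-30"),
                          data_end_date = as.Date("2018-06-30"),
                          claims_end_date = as.Date("2017-09-30"),
                          fixed_index_end = as.Date("2016-09-30"),
                          enrollment_months_pre = 12L,
                          treatment_assignment_coefs = c("(Intercept)" = 0, copd = 0.5),
                          true_discontinuation_hr = 0.8,
                          baseline_gap_hazard = log(2) / 180,
                          copd_discontinuation_hr = 1.3,
                          true_cost_ratio = 0.85,
                          cost_shape = 1.5,
                          monthly_cost_base = 11000,
                          copd_cost_ratio = 1.2,
                          drug_cost_share = 0.65,
                          days_supply = 30L,
                          covariate_prevalences = NULL,
                          switch_frac = 0.10,
                          transplant_frac = 0.056,
                          reinit_frac = 0.16,
                          death_frac = 0.05,
                          nonstandard_titration_frac = 0.15,
                          other_ild_frac = 0,
                          no_ipf_frac = 0,
                          underage_frac = 0,
                          short_enrollment_frac = 0) {
  if (!is.numeric(n_patients) || n_patients < 2) {
    abort("configuration error: `n_patients` must be >= 2")
  }
  for (nm in c("true_discontinuation_hr", "baseline_gap_hazard",
               "copd_discontinuation_hr", "true_cost_ratio", "cost_shape",
               "monthly_cost_base", "copd_cost_ratio", "drug_cost_share",
               "days_supply")) {
    assert_positive(get(nm), nm)
  }
  if (enrollment_months_pre < 12) {
    abort("configuration error: `enrollment_months_pre` must be >= 12")
  }
  prev <- list(
    female = 0.313, copd = 0.476, stroke = 0.025, recent_pneumonia = 0.102,
    ild_center_visit = 0.076, oxygen = 0.597, dyspnea = 0.777,
    opioid = 0.383, cardiovascular = 0.44, cancer = 0.185,
    lung_cancer = 0.021,
    age_probs = c("40-44" = 0.001, "45-54" = 0.047, "55-64" = 0.259,
                  "65-74" = 0.306, "75-79" = 0.185, "80+" = 0.202),
    region_probs = c(Northeast = 0.186, `North Central` = 0.314,
                     South = 0.381, West = 0.116, Unknown = 0.003),
    comorbidity_probs = c(chf = 0.25, dementia = 0.12, diabetes = 0.35,
                          peptic_ulcer = 0.08, renal = 0.18,
                          hemiplegia = 0.04)
  )
  if (!is.null(covariate_prevalences)) {
    for (k in names(covariate_prevalences)) prev[[k]] <- covariate_prevalences[[k]]
  }
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    study_start = study_start, index_end = index_end,
    data_end_date = data_end_date, claims_end_date = claims_end_date,
    fixed_index_end = fixed_index_end,
    enrollment_months_pre = as.integer(enrollment_months_pre),
    treatment_assignment_coefs = treatment_assignment_coefs,
    true_discontinuation_hr = true_discontinuation_hr,
    baseline_gap_hazard = baseline_gap_hazard,
    copd_discontinuation_hr = copd_discontinuation_hr,
    true_cost_ratio = true_cost_ratio, cost_shape = cost_shape,
    monthly_cost_base = monthly_cost_base, copd_cost_ratio = copd_cost_ratio,
    drug_cost_share = drug_cost_share, days_supply = as.integer(days_supply),
    covariate_prevalences = prev,
    switch_frac = switch_frac, transplant_frac = transplant_frac,
    reinit_frac = reinit_frac, death_frac = death_frac,
    nonstandard_titration_frac = nonstandard_titration_frac,
    other_ild_frac = other_ild_frac, no_ipf_frac = no_ipf_frac,
    underage_frac = underage_frac,
    short_enrollment_frac = short_enrollment_frac
  )
  structure(cfg, class = "claims_config")
}

#' @export
print.claims_config <- function(x, ...) {
  cat("<claims_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  index window:", format(x$study_start), "to", format(x$index_end), "\n")
  cat("  true discontinuation HR (A vs B):", x$true_discontinuation_hr, "\n")
  cat("  true cost ratio (A vs B):", x$true_cost_ratio, "\n")
  invisible(x)
}
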