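#' Build the patient-level analysis table from raw claims
#'
#' Convenience wrapper chaining cohort selection, follow-up assignment,
#' baseline covariates, and treatment-pattern episode construction into a
#' single per-patient tibble ready for weighting and outcome modelling.
#'
#' @param tables A `claims_tables` list (from [simulate_claims()] or
#'   [read_claims()]).
#' @param code_config Code sets.
#' @param dataset Follow-up framing passed to [assign_followup()].
#' @param cutoffs Study calendar, see [study_cutoffs()].
#' @param gap_days,pdc_threshold,adherence_rule Episode settings, see
#'   [treatment_patterns()].
#' @return A tibble with one row per analysed patient: covariates joined to
#'   episode fields. Attributes `attrition`/`exclusions` from
#'   [select_cohort()] are carried over.
#' @export
#' @examples
#' tabs <- simulate_claims(claims_config(n_patients = 120, seed = 3))
#' nrow(prepare_analysis(tabs))
prepare_analysis <- function(tables, code_config = default_code_config(),
                             dataset = "treatment_patterns",
                             cutoffs = study_cutoffs(),
                             gap_days = 60L, pdc_threshold = 0.8,
                             adherence_rule = "gt") {
  cohort <- select_cohort(tables$enrollment, tables$pharmacy,
                          tables$medical, code_config,
                          study_start = as.Date("2014-10-01"),
                          study_end = cutoffs$data_end)
  fu <- assign_followup(cohort, tables$medical, dataset, cutoffs)
  covs <- baseline_covariates(fu, tables$medical, tables$pharmacy,
                              code_config)
  eps <- treatment_patterns(fu, tables$pharmacy, tables$medical,
                            code_config, gap_days = gap_days,
                            pdc_threshold = pdc_threshold,
                            adherence_rule = adherence_rule)
  out <- covs |>
    inner_join(eps |> select(-"index_date", -"index_drug"),
               by = "patient_id")
  attr(out, "attrition") <- attr(cohort, "attrition")
  attr(out, "exclusions") <- attr(cohort, "exclusions")
  out
}

#' Fit propensity weights onto an analysis table
#'
#' Fits the assignment model on the analysis tibble and appends
#' `propensity` and `iptw` columns.
#'
#' @param data Output of [prepare_analysis()] (or any covariate tibble).
#' @param treatment,treated,covariates As in [fit_propensity()].
#' @param ... Passed to [compute_iptw()] (stabilization, truncation).
#' @return `data` with `propensity` and `iptw` columns; the fit is attached
#'   as attribute `propensity_fit`.
#' @export
add_iptw <- function(data, treatment = "index_drug", treated = NULL,
                     covariates = propensity_covariates(), ...) {
  fit <- fit_propensity(data, treatment, treated, covariates)
  out <- data |>
    mutate(propensity = propensity_scores(fit),
           iptw = compute_iptw(.data$propensity, data[[treatment]],
                               fit$treated, ...))
  attr(out, "propensity_fit") <- fit
  out
}
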