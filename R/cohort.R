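#' Study calendar cutoffs
#'
#' @param data_end End of the full claims stream (last usable service date).
#' @param claims_end End of fully-adjudicated claims; bounds the
#'   variable-length cost dataset.
#' @param fixed_index_end Latest index date admitting 12 months of
#'   post-index adjudicated data.
#' @return A named list of Dates.
#' @export
study_cutoffs <- function(data_end = as.Date("2018-06-30"),
                          claims_end = as.Date("2017-09-30"),
                          fixed_index_end = as.Date("2016-09-30")) {
  list(data_end = data_end, claims_end = claims_end,
       fixed_index_end = fixed_index_end)
}

# merge a patient's enrollment spans; error on overlap, allow gaps <= tol
# days. Vectorised over the whole table: runs get globally unique ids.
merge_spans <- function(enrollment, gap_tolerance = 0L) {
  e <- enrollment |> arrange(.data$patient_id, .data$start)
  n <- nrow(e)
  if (n == 0L) return(e |> mutate(overlap = logical(), run = integer()))
  prev_end <- c(e$end[1], e$end[-n])
  same <- c(FALSE, e$patient_id[-1] == e$patient_id[-n])
  e$overlap <- same & e$start <= prev_end
  new_run <- !same | as.integer(e$start - prev_end) > gap_tolerance + 1L
  e$run <- cumsum(new_run)
  e
}

# collapse merged spans to one row per run (spans are sorted and disjoint,
# so run bounds are the first start and last end)
span_runs <- function(spans) {
  first <- !duplicated(spans$run)
  last <- !duplicated(spans$run, fromLast = TRUE)
  tibble(patient_id = spans$patient_id[first],
         run_start = spans$start[first],
         run_end = spans$end[last])
}

#' Select the analysis cohort from raw claims tables
#'
#' Applies the new-user inclusion/exclusion cascade, in order: (a) at least
#' one index-drug pharmacy claim in the study window (the first such claim
#' sets the index date and arm); (b) age >= `min_age` at index; (c) at least
#' 365 days of continuous enrollment before the index date; (d) at least one
#' non-diagnostic medical claim with an IPF diagnosis between the start of
#' baseline and the study end; (e) no other-ILD diagnosis between index and
#' study end. Each excluded patient is recorded with the first rule that
#' removed them, so the attrition table mirrors a patient-selection flowchart.
#'
#' @param enrollment,pharmacy,medical Claims tables (see [simulate_claims()]
#'   for schemas).
#' @param code_config Code sets; see [default_code_config()].
#' @param study_start,study_end Bounds of the index-claim window; `study_end`
#'   is also the horizon for the IPF and other-ILD rules.
#' @param min_age Minimum index age (years, from birth year).
#' @param gap_tolerance Maximum enrollment gap (days) still treated as
#'   continuous.
#' @return A tibble with one row per retained patient (`patient_id`,
#'   `index_date`, `index_drug`, `birth_year`, `sex`, `region`,
#'   `enroll_start`, `enroll_end`), with attributes `attrition` (step-by-step
#'   exclusion counts) and `exclusions` (per-patient reasons), retrievable
#'   via [attrition()].
#' @export
select_cohort <- function(enrollment, pharmacy, medical,
                          code_config = default_code_config(),
                          study_start = as.Date("2014-10-01"),
                          study_end = as.Date("2018-06-30"),
                          min_age = 40L,
                          gap_tolerance = 0L) {
  cc <- code_config
  spans <- merge_spans(enrollment, gap_tolerance)
  if (any(spans$overlap)) {
    bad <- unique(spans$patient_id[spans$overlap])
    abort(sprintf("data-quality error: overlapping enrollment spans for %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  all_ids <- unique(enrollment$patient_id)

  index_claims <- pharmacy |>
    filter(.data$drug %in% c(cc$drug_a, cc$drug_b),
           .data$service_date >= study_start,
           .data$service_date <= study_end) |>
    mutate(.drug_rank = match(.data$drug, c(cc$drug_a, cc$drug_b))) |>
    arrange(.data$patient_id, .data$service_date, .data$.drug_rank) |>
    filter(!duplicated(.data$patient_id)) |>
    select("patient_id", index_date = "service_date", index_drug = "drug")

  demo <- enrollment |>
    distinct(.data$patient_id, .data$birth_year, .data$sex, .data$region)

  cand <- index_claims |> left_join(demo, by = "patient_id")

  exclusions <- tibble(patient_id = setdiff(all_ids, cand$patient_id),
                       reason = "no_index_claim")
  steps <- tibble(step = "no_index_claim",
                  excluded = length(all_ids) - nrow(cand))

  ## (b) age
  cand <- cand |> mutate(age = year_of(.data$index_date) - .data$birth_year)
  drop <- cand |> filter(.data$age < min_age)
  exclusions <- bind_rows(exclusions,
                          tibble(patient_id = drop$patient_id, reason = "age"))
  steps <- bind_rows(steps, tibble(step = "age", excluded = nrow(drop)))
  cand <- cand |> filter(.data$age >= min_age)

  ## (c) continuous pre-index enrollment
  pre_ids <- cand$patient_id
  runs <- span_runs(merge_spans(enrollment |>
                                  filter(.data$patient_id %in%
                                           cand$patient_id),
                                gap_tolerance))
  cand <- cand |>
    left_join(runs, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$index_date >= .data$run_start,
           .data$index_date <= .data$run_end) |>
    rename(enroll_start = "run_start", enroll_end = "run_end")
  cand <- cand |> filter(.data$enroll_start <= .data$index_date - 365L)
  drop <- setdiff(pre_ids, cand$patient_id)
  exclusions <- bind_rows(exclusions,
                          tibble(patient_id = drop, reason = "enrollment"))
  steps <- bind_rows(steps,
                     tibble(step = "enrollment", excluded = length(drop)))

  ## (d) non-diagnostic IPF claim between baseline start and study end
  ipf_claims <- medical |>
    filter(!.data$claim_type %in% cc$nondiagnostic_excluded_types,
           dx_match_any(.data$dx, cc$ipf)) |>
    select("patient_id", "svc_start")
  has_ipf <- cand |>
    inner_join(ipf_claims, by = "patient_id",
               relationship = "one-to-many") |>
    filter(.data$svc_start >= .data$index_date - 365L,
           .data$svc_start <= study_end) |>
    distinct(.data$patient_id)
  drop <- setdiff(cand$patient_id, has_ipf$patient_id)
  exclusions <- bind_rows(exclusions,
                          tibble(patient_id = drop, reason = "no_ipf_claim"))
  steps <- bind_rows(steps,
                     tibble(step = "no_ipf_claim", excluded = length(drop)))
  cand <- cand |> filter(.data$patient_id %in% has_ipf$patient_id)

  ## (e) other interstitial lung disease after index
  oth <- medical |>
    filter(dx_match_any(.data$dx, cc$other_ild)) |>
    select("patient_id", "svc_start") |>
    inner_join(cand |> select("patient_id", "index_date"),
               by = "patient_id", relationship = "many-to-many") |>
    filter(.data$svc_start >= .data$index_date,
           .data$svc_start <= study_end) |>
    distinct(.data$patient_id)
  exclusions <- bind_rows(exclusions,
                          tibble(patient_id = oth$patient_id,
                                 reason = "other_ild"))
  steps <- bind_rows(steps,
                     tibble(step = "other_ild", excluded = nrow(oth)))
  cand <- cand |> filter(!.data$patient_id %in% oth$patient_id)

  out <- cand |>
    select("patient_id", "index_date", "index_drug", "birth_year",
           "sex", "region", "enroll_start", "enroll_end") |>
    arrange(.data$patient_id)
  steps$remaining <- length(all_ids) - cumsum(steps$excluded)
  attr(out, "attrition") <- steps
  attr(out, "exclusions") <- exclusions
  out
}

#' Attrition report for a selected cohort
#'
#' @param cohort Output of [select_cohort()].
#' @return A tibble with columns `step`, `excluded`, `remaining`.
#' @export
attrition <- function(cohort) attr(cohort, "attrition")

#' Assign follow-up windows for one of the three study datasets
#'
#' Follow-up runs from the index date to the earliest of inpatient death, end
#' of continuous enrollment, or the dataset's data cutoff. The
#' `treatment_patterns` dataset keeps all patients through `data_end`; the
#' `variable_cost` dataset keeps patients indexing on or before `claims_end`
#' and censors there; the `fixed_12m` dataset keeps patients indexing on or
#' before `fixed_index_end` with at least 12 months of continuous post-index
#' enrollment, and fixes the observation window to days index .. index+364.
#'
#' @param cohort Output of [select_cohort()].
#' @param medical Medical claims table (inpatient death is taken from
#'   inpatient claims flagged `death`).
#' @param dataset One of `"treatment_patterns"`, `"variable_cost"`,
#'   `"fixed_12m"`.
#' @param cutoffs A [study_cutoffs()] list.
#' @return The cohort tibble with `follow_up_end`, `end_reason` and `dataset`
#'   columns; rows not eligible for the requested dataset are dropped.
#' @export
assign_followup <- function(cohort, medical,
                            dataset = c("treatment_patterns",
                                        "variable_cost", "fixed_12m"),
                            cutoffs = study_cutoffs()) {
  dataset <- match.arg(dataset)
  deaths <- medical |>
    filter(.data$setting == "inpatient", .data$death %in% TRUE) |>
    arrange(.data$patient_id, .data$svc_end) |>
    filter(!duplicated(.data$patient_id)) |>
    select("patient_id", death_date = "svc_end")
  out <- cohort |>
    left_join(deaths, by = "patient_id")

  cut <- switch(dataset,
                treatment_patterns = cutoffs$data_end,
                variable_cost = cutoffs$claims_end,
                fixed_12m = cutoffs$data_end)
  if (dataset == "variable_cost") {
    out <- out |> filter(.data$index_date <= cutoffs$claims_end)
  }
  if (dataset == "fixed_12m") {
    out <- out |>
      filter(.data$index_date <= cutoffs$fixed_index_end,
             pmin(.data$enroll_end,
                  coalesce(.data$death_date, as.Date("9999-12-31"))) >=
               .data$index_date + 364L)
  }
  out <- out |>
    mutate(
      .death = coalesce(.data$death_date, as.Date("9999-12-31")),
      follow_up_end = pmin(.data$.death, .data$enroll_end, cut),
      end_reason = case_when(
        .data$follow_up_end == .data$.death ~ "inpatient_death",
        .data$follow_up_end == .data$enroll_end ~ "disenrollment",
        TRUE ~ "data_end"
      )
    )
  if (dataset == "fixed_12m") {
    out <- out |>
      mutate(follow_up_end = .data$index_date + 364L,
             end_reason = "data_end")
  }
  out |>
    mutate(dataset = dataset) |>
    select(-".death", -"death_date")
}

#' Baseline covariates from claims
#'
#' Computes demographics, comorbidity flags, and the Charlson index (with and
#' without COPD codes) over the 12-month pre-index baseline window
#' (days index-365 .. index-1). The recent-pneumonia flag uses only the 90
#' days preceding index. Age is computed from birth year (claims convention),
#' then binned into the six propensity-model age groups.
#'
#' @param cohort Cohort tibble with `patient_id`, `index_date`, `birth_year`,
#'   `sex`, `region`.
#' @param medical,pharmacy Claims tables.
#' @param code_config Code sets; see [default_code_config()].
#' @param charlson_map Condition/weight map for [charlson()].
#' @return The cohort tibble extended with `age`, `age_group`, factor-coded
#'   `sex` and `region`, `cci`, `cci_excl_copd`, and logical flags
#'   `supplemental_oxygen`, `opioid`, `dyspnea`, `cardiovascular`, `stroke`,
#'   `copd`, `cancer`, `lung_cancer`, `recent_pneumonia`, `ild_center_visit`.
#' @export
baseline_covariates <- function(cohort, medical, pharmacy,
                                code_config = default_code_config(),
                                charlson_map = default_charlson_map()) {
  cc <- code_config
  idx <- cohort |> select("patient_id", "index_date")

  med <- medical |>
    inner_join(idx, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$svc_start >= .data$index_date - 365L,
           .data$svc_start <= .data$index_date - 1L)
  dx_long <- med |>
    filter(!is.na(.data$dx)) |>
    select("patient_id", "svc_start", "index_date", "dx") |>
    separate_rows("dx", sep = ";") |>
    rename(code = "dx")

  flag_tbl <- function(tab, label) {
    tibble(patient_id = unique(tab$patient_id), flag = TRUE) |>
      setNames(c("patient_id", label))
  }
  dx_flag <- function(patterns, label, window_days = 365L) {
    hits <- dx_long |>
      filter(match_codes(.data$code, patterns),
             .data$svc_start >= .data$index_date - window_days)
    flag_tbl(hits, label)
  }

  cci_tab <- charlson_scores(dx_long, charlson_map)
  cci_ex_tab <- charlson_scores(dx_long, charlson_map, exclude = cc$copd) |>
    rename(cci_excl_copd = "cci")

  oxy <- flag_tbl(med |> filter(match_codes(.data$proc, cc$oxygen_proc)),
                  "supplemental_oxygen")
  opi <- flag_tbl(
    pharmacy |>
      inner_join(idx, by = "patient_id", relationship = "many-to-many") |>
      filter(.data$service_date >= .data$index_date - 365L,
             .data$service_date <= .data$index_date - 1L,
             .data$drug %in% cc$opioid_drugs),
    "opioid")
  ild <- flag_tbl(med |> filter(.data$ild_center %in% TRUE),
                  "ild_center_visit")

  flags <- list(
    dx_flag(cc$dyspnea, "dyspnea"),
    dx_flag(cc$cardiovascular, "cardiovascular"),
    dx_flag(cc$stroke, "stroke"),
    dx_flag(cc$copd, "copd"),
    dx_flag(cc$cancer, "cancer"),
    dx_flag(cc$lung_cancer, "lung_cancer"),
    dx_flag(cc$pneumonia, "recent_pneumonia", window_days = 90L),
    oxy, opi, ild
  )

  out <- cohort |>
    mutate(age = year_of(.data$index_date) - .data$birth_year,
           age_group = cut(.data$age, c(-Inf, 44, 54, 64, 74, 79, Inf),
                           labels = c("40-44", "45-54", "55-64", "65-74",
                                      "75-79", "80+")),
           sex = factor(.data$sex),
           region = factor(.data$region)) |>
    left_join(cci_tab, by = "patient_id") |>
    left_join(cci_ex_tab, by = "patient_id") |>
    mutate(cci = coalesce(.data$cci, 0L),
           cci_excl_copd = coalesce(.data$cci_excl_copd, 0L))
  for (f in flags) out <- out |> left_join(f, by = "patient_id")
  out |>
    mutate(across(c("supplemental_oxygen", "opioid", "dyspnea",
                    "cardiovascular", "stroke", "copd", "cancer",
                    "lung_cancer", "recent_pneumonia", "ild_center_visit"),
                  ~ coalesce(.x, FALSE)))
}
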