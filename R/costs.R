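#' Classify claims for utilization and cost aggregation
#'
#' Medical claims are respiratory-related when the first-position (primary)
#' diagnosis matches the respiratory code set; diagnoses in later positions
#' do not qualify. Pharmacy claims are respiratory-related when the drug is a
#' respiratory therapy (antifibrotics, oral corticosteroids, pneumonia/ARI
#' antibiotics, azathioprine, N-acetylcysteine, mycophenolate mofetil), and
#' index-drug-related when the drug is one of the two antifibrotics.
#' Lung-transplant admissions are flagged so they can be excluded from
#' inpatient counts. Medical claims with no diagnosis are classified
#' non-respiratory with a warning.
#'
#' @param claims A medical or pharmacy claims table.
#' @param code_config Code sets; see [default_code_config()].
#' @param type `"medical"` or `"pharmacy"`.
#' @return The claims tibble with added logical columns
#'   `respiratory_related`, `index_drug_related`, `lung_transplant`, and a
#'   normalized `setting` (`"pharmacy"` for pharmacy claims).
#' @export
classify_claims <- function(claims, code_config = default_code_config(),
                            type = c("medical", "pharmacy")) {
  type <- match.arg(type)
  cc <- code_config
  if (type == "medical") {
    no_dx <- is.na(claims$dx) | !nzchar(claims$dx)
    if (any(no_dx)) {
      warn(sprintf(
        "%d medical claim(s) without a diagnosis classified non-respiratory",
        sum(no_dx)))
    }
    claims |>
      mutate(
        respiratory_related = match_codes(first_dx(.data$dx),
                                          cc$respiratory_dx),
        index_drug_related = FALSE,
        lung_transplant = match_codes(.data$proc, cc$transplant_proc)
      )
  } else {
    claims |>
      mutate(
        setting = "pharmacy",
        respiratory_related = .data$drug %in% cc$respiratory_drugs,
        index_drug_related = .data$drug %in% c(cc$drug_a, cc$drug_b),
        lung_transplant = FALSE
      )
  }
}

#' Aggregate utilization and costs over per-patient windows
#'
#' Filters classified claims to each patient's observation window, inflates
#' paid amounts to `target_year` dollars with the medical-care CPI, and
#' summarises counts, any-use flags, inpatient length of stay, and costs by
#' category (all-cause, respiratory-related, index-drug-related) and setting.
#' Normalization: PPPM divides totals by `window_days / 30.4375` (the average
#' Gregorian month); PPPY divides by `window_days / 365`. Lung-transplant
#' admissions are always excluded from inpatient counts; their costs are
#' excluded too by default (`exclude_transplant_costs = FALSE` keeps the
#' dollars while still excluding the admission from counts).
#'
#' @param medical Classified medical claims (see [classify_claims()]).
#' @param pharmacy Classified pharmacy claims.
#' @param windows Tibble with `patient_id`, `start`, `end` (Dates, inclusive).
#' @param cpi_table Year/index table for [inflate_costs()].
#' @param target_year Reference dollar year.
#' @param month_days Days per month for PPPM normalization.
#' @param exclude_transplant_costs Drop transplant-admission dollars as well
#'   as the admission counts.
#' @return One row per window patient: `window_days`; per-setting costs
#'   (`cost_inpatient`, `cost_emergency`, `cost_office`,
#'   `cost_other_outpatient`, `cost_pharmacy`) which sum to
#'   `all_cause_cost`; `respiratory_cost` and `index_drug_cost`; utilization
#'   counts and any-use flags per setting for all-cause and
#'   respiratory-related claims; mean inpatient length of stay (`los_mean`,
#'   `resp_los_mean`); and PPPM/PPPY versions of the three cost categories.
#' @export
aggregate_costs <- function(medical, pharmacy, windows,
                            cpi_table = default_cpi_table(),
                            target_year = 2017L,
                            month_days = 30.4375,
                            exclude_transplant_costs = TRUE) {
  if (any(windows$end < windows$start)) {
    abort("aggregation window with end < start")
  }
  med <- medical |>
    inner_join(windows, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$svc_start >= .data$start, .data$svc_start <= .data$end) |>
    mutate(paid = inflate_costs(.data$paid, year_of(.data$svc_start),
                                cpi_table, target_year),
           los = as.integer(.data$svc_end - .data$svc_start) + 1L)
  if (exclude_transplant_costs) {
    med <- med |> filter(!.data$lung_transplant)
  }
  rx <- pharmacy |>
    inner_join(windows, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$service_date >= .data$start,
           .data$service_date <= .data$end) |>
    mutate(paid = inflate_costs(.data$paid, year_of(.data$service_date),
                                cpi_table, target_year))

  count_block <- function(df, prefix = "") {
    dtm <- as.data.table(df[, c("patient_id", "setting",
                                "lung_transplant", "los", "paid")])
    dtm[, `:=`(is_ip = setting == "inpatient" & !lung_transplant,
               is_ed = setting == "emergency",
               is_of = setting == "office",
               is_ot = setting == "other_outpatient")]
    out <- dtm[, list(
      inpatient_n = sum(is_ip),
      emergency_n = sum(is_ed),
      office_n = sum(is_of),
      other_outpatient_n = sum(is_ot),
      los_total = sum(los * is_ip),
      medical_cost = sum(paid),
      cost_inpatient = sum(paid * (setting == "inpatient")),
      cost_emergency = sum(paid * is_ed),
      cost_office = sum(paid * is_of),
      cost_other_outpatient = sum(paid * is_ot)
    ), by = "patient_id"]
    as_tibble(out) |>
      mutate(los_mean = if_else(.data$inpatient_n > 0,
                                .data$los_total / .data$inpatient_n,
                                NA_real_)) |>
      select(-"los_total") |>
      rename_with(~ paste0(prefix, .x), -"patient_id")
  }
  med_all <- count_block(med)
  med_resp <- count_block(med |> filter(.data$respiratory_related), "resp_")
  dtr <- as.data.table(rx[, c("patient_id", "paid", "respiratory_related",
                              "index_drug_related")])
  rx_all <- as_tibble(dtr[, list(
    pharmacy_n = .N, cost_pharmacy = sum(paid),
    resp_pharmacy_n = sum(respiratory_related),
    resp_cost_pharmacy = sum(paid * respiratory_related),
    index_drug_n = sum(index_drug_related),
    index_drug_cost = sum(paid * index_drug_related)
  ), by = "patient_id"])

  out <- windows |>
    mutate(window_days = as.integer(.data$end - .data$start) + 1L) |>
    left_join(med_all, by = "patient_id") |>
    left_join(med_resp, by = "patient_id") |>
    left_join(rx_all, by = "patient_id") |>
    mutate(across(-c("patient_id", "start", "end", "window_days",
                     "los_mean", "resp_los_mean"),
                  ~ coalesce(.x, 0))) |>
    mutate(
      all_cause_cost = .data$medical_cost + .data$cost_pharmacy,
      respiratory_cost = .data$resp_medical_cost + .data$resp_cost_pharmacy,
      inpatient_any = .data$inpatient_n > 0,
      emergency_any = .data$emergency_n > 0,
      office_any = .data$office_n > 0,
      outpatient_any = .data$emergency_n + .data$office_n +
        .data$other_outpatient_n > 0,
      resp_inpatient_any = .data$resp_inpatient_n > 0,
      resp_outpatient_any = .data$resp_emergency_n + .data$resp_office_n +
        .data$resp_other_outpatient_n > 0,
      months = .data$window_days / month_days,
      years = .data$window_days / 365,
      all_cause_pppm = .data$all_cause_cost / .data$months,
      respiratory_pppm = .data$respiratory_cost / .data$months,
      index_drug_pppm = .data$index_drug_cost / .data$months,
      all_cause_pppy = .data$all_cause_cost / .data$years,
      respiratory_pppy = .data$respiratory_cost / .data$years,
      index_drug_pppy = .data$index_drug_cost / .data$years,
      inpatient_pppm = .data$inpatient_n / .data$months,
      emergency_pppm = .data$emergency_n / .data$months,
      office_pppm = .data$office_n / .data$months,
      pharmacy_pppm = .data$pharmacy_n / .data$months
    ) |>
    select(-"months", -"years")
  out
}

#' Inflate paid amounts to reference-year dollars
#'
#' Multiplies by `index(target_year) / index(service_year)` using the
#' medical-care CPI.
#'
#' @param amount Numeric amounts.
#' @param service_year Integer year(s) of service.
#' @param cpi_table Tibble with `year` and `cpi` columns covering both years.
#' @param target_year Reference year (default 2017).
#' @return Inflated amounts.
#' @export
#' @examples
#' inflate_costs(100, 2014, tibble::tibble(year = c(2014, 2017),
#'                                         cpi = c(240, 250)))
inflate_costs <- function(amount, service_year,
                          cpi_table = default_cpi_table(),
                          target_year = 2017L) {
  i_svc <- cpi_table$cpi[match(service_year, cpi_table$year)]
  i_tgt <- cpi_table$cpi[match(target_year, cpi_table$year)]
  if (any(is.na(i_svc)) || any(is.na(i_tgt))) {
    missing_years <- unique(c(service_year[is.na(i_svc)],
                              target_year[is.na(i_tgt)]))
    abort(sprintf("CPI table missing year(s): %s",
                  paste(missing_years, collapse = ", ")))
  }
  amount * i_tgt / i_svc
}
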