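#' Treatment-pattern episodes for a cohort
#'
#' Runs the full episode construction for every patient in a cohort with
#' assigned follow-up: titration adjustment of the first index-drug fill,
#' coverage-timeline building with overlap appending, PDC over the follow-up
#' window, >= `gap_days` gap discontinuation with the lung-transplant
#' exception, switching (first fill of the alternate antifibrotic on or after
#' index), persistence, and re-initiation. Equivalent to calling
#' [build_episode()] per patient, but vectorised.
#'
#' Transplant dates are taken from medical claims whose procedure code
#' matches `code_config$transplant_proc` on or after the index date.
#'
#' @param cohort Output of [assign_followup()] (needs `patient_id`,
#'   `index_date`, `index_drug`, `follow_up_end`).
#' @param pharmacy Pharmacy claims table.
#' @param medical Medical claims table, or `NULL` to skip transplants.
#' @param code_config Code sets; see [default_code_config()].
#' @param gap_days Minimum discontinuation gap (days).
#' @param pdc_threshold,adherence_rule Adherence settings; the default flags
#'   PDC strictly greater than 0.8.
#' @return A tibble, one row per cohort patient, with the [build_episode()]
#'   columns plus `patient_id`, `index_date`, `index_drug`,
#'   `follow_up_days` (inclusive day count), `total_covered_days`, and the
#'   composite-event helpers `days_disc_switch` / `event_disc_switch`
#'   (earlier of discontinuation and switch; censoring at transplant or end
#'   of follow-up) and `persistence_time` (persistence days, for time-to-event
#'   models). Day-valued columns are integer offsets from the index date.
#' @export
treatment_patterns <- function(cohort, pharmacy, medical = NULL,
                               code_config = default_code_config(),
                               gap_days = 60L, pdc_threshold = 0.8,
                               adherence_rule = c("gt", "ge")) {
  adherence_rule <- match.arg(adherence_rule)
  cc <- code_config
  idx <- cohort |>
    select("patient_id", "index_date", "index_drug", "follow_up_end") |>
    mutate(fu = as.integer(.data$follow_up_end - .data$index_date))

  fills <- pharmacy |>
    inner_join(idx, by = "patient_id", relationship = "many-to-many") |>
    mutate(day = as.integer(.data$service_date - .data$index_date)) |>
    filter(.data$day >= 0L, .data$day <= .data$fu,
           .data$drug %in% c(cc$drug_a, cc$drug_b))

  own0 <- fills |> filter(.data$drug == .data$index_drug)
  dt <- as.data.table(own0[, c("patient_id", "day", "days_supply",
                               "quantity", "index_drug", "fu")])
  dt <- dt[, list(days_supply = sum(days_supply),
                  quantity = sum(quantity),
                  index_drug = index_drug[1L], fu = fu[1L]),
           by = c("patient_id", "day")]
  setorder(dt, patient_id, day)
  first_fill <- !duplicated(dt$patient_id)
  supply <- dt$days_supply
  supply[first_fill] <- adjust_titration(dt$days_supply[first_fill],
                                         dt$quantity[first_fill],
                                         dt$index_drug[first_fill],
                                         cc$titration_drug)
  ## group-wise running quantities without per-group dispatch: global
  ## cumulative sums rebased at each patient's first fill
  cs <- cumsum(supply)
  grp <- cumsum(first_fill)
  cum <- cs - (cs - supply)[first_fill][grp]
  prev_cum <- ifelse(first_fill, 0L, c(0L, cum[-length(cum)]))
  dt[, `:=`(supply = supply, cum = cum, prev_cum = prev_cum)]
  dt[, cov_end := cum + cummax(day - prev_cum) - 1L, by = "patient_id"]
  nr <- nrow(dt)
  prev_end_na <- c(NA_integer_, dt$cov_end[-nr])
  prev_end_na[first_fill] <- NA_integer_
  prev_end <- ifelse(is.na(prev_end_na), -1L, prev_end_na)
  gap_before <- dt$day - prev_end_na - 1L
  seg_start <- pmax(dt$day, prev_end + 1L)
  dt[, cov_in_fu := pmax(0L, pmin(cov_end, fu) - pmax(seg_start, 0L) + 1L)]
  ## first qualifying gap: cov_end is non-decreasing within patient, so
  ## min() over candidates picks the earliest one
  dt[, disc_cand := ifelse(!is.na(gap_before) & gap_before >= gap_days,
                           prev_end_na, .Machine$integer.max)]
  own <- as_tibble(dt[, c("patient_id", "day")])
  per_patient <- as_tibble(dt[, list(total_covered_days = sum(cov_in_fu),
                                     n_fills = .N,
                                     disc_internal = min(disc_cand),
                                     last_cov_end = max(cov_end)),
                              by = "patient_id"]) |>
    mutate(disc_internal = if_else(.data$disc_internal ==
                                     .Machine$integer.max,
                                   NA_integer_, .data$disc_internal))

  switches <- fills |>
    filter(.data$drug != .data$index_drug) |>
    arrange(.data$patient_id, .data$day) |>
    filter(!duplicated(.data$patient_id)) |>
    select("patient_id", switch_day = "day")

  if (!is.null(medical)) {
    transplants <- medical |>
      filter(match_codes(.data$proc, cc$transplant_proc)) |>
      inner_join(idx, by = "patient_id", relationship = "many-to-many") |>
      mutate(day = as.integer(.data$svc_start - .data$index_date)) |>
      filter(.data$day >= 0L, .data$day <= .data$fu) |>
      arrange(.data$patient_id, .data$day) |>
      filter(!duplicated(.data$patient_id)) |>
      select("patient_id", transplant_day = "day")
  } else {
    transplants <- tibble(patient_id = character(),
                          transplant_day = integer())
  }

  out <- idx |>
    left_join(per_patient, by = "patient_id") |>
    left_join(switches, by = "patient_id") |>
    left_join(transplants, by = "patient_id") |>
    mutate(
      total_covered_days = coalesce(.data$total_covered_days, 0L),
      disc_raw = if_else(!is.na(.data$disc_internal), .data$disc_internal,
                         if_else(!is.na(.data$last_cov_end) &
                                   .data$fu - .data$last_cov_end >= gap_days,
                                 .data$last_cov_end, NA_integer_)),
      discontinuation_day = if_else(
        !is.na(.data$disc_raw) & !is.na(.data$transplant_day) &
          .data$transplant_day < .data$disc_raw + gap_days,
        NA_integer_, .data$disc_raw),
      pdc = pmin(.data$total_covered_days / (.data$fu + 1), 1.0),
      adherent = classify_adherent(.data$pdc, pdc_threshold, adherence_rule)
    )

  disc_map <- out$discontinuation_day[match(own$patient_id, out$patient_id)]
  reinit_tbl <- own[!is.na(disc_map) & own$day > disc_map + gap_days, ] |>
    filter(!duplicated(.data$patient_id)) |>   # own is sorted by (id, day)
    select("patient_id", reinitiation_day = "day")
  out <- out |>
    left_join(reinit_tbl, by = "patient_id") |>
    mutate(days_to_reinitiation = .data$reinitiation_day -
             .data$discontinuation_day)

  pe <- pmin(
    coalesce(out$transplant_day, .Machine$integer.max),
    coalesce(out$switch_day, .Machine$integer.max),
    coalesce(out$discontinuation_day, .Machine$integer.max),
    out$fu
  )
  reason <- dplyr::case_when(
    !is.na(out$transplant_day) & out$transplant_day == pe ~ "transplant",
    !is.na(out$switch_day) & out$switch_day == pe ~ "switched",
    !is.na(out$discontinuation_day) & out$discontinuation_day == pe ~
      "discontinued",
    TRUE ~ "censored"
  )
  ds <- pmin(coalesce(out$discontinuation_day, .Machine$integer.max),
             coalesce(out$switch_day, .Machine$integer.max))
  has_ds <- ds <= pmin(coalesce(out$transplant_day, .Machine$integer.max),
                       out$fu)
  censor_day <- as.integer(pmin(coalesce(out$transplant_day,
                                         .Machine$integer.max), out$fu))
  ds[!has_ds] <- NA_integer_
  out |>
    mutate(
      persistence_end = as.integer(pe),
      persistence_days = as.integer(pe) + 1L,
      persistence_reason = reason,
      follow_up_days = .data$fu + 1L,
      days_disc_switch = as.integer(ds),
      event_disc_switch = as.integer(has_ds),
      persistence_time = if_else(has_ds, as.integer(ds), censor_day) + 1L
    ) |>
    select("patient_id", "index_date", "index_drug", "follow_up_days",
           "total_covered_days", "pdc", "adherent", "discontinuation_day",
           "switch_day", "transplant_day", "persistence_end",
           "persistence_days", "persistence_reason", "reinitiation_day",
           "days_to_reinitiation", "days_disc_switch", "event_disc_switch",
           "persistence_time")
}
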