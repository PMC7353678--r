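#' Simulate a synthetic administrative-claims extract with known ground truth
#'
#' Generates the three flat tables of a claims extract — enrollment spans,
#' outpatient pharmacy claims, and medical claims — for a two-arm antifibrotic
#' new-user cohort, together with a ground-truth table holding each patient's
#' true propensity score, assigned arm, treatment-stop day, and mean monthly
#' cost. Treatment is assigned by a logistic model on the baseline covariates;
#' refills follow a fixed 30-day supply with small jitter and a geometric
#' per-fill stopping rule calibrated (via the complementary log-log link) so
#' the arm contrast on the >= 60-day gap event is exactly
#' `true_discontinuation_hr` under proportional hazards; monthly costs are
#' gamma with log-linear arm and COPD effects. Baseline diagnosis claims are
#' emitted so that the covariates recovered by [baseline_covariates()] equal
#' the covariates used for assignment.
#'
#' All randomness is drawn from stage-specific RNG streams derived from
#' `config$seed`, so a fixed config reproduces the tables exactly.
#'
#' @param config A [claims_config()] object.
#' @return An object of class `claims_tables`: a list with tibbles
#'   `enrollment`, `pharmacy`, `medical`, `ground_truth`, plus the `config`.
#'   Day-valued ground-truth columns (`true_disc_day`, `switch_day`,
#'   `transplant_day`, `reinit_day`) are integer offsets from the index date.
#' @export
#' @examples
#' tabs <- simulate_claims(claims_config(n_patients = 50, seed = 7))
#' nrow(tabs$enrollment)
simulate_claims <- function(config = claims_config()) {
  if (!inherits(config, "claims_config")) {
    abort("`config` must be created by claims_config()")
  }
  cfg <- config
  n <- cfg$n_patients
  prev <- cfg$covariate_prevalences
  cc <- default_code_config()
  supply <- cfg$days_supply

  ## ---- stream 1: demographics, baseline morbidity, enrollment ----
  set.seed(stream_seed(cfg$seed, 1L))
  patient_id <- sprintf("P%06d", seq_len(n))
  index_span <- as.integer(cfg$index_end - cfg$study_start) + 1L
  index_date <- cfg$study_start + (sample.int(index_span, n, replace = TRUE) - 1L)

  age_group <- sample(names(prev$age_probs), n, TRUE, prob = prev$age_probs)
  age_lo <- c("40-44" = 40, "45-54" = 45, "55-64" = 55,
              "65-74" = 65, "75-79" = 75, "80+" = 80)[age_group]
  age_hi <- c("40-44" = 44, "45-54" = 54, "55-64" = 64,
              "65-74" = 74, "75-79" = 79, "80+" = 89)[age_group]
  age <- as.integer(age_lo + floor(runif(n) * (age_hi - age_lo + 1)))
  female <- runif(n) < prev$female
  region <- sample(names(prev$region_probs), n, TRUE, prob = prev$region_probs)
  copd <- runif(n) < prev$copd
  stroke <- runif(n) < prev$stroke
  cardiovascular <- runif(n) < prev$cardiovascular
  cancer <- runif(n) < prev$cancer
  lung_cancer <- cancer & runif(n) < prev$lung_cancer / prev$cancer
  dyspnea <- runif(n) < prev$dyspnea
  oxygen <- runif(n) < prev$oxygen
  opioid <- runif(n) < prev$opioid
  ild_center <- runif(n) < prev$ild_center_visit
  recent_pneumonia <- runif(n) < prev$recent_pneumonia
  extra <- vapply(prev$comorbidity_probs,
                  function(p) runif(n) < p, logical(n))
  if (n == 1L) extra <- matrix(extra, nrow = 1,
                               dimnames = list(NULL, names(prev$comorbidity_probs)))

  pre_days <- 365L + 30L * rpois(n, 8)
  disenroll_off <- as.integer(round(rexp(n, 1 / 900)))
  died <- runif(n) < cfg$death_frac
  death_off <- 30L + as.integer(floor(runif(n) * 1100))

  underage <- runif(n) < cfg$underage_frac
  short_enr <- runif(n) < cfg$short_enrollment_frac
  no_ipf <- runif(n) < cfg$no_ipf_frac
  other_ild <- runif(n) < cfg$other_ild_frac

  age[underage] <- 35L
  pre_days[short_enr] <- 180L
  birth_year <- year_of(index_date) - age

  data_cap <- as.integer(cfg$data_end_date - index_date)
  end_off <- pmin(disenroll_off, data_cap)
  died_obs <- died & death_off <= end_off
  end_off[died_obs] <- death_off[died_obs]

  ## baseline diagnosis codes: one claim per positive concept, so the flags
  ## recovered from claims equal the flags used for assignment
  extra_codes <- c(chf = "I50.9", dementia = "F03.90", diabetes = "E11.9",
                   peptic_ulcer = "K25.9", renal = "N18.4",
                   hemiplegia = "G81.90")
  code_piece <- function(flag, code) {
    tibble(patient_id = patient_id[flag], code = code)
  }
  dx_long <- bind_rows(
    code_piece(copd, "J44.9"),
    code_piece(stroke, "I63.9"),
    code_piece(cardiovascular, "I25.10"),
    code_piece(cancer, "C50.911"),
    code_piece(lung_cancer, "C34.90"),
    code_piece(dyspnea, "R06.02"),
    code_piece(recent_pneumonia, "J18.9"),
    bind_rows(lapply(names(extra_codes), function(cn) {
      code_piece(extra[, cn], unname(extra_codes[cn]))
    }))
  )
  cci_tab <- charlson_scores(dx_long)
  cci_ex_tab <- charlson_scores(dx_long, exclude = cc$copd) |>
    rename(cci_excl_copd = "cci")
  base <- tibble(patient_id) |>
    left_join(cci_tab, by = "patient_id") |>
    left_join(cci_ex_tab, by = "patient_id") |>
    mutate(cci = coalesce(.data$cci, 0L),
           cci_excl_copd = coalesce(.data$cci_excl_copd, 0L))

  ## ---- stream 2: treatment assignment ----
  covs <- tibble(
    age_group = factor(age_group, levels = names(prev$age_probs)),
    sex = factor(ifelse(female, "F", "M"), levels = c("F", "M")),
    region = factor(region, levels = names(prev$region_probs)),
    cci_excl_copd = base$cci_excl_copd,
    copd = copd, stroke = stroke, recent_pneumonia = recent_pneumonia,
    ild_center_visit = ild_center
  )
  X <- model.matrix(~ age_group + sex + region + cci_excl_copd + copd +
                      stroke + recent_pneumonia + ild_center_visit, covs)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  for (nm in names(cfg$treatment_assignment_coefs)) {
    hit <- if (nm %in% names(beta)) nm
           else if (paste0(nm, "TRUE") %in% names(beta)) paste0(nm, "TRUE")
           else NA_character_
    if (is.na(hit)) {
      warn(sprintf("treatment coefficient `%s` matches no design column", nm))
    } else {
      beta[hit] <- cfg$treatment_assignment_coefs[[nm]]
    }
  }
  propensity <- plogis(drop(X %*% beta))
  set.seed(stream_seed(cfg$seed, 2L))
  arm_a <- runif(n) < propensity
  drug <- ifelse(arm_a, cc$drug_a, cc$drug_b)

  ## ---- stream 3: index-drug refill process ----
  rate <- cfg$baseline_gap_hazard *
    cfg$true_discontinuation_hr^arm_a * cfg$copd_discontinuation_hr^copd
  q_stop <- 1 - exp(-supply * rate)
  set.seed(stream_seed(cfg$seed, 3L))
  n_fills <- pmin(1L + rgeom(n, q_stop), 60L)
  nonstd <- arm_a & runif(n) < cfg$nonstandard_titration_frac

  ft <- tibble(patient_id, arm_a, nonstd, fu_off = end_off, n_fills) |>
    uncount(.data$n_fills, .id = "fill_no")
  m <- nrow(ft)
  ft$delay <- ifelse(ft$fill_no == 1L, 0L,
                     pmin(rgeom(m, 0.35), 45L) - 2L)
  ft$eff <- ifelse(ft$fill_no == 1L & ft$nonstd, supply + 7L, supply)
  ft$quantity <- ifelse(!ft$arm_a, 60L,
                        ifelse(ft$fill_no > 1L, 270L,
                               ifelse(ft$nonstd, 90L, 207L)))
  ## per-patient running coverage without grouped dispatch: global cumsum
  ## rebased at each patient's first fill
  adv <- ft$eff + pmax(ft$delay, 0L)
  cs_adv <- cumsum(adv)
  first_fill <- ft$fill_no == 1L
  ft$cov_end <- cs_adv - (cs_adv - adv)[first_fill][cumsum(first_fill)] - 1L
  prev_end <- c(-1L, ft$cov_end[-nrow(ft)])
  prev_end[first_fill] <- -1L
  ft$day <- prev_end + 1L + ft$delay
  kept <- ft |> filter(.data$day <= .data$fu_off)
  truth_fill <- kept |>
    group_by(.data$patient_id) |>
    summarise(n_emit = n(), stop_day = max(.data$cov_end), .groups = "drop")
  truth <- tibble(patient_id, n_fills) |>
    left_join(truth_fill, by = "patient_id") |>
    mutate(true_disc_day = if_else(!is.na(.data$n_emit) &
                                     .data$n_emit == .data$n_fills,
                                   .data$stop_day, NA_integer_))

  ## ---- stream 5: switches, transplants, re-initiation, extras ----
  set.seed(stream_seed(cfg$seed, 5L))
  switch_day <- 30L + as.integer(floor(runif(n) * 470))
  switch_day[!(runif(n) < cfg$switch_frac) | switch_day >= end_off] <- NA_integer_
  transplant_day <- 60L + as.integer(floor(runif(n) * 540))
  transplant_day[!(runif(n) < cfg$transplant_frac) |
                   transplant_day >= end_off] <- NA_integer_
  true_disc_day <- truth$true_disc_day
  reinit_elig <- !is.na(true_disc_day) &
    (is.na(transplant_day) | transplant_day >= true_disc_day + 60L)
  reinit_sel <- reinit_elig & runif(n) < cfg$reinit_frac
  reinit_day <- true_disc_day + 61L + as.integer(rgeom(n, 1 / 97))
  reinit_day[!reinit_sel | is.na(reinit_day) | reinit_day >= end_off] <- NA_integer_

  ## ---- stream 6: baseline claim placement ----
  set.seed(stream_seed(cfg$seed, 6L))
  pre_place <- function(flag) -(30L + as.integer(floor(runif(n) * 330)))
  base_rows <- list()
  add_base <- function(flag, code, day_off) {
    tibble(patient_id = patient_id[flag], day = day_off[flag], dx = code,
           setting = "office", claim_type = "standard")
  }
  base_rows$copd <- add_base(copd, "J44.9", pre_place())
  base_rows$stroke <- add_base(stroke, "I63.9", pre_place())
  base_rows$cvd <- add_base(cardiovascular, "I25.10", pre_place())
  base_rows$cancer <- add_base(cancer, "C50.911", pre_place())
  base_rows$lung_cancer <- add_base(lung_cancer, "C34.90", pre_place())
  base_rows$dyspnea <- add_base(dyspnea, "R06.02", pre_place())
  pneu_day <- -(1L + as.integer(floor(runif(n) * 90)))
  base_rows$pneumonia <- add_base(recent_pneumonia, "J18.9", pneu_day)
  for (cn in names(extra_codes)) {
    base_rows[[cn]] <- add_base(extra[, cn], unname(extra_codes[cn]), pre_place())
  }
  ipf_day <- -(10L + as.integer(floor(runif(n) * 350)))
  base_rows$ipf <- add_base(!no_ipf, "J84.112", ipf_day)
  ild_day <- -(10L + as.integer(floor(runif(n) * 350)))
  baseline_med <- bind_rows(base_rows) |>
    mutate(proc = NA_character_, death = FALSE, ild_center = FALSE, los = 1L)
  ild_rows <- tibble(patient_id = patient_id[ild_center],
                     day = ild_day[ild_center], dx = "Z09",
                     setting = "office", claim_type = "standard",
                     proc = NA_character_, death = FALSE, ild_center = TRUE,
                     los = 1L)
  oxy_rows <- tibble(patient_id = patient_id[oxygen],
                     day = pre_place()[oxygen], dx = NA_character_,
                     setting = "other_outpatient", claim_type = "standard",
                     proc = "E0424", death = FALSE, ild_center = FALSE,
                     los = 1L)
  opioid_day <- -(1L + as.integer(floor(runif(n) * 365)))

  ## ---- stream 4: follow-up utilization and paid amounts ----
  mu <- cfg$monthly_cost_base * cfg$true_cost_ratio^arm_a *
    cfg$copd_cost_ratio^copd
  set.seed(stream_seed(cfg$seed, 4L))
  m_total <- pmax(1L, as.integer(ceiling((end_off + 1L) / 30)))
  ## patients seeded without IPF evidence get a different (still
  ## respiratory) primary diagnosis on their routine visits
  office_dx <- ifelse(no_ipf, "J96.00", "J84.112")
  mt <- tibble(patient_id, mu, fu_off = end_off, m_total, office_dx) |>
    uncount(.data$m_total, .id = "month")
  mm <- nrow(mt)
  med_mu <- (1 - cfg$drug_cost_share) * mt$mu
  M <- rgamma(mm, shape = cfg$cost_shape, rate = cfg$cost_shape / med_mu)
  ## medical cost accrues daily: a final partial month carries a
  ## proportional share, so short follow-up does not inflate per-month cost
  ms_frac <- 30L * (mt$month - 1L)
  M <- M * (pmin(ms_frac + 29L, mt$fu_off) - ms_frac + 1L) / 30
  ed <- runif(mm) < 0.07
  ip <- runif(mm) < 0.02
  ip_resp <- runif(mm) < 0.5
  los_ip <- 3L + as.integer(floor(runif(mm) * 5))
  rem <- 1 - 0.5 * ip - 0.2 * ed
  ms <- 30L * (mt$month - 1L)
  month_rows <- bind_rows(
    tibble(patient_id = mt$patient_id, day = pmin(ms + 10L, mt$fu_off),
           dx = mt$office_dx, setting = "office", paid = 0.6 * rem * M,
           los = 1L),
    tibble(patient_id = mt$patient_id, day = pmin(ms + 20L, mt$fu_off),
           dx = "I10", setting = "other_outpatient", paid = 0.4 * rem * M,
           los = 1L),
    tibble(patient_id = mt$patient_id[ed], day = pmin(ms + 15L, mt$fu_off)[ed],
           dx = "J18.9", setting = "emergency", paid = (0.2 * M)[ed],
           los = 1L),
    tibble(patient_id = mt$patient_id[ip], day = pmin(ms + 5L, mt$fu_off)[ip],
           dx = ifelse(ip_resp, "J96.00", "I21.4")[ip],
           setting = "inpatient", paid = (0.5 * M)[ip], los = los_ip[ip])
  ) |>
    mutate(claim_type = "standard", proc = NA_character_,
           death = FALSE, ild_center = FALSE)

  fill_paid <- cfg$drug_cost_share *
    rgamma(nrow(kept), shape = cfg$cost_shape,
           rate = cfg$cost_shape /
             (mu[match(kept$patient_id, patient_id)]))
  pharmacy <- kept |>
    mutate(drug = ifelse(.data$arm_a, cc$drug_a, cc$drug_b),
           days_supply = supply, paid = fill_paid) |>
    select("patient_id", "day", "drug", "days_supply", "quantity", "paid")

  has_reinit <- !is.na(reinit_day)
  reinit_rows <- bind_rows(
    tibble(patient_id = patient_id[has_reinit], day = reinit_day[has_reinit]),
    tibble(patient_id = patient_id[has_reinit],
           day = reinit_day[has_reinit] + 31L)
  ) |>
    left_join(tibble(patient_id, arm_a, fu_off = end_off, mu),
              by = "patient_id") |>
    filter(.data$day <= .data$fu_off) |>
    mutate(drug = as.character(ifelse(.data$arm_a, cc$drug_a, cc$drug_b)),
           days_supply = supply,
           quantity = as.integer(ifelse(.data$arm_a, 270L, 60L)))
  reinit_rows$paid <- cfg$drug_cost_share *
    rgamma(nrow(reinit_rows), shape = cfg$cost_shape,
           rate = cfg$cost_shape / reinit_rows$mu)

  has_switch <- !is.na(switch_day)
  switch_rows <- tibble(patient_id = patient_id[has_switch],
                        day = switch_day[has_switch],
                        drug = as.character(ifelse(arm_a[has_switch],
                                                   cc$drug_b, cc$drug_a)),
                        days_supply = supply,
                        quantity = as.integer(ifelse(arm_a[has_switch],
                                                     60L, 207L)))
  switch_rows$paid <- cfg$drug_cost_share *
    rgamma(nrow(switch_rows), shape = cfg$cost_shape,
           rate = cfg$cost_shape / mu[has_switch])

  op_rows <- tibble(patient_id = patient_id[opioid],
                    day = opioid_day[opioid], drug = "oxycodone",
                    days_supply = 30L, quantity = 60L)
  op_rows$paid <- rgamma(nrow(op_rows), shape = 2, rate = 2 / 60)

  baseline_med$paid <- rgamma(nrow(baseline_med), shape = 2, rate = 2 / 150)
  ild_rows$paid <- rgamma(nrow(ild_rows), shape = 2, rate = 2 / 200)
  oxy_rows$paid <- rgamma(nrow(oxy_rows), shape = 2, rate = 2 / 300)

  tx_rows <- tibble(patient_id = patient_id[!is.na(transplant_day)],
                    day = transplant_day[!is.na(transplant_day)],
                    dx = "J84.112", setting = "inpatient",
                    claim_type = "standard", proc = "33935",
                    death = FALSE, ild_center = FALSE, los = 12L)
  tx_rows$paid <- rgamma(nrow(tx_rows), shape = 3, rate = 3 / 150000)

  death_rows <- tibble(patient_id = patient_id[died_obs],
                       day = pmax(death_off[died_obs] - 3L, 0L),
                       dx = "J96.00", setting = "inpatient",
                       claim_type = "standard", proc = NA_character_,
                       death = TRUE, ild_center = FALSE, los = 4L)
  death_rows$paid <- rgamma(nrow(death_rows), shape = 2, rate = 2 / 30000)

  oth_ild_rows <- tibble(patient_id = patient_id[other_ild],
                         day = 10L, dx = "D86.0", setting = "office",
                         claim_type = "standard", proc = NA_character_,
                         death = FALSE, ild_center = FALSE, los = 1L)
  oth_ild_rows$paid <- rgamma(nrow(oth_ild_rows), shape = 2, rate = 2 / 150)

  ## ---- assemble calendar tables ----
  idx <- tibble(patient_id, index_date)
  to_dates <- function(df) {
    df |>
      left_join(idx, by = "patient_id") |>
      mutate(svc_start = .data$index_date + .data$day,
             svc_end = .data$svc_start + .data$los - 1L) |>
      select(-"index_date", -"day", -"los")
  }
  medical <- bind_rows(baseline_med, ild_rows, oxy_rows, month_rows,
                       tx_rows, death_rows, oth_ild_rows) |>
    to_dates() |>
    select("patient_id", "svc_start", "svc_end", "setting", "claim_type",
           "dx", "proc", "death", "ild_center", "paid")

  pharmacy <- bind_rows(
    pharmacy |> select("patient_id", "day", "drug", "days_supply",
                       "quantity", "paid"),
    reinit_rows |> select("patient_id", "day", "drug", "days_supply",
                          "quantity", "paid"),
    switch_rows, op_rows
  ) |>
    left_join(idx, by = "patient_id") |>
    mutate(service_date = .data$index_date + .data$day) |>
    select("patient_id", "service_date", "drug", "days_supply",
           "quantity", "paid")

  ## emit nominal-year dollars so CPI inflation restores 2017 dollars exactly
  cpi <- default_cpi_table()
  defl <- function(paid, date) {
    paid * cpi$cpi[match(year_of(date), cpi$year)] /
      cpi$cpi[match(2017L, cpi$year)]
  }
  medical$paid <- defl(medical$paid, medical$svc_start)
  pharmacy$paid <- defl(pharmacy$paid, pharmacy$service_date)

  medical <- medical |> arrange(.data$patient_id, .data$svc_start,
                                .data$setting, .data$dx)
  pharmacy <- pharmacy |> arrange(.data$patient_id, .data$service_date,
                                  .data$drug)

  enrollment <- tibble(
    patient_id,
    start = index_date - pre_days,
    end = index_date + end_off,
    birth_year, sex = as.character(covs$sex), region
  )

  ground_truth <- tibble(
    patient_id, arm = drug, propensity = as.numeric(propensity),
    true_disc_day, true_monthly_cost = mu,
    switch_day, transplant_day, reinit_day,
    index_date, fu_days = end_off
  )

  structure(list(enrollment = enrollment, pharmacy = pharmacy,
                 medical = medical, ground_truth = ground_truth,
                 config = cfg),
            class = "claims_tables")
}

#' @export
print.claims_tables <- function(x, ...) {
  cat("<claims_tables>\n")
  cat(sprintf("  %d patients | %d pharmacy claims | %d medical claims\n",
              nrow(x$enrollment), nrow(x$pharmacy), nrow(x$medical)))
  invisible(x)
}

claims_specs <- function() {
  list(
    enrollment = readr::cols(
      patient_id = readr::col_character(), start = readr::col_date(),
      end = readr::col_date(), birth_year = readr::col_integer(),
      sex = readr::col_character(), region = readr::col_character()
    ),
    pharmacy = readr::cols(
      patient_id = readr::col_character(),
      service_date = readr::col_date(), drug = readr::col_character(),
      days_supply = readr::col_integer(), quantity = readr::col_integer(),
      paid = readr::col_double()
    ),
    medical = readr::cols(
      patient_id = readr::col_character(), svc_start = readr::col_date(),
      svc_end = readr::col_date(), setting = readr::col_character(),
      claim_type = readr::col_character(), dx = readr::col_character(),
      proc = readr::col_character(), death = readr::col_logical(),
      ild_center = readr::col_logical(), paid = readr::col_double()
    ),
    ground_truth = readr::cols(
      patient_id = readr::col_character(), arm = readr::col_character(),
      propensity = readr::col_double(), true_disc_day = readr::col_integer(),
      true_monthly_cost = readr::col_double(),
      switch_day = readr::col_integer(),
      transplant_day = readr::col_integer(),
      reinit_day = readr::col_integer(), index_date = readr::col_date(),
      fu_days = readr::col_integer()
    )
  )
}

#' Write and read claims tables as CSV
#'
#' `write_claims()` writes `enrollment.csv`, `pharmacy.csv`, `medical.csv` and
#' (when present) `ground_truth.csv` into a directory as UTF-8 comma-separated
#' files with ISO-8601 dates; `read_claims()` reads them back. The round trip
#' reproduces the tables exactly, including dates and full double precision.
#'
#' @param tables A `claims_tables` object or a plain named list of the tables.
#' @param directory Directory to write into (created if needed) / read from.
#' @return `write_claims()` returns the directory invisibly; `read_claims()`
#'   returns a `claims_tables` list.
#' @export
write_claims <- function(tables, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("enrollment", "pharmacy", "medical", "ground_truth")) {
    if (!is.null(tables[[nm]])) {
      readr::write_csv(tables[[nm]], file.path(directory, paste0(nm, ".csv")),
                       na = "")
    }
  }
  invisible(directory)
}

#' @rdname write_claims
#' @export
read_claims <- function(directory) {
  specs <- claims_specs()
  out <- list()
  for (nm in names(specs)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm == "ground_truth") next
      abort(sprintf("missing claims file: %s", path))
    }
    tab <- readr::read_csv(path, col_types = specs[[nm]], na = "",
                           progress = FALSE)
    probs <- readr::problems(tab)
    if (nrow(probs) > 0) {
      abort(sprintf("parse error in %s at row %d, column %d: expected %s",
                    basename(path), probs$row[1], probs$col[1],
                    probs$expected[1]))
    }
    out[[nm]] <- tab
  }
  structure(out, class = "claims_tables")
}
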