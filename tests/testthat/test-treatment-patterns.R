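test_that("titration adds 7 days except for the 207-pill/30-day pack", {
  expect_equal(adjust_titration(30L, 90L, "pirfenidone"), 37L)
  expect_equal(adjust_titration(30L, 207L, "pirfenidone"), 30L)
  expect_equal(adjust_titration(30L, 60L, "nintedanib"), 30L)
  expect_equal(adjust_titration(45L, 207L, "pirfenidone"), 52L)  # not 30-day
})

test_that("coverage timelines append overlapping supply", {
  tl <- build_timeline(0L, 30L)
  expect_equal(as.data.frame(tl), data.frame(start = 0L, end = 29L))
  tl2 <- build_timeline(c(0L, 20L), c(30L, 30L))
  expect_equal(as.data.frame(tl2), data.frame(start = 0L, end = 59L))
  tl3 <- build_timeline(c(0L, 90L), c(30L, 30L))
  expect_equal(tl3$start, c(0L, 90L))
  expect_equal(tl3$end, c(29L, 119L))
  # same-day duplicate fills are summed into one fill
  tl4 <- build_timeline(c(0L, 0L), c(10L, 5L))
  expect_equal(tl4$end, 14L)
  # presentation order of fills does not matter
  tl5 <- build_timeline(c(90L, 0L), c(30L, 30L))
  expect_identical(as.data.frame(tl5), as.data.frame(tl3))
})

test_that("pdc counts inclusive days and truncates at 1", {
  full <- build_timeline(0L, 100L)
  expect_equal(compute_pdc(full, 0L, 99L), 1.0)
  part <- build_timeline(0L, 60L)
  expect_equal(compute_pdc(part, 0L, 89L), 60 / 90)
  # appended supply overrunning the window truncates to exactly 1
  over <- build_timeline(c(0L, 10L, 20L), c(30L, 30L, 30L))
  expect_identical(compute_pdc(over, 0L, 59L), 1.0)
  expect_error(compute_pdc(full, 10L, 9L), "window")
})

test_that("adherence uses a strict 0.8 threshold by default, >= on request", {
  expect_true(classify_adherent(0.81))
  expect_false(classify_adherent(0.80))
  expect_true(classify_adherent(0.80, rule = "ge"))
  expect_true(classify_adherent(1.0))
})

test_that("discontinuation is the last covered day before the first 60-day gap", {
  tl <- build_timeline(c(0L, 90L), c(30L, 30L))  # gap days 30-89 = 60 days
  expect_equal(detect_discontinuation(tl, 365L), 29L)
  tl2 <- build_timeline(c(0L, 85L), c(30L, 30L))  # 55-day internal gap
  expect_equal(detect_discontinuation(tl2, 170L), NA_integer_)
  # but a long enough trailing gap after the last fill still qualifies
  expect_equal(detect_discontinuation(tl2, 174L), 114L)
  # trailing gap to follow-up end
  one <- build_timeline(0L, 30L)
  expect_equal(detect_discontinuation(one, 89L), 29L)
  expect_equal(detect_discontinuation(one, 88L), NA_integer_)
})

test_that("a transplant before the gap completes cancels discontinuation", {
  tl <- build_timeline(c(0L, 90L), c(30L, 30L))
  expect_equal(detect_discontinuation(tl, 365L, transplant_date = 70L),
               NA_integer_)
  # the 60th uncovered day is day 89; a transplant that day does not cancel
  expect_equal(detect_discontinuation(tl, 365L, transplant_date = 89L), 29L)
  expect_equal(detect_discontinuation(tl, 365L, transplant_date = 88L),
               NA_integer_)
})

test_that("switch date is the earliest alternate-drug fill", {
  expect_equal(detect_switch(integer()), NA_integer_)
  expect_equal(detect_switch(200L), 200L)
  expect_equal(detect_switch(c(300L, 150L)), 150L)
})

test_that("episodes combine events with documented tie-breaking", {
  tl <- build_timeline(c(0L, 90L), c(30L, 30L))
  ep <- build_episode(tl, 365L, index_drug_fill_dates = c(0L, 90L))
  expect_equal(ep$discontinuation_day, 29L)
  expect_equal(ep$reinitiation_day, 90L)
  expect_equal(ep$days_to_reinitiation, 61L)
  expect_equal(ep$persistence_reason, "discontinued")
  # switch before a later discontinuation ends persistence at the switch
  tl2 <- build_timeline(c(0L, 30L, 60L, 90L, 120L, 150L), rep(30L, 6))
  ep2 <- build_episode(tl2, 400L, switch_date = 150L,
                       index_drug_fill_dates = seq(0L, 150L, 30L))
  expect_equal(ep2$persistence_reason, "switched")
  expect_equal(ep2$persistence_end, 150L)
  # no events: censored at follow-up end
  ep3 <- build_episode(build_timeline(0L, 500L), 400L,
                       index_drug_fill_dates = 0L)
  expect_equal(ep3$persistence_reason, "censored")
  expect_equal(ep3$persistence_end, 400L)
  # same-day tie: transplant outranks switch outranks discontinuation
  ep4 <- build_episode(tl, 365L, switch_date = 29L, transplant_date = 29L,
                       index_drug_fill_dates = c(0L, 90L))
  expect_equal(ep4$persistence_reason, "transplant")
  expect_error(build_episode(tl, 365L, switch_date = -5L), "event")
})

test_that("pdc and discontinuation agree exactly with the day-marking oracle", {
  set.seed(77)
  for (i in 1:1000) {
    p <- random_fill_pattern()
    tl <- build_timeline(p$dates, p$supplies)
    pdc <- compute_pdc(tl, 0L, p$fu)
    expect_identical(pdc, oracle_pdc(p$dates, p$supplies, p$fu))
    expect_true(pdc >= 0 && pdc <= 1)
    expect_identical(detect_discontinuation(tl, p$fu),
                     oracle_disc(p$dates, p$supplies, p$fu))
  }
})

test_that("pdc is non-decreasing when a fill is added", {
  set.seed(78)
  for (i in 1:200) {
    p <- random_fill_pattern()
    base <- compute_pdc(build_timeline(p$dates, p$supplies), 0L, p$fu)
    extra <- compute_pdc(build_timeline(c(p$dates, sample(0:300, 1)),
                                        c(p$supplies, sample(1:40, 1))),
                         0L, p$fu)
    expect_gte(extra, base)
  }
})

test_that("the discontinuation date is always a covered day", {
  set.seed(79)
  for (i in 1:200) {
    p <- random_fill_pattern()
    tl <- build_timeline(p$dates, p$supplies)
    d <- detect_discontinuation(tl, p$fu)
    if (!is.na(d)) {
      expect_true(any(tl$start <= d & tl$end >= d))
    }
  }
})

test_that("the cohort driver matches the per-patient operations", {
  set.seed(80)
  cohort <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:40),
    index_date = as.Date("2016-01-01"),
    index_drug = sample(c("pirfenidone", "nintedanib"), 40, TRUE),
    follow_up_end = as.Date("2016-01-01") + sample(200:420, 40, TRUE)
  )
  rx <- purrr::map_dfr(1:40, function(i) {
    k <- sample(1:6, 1)
    mk_rx(cohort$patient_id[i],
          cohort$index_date[i] + c(0L, sort(sample(1:400, k - 1))),
          drug = cohort$index_drug[i],
          days_supply = sample(c(15L, 30L), k, TRUE),
          quantity = sample(c(90L, 207L, 270L), k, TRUE))
  })
  # a few alternate-drug fills
  alt <- mk_rx(cohort$patient_id[1:8],
               cohort$index_date[1:8] + sample(30:300, 8),
               drug = ifelse(cohort$index_drug[1:8] == "pirfenidone",
                             "nintedanib", "pirfenidone"))
  eps <- treatment_patterns(cohort, dplyr::bind_rows(rx, alt))
  for (i in 1:40) {
    pid <- cohort$patient_id[i]
    fu <- as.integer(cohort$follow_up_end[i] - cohort$index_date[i])
    mine <- rx |> dplyr::filter(patient_id == pid,
                                service_date <= cohort$follow_up_end[i])
    days <- as.integer(mine$service_date - cohort$index_date[i])
    sup <- mine$days_supply
    o <- order(days)
    days <- days[o]; sup <- sup[o]; qty <- mine$quantity[o]
    sup[1] <- adjust_titration(sup[1], qty[1], cohort$index_drug[i])
    tl <- build_timeline(days, sup)
    sw <- alt |> dplyr::filter(patient_id == pid,
                               service_date <= cohort$follow_up_end[i])
    ep <- build_episode(
      tl, fu,
      switch_date = if (nrow(sw)) as.integer(min(sw$service_date) -
                                               cohort$index_date[i])
                    else NA_integer_,
      index_drug_fill_dates = days)
    row <- eps[eps$patient_id == pid, ]
    expect_equal(row$pdc, ep$pdc)
    expect_equal(row$discontinuation_day, ep$discontinuation_day)
    expect_equal(row$switch_day, ep$switch_day)
    expect_equal(row$persistence_end, ep$persistence_end)
    expect_equal(row$persistence_reason, ep$persistence_reason)
    expect_equal(row$reinitiation_day, ep$reinitiation_day)
  }
})

test_that("re-initiation is never earlier than 61 days after discontinuation", {
  for (s in c(4, 5)) {
    tabs <- simulate_claims(claims_config(n_patients = 600, seed = s,
                                          reinit_frac = 0.5))
    an <- prepare_analysis(tabs)
    r <- an$days_to_reinitiation
    expect_true(all(is.na(r) | r >= 61L))
    expect_gt(sum(!is.na(r)), 20)
  }
})
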