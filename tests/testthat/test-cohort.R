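test_that("selection cascade keeps qualifying patients and records reasons", {
  tabs <- fixture_selection_tables()
  coh <- select_cohort(tabs$enrollment, tabs$pharmacy, tabs$medical)
  expect_setequal(coh$patient_id, paste0("ok", 1:5))
  ex <- attr(coh, "exclusions")
  expect_equal(ex$reason[ex$patient_id == "x_noidx"], "no_index_claim")
  expect_equal(ex$reason[ex$patient_id == "x_age"], "age")
  expect_equal(ex$reason[ex$patient_id == "x_enr"], "enrollment")
  expect_equal(ex$reason[ex$patient_id == "x_ipf"], "no_ipf_claim")
  expect_equal(ex$reason[ex$patient_id == "x_ild"], "other_ild")
  att <- attrition(coh)
  expect_equal(sum(att$excluded) + nrow(coh),
               dplyr::n_distinct(tabs$enrollment$patient_id))
  expect_equal(att$remaining[nrow(att)], nrow(coh))
})

test_that("age 39 at index is excluded; age 40 retained", {
  tabs <- fixture_selection_tables()
  born_77 <- tabs$enrollment |>
    dplyr::mutate(birth_year = ifelse(patient_id == "ok1", 1977L, birth_year))
  coh <- select_cohort(born_77, tabs$pharmacy, tabs$medical)
  expect_false("ok1" %in% coh$patient_id)  # 2016 - 1977 = 39
  born_76 <- tabs$enrollment |>
    dplyr::mutate(birth_year = ifelse(patient_id == "ok1", 1976L, birth_year))
  coh2 <- select_cohort(born_76, tabs$pharmacy, tabs$medical)
  expect_true("ok1" %in% coh2$patient_id)
})

test_that("a sarcoidosis code after index excludes the patient", {
  tabs <- fixture_selection_tables()
  ex <- attr(select_cohort(tabs$enrollment, tabs$pharmacy, tabs$medical),
             "exclusions")
  expect_equal(ex$reason[ex$patient_id == "x_ild"], "other_ild")
  # the same code strictly before index does not exclude
  med <- dplyr::bind_rows(
    tabs$medical |> dplyr::filter(patient_id != "x_ild" | dx != "D86.0"),
    mk_med("x_ild", "2015-12-01", dx = "D86.0"))
  coh <- select_cohort(tabs$enrollment, tabs$pharmacy, med)
  expect_true("x_ild" %in% coh$patient_id)
})

test_that("diagnosis-only (lab/radiology) claims do not satisfy the IPF rule", {
  tabs <- fixture_selection_tables()
  med <- tabs$medical |>
    dplyr::mutate(claim_type = ifelse(patient_id == "ok2", "lab", claim_type))
  coh <- select_cohort(tabs$enrollment, tabs$pharmacy, med)
  expect_false("ok2" %in% coh$patient_id)
  ex <- attr(coh, "exclusions")
  expect_equal(ex$reason[ex$patient_id == "ok2"], "no_ipf_claim")
})

test_that("overlapping enrollment spans raise a data-quality error", {
  tabs <- fixture_selection_tables()
  enr <- dplyr::bind_rows(tabs$enrollment,
                          mk_enroll("ok1", "2015-01-01", "2015-06-01"))
  expect_error(select_cohort(enr, tabs$pharmacy, tabs$medical), "overlap")
})

test_that("generator output with exclusion features disabled is fully retained", {
  tabs <- simulate_claims(claims_config(n_patients = 300, seed = 8))
  coh <- select_cohort(tabs$enrollment, tabs$pharmacy, tabs$medical)
  expect_equal(nrow(coh), 300)
  # and seeded exclusion testers are removed for the right reasons
  tabs2 <- simulate_claims(claims_config(n_patients = 400, seed = 8,
                                         other_ild_frac = 0.1,
                                         underage_frac = 0.1,
                                         no_ipf_frac = 0.1,
                                         short_enrollment_frac = 0.1))
  coh2 <- select_cohort(tabs2$enrollment, tabs2$pharmacy, tabs2$medical)
  att <- attrition(coh2)
  expect_equal(sum(att$excluded) + nrow(coh2), 400)
  expect_true(all(att$excluded[att$step != "no_index_claim"] > 0))
})

test_that("follow-up end is the earliest of death, disenrollment, cutoff", {
  coh <- tibble::tibble(patient_id = c("a", "b"),
                        index_date = as.Date("2016-01-01"),
                        index_drug = "pirfenidone", birth_year = 1950L,
                        sex = "M", region = "South",
                        enroll_start = as.Date("2014-01-01"),
                        enroll_end = as.Date("2016-01-01") + c(100L, 80L))
  med <- mk_med("b", "2016-02-17", setting = "inpatient", death = TRUE,
                end = "2016-02-20")  # death day 50
  fu_a <- assign_followup(coh[1, ], med[0, ])
  expect_equal(as.integer(fu_a$follow_up_end - fu_a$index_date), 100L)
  expect_equal(fu_a$end_reason, "disenrollment")
  fu_b <- assign_followup(coh[2, ], med)
  expect_equal(as.integer(fu_b$follow_up_end - fu_b$index_date), 50L)
  expect_equal(fu_b$end_reason, "inpatient_death")
})

test_that("fixed 12-month dataset needs a year of adjudicated post-index data", {
  mk <- function(index, enroll_end) {
    tibble::tibble(patient_id = "a", index_date = as.Date(index),
                   index_drug = "pirfenidone", birth_year = 1950L,
                   sex = "M", region = "South",
                   enroll_start = as.Date("2013-01-01"),
                   enroll_end = as.Date(enroll_end))
  }
  med0 <- mk_med("zz", "2010-01-01")[0, ]
  # index 300 days before the fixed cutoff: kept for treatment patterns,
  # dropped from the fixed 12-month dataset
  late <- mk("2015-12-05", "2018-06-30")
  expect_equal(nrow(assign_followup(late, med0, "treatment_patterns")), 1L)
  expect_equal(nrow(assign_followup(mk("2016-12-05", "2018-06-30"), med0,
                                    "fixed_12m")), 0L)
  # short post-index enrollment also disqualifies
  expect_equal(nrow(assign_followup(mk("2015-12-05", "2016-06-30"), med0,
                                    "fixed_12m")), 0L)
  ok <- assign_followup(mk("2015-12-05", "2017-06-30"), med0, "fixed_12m")
  expect_equal(nrow(ok), 1L)
  expect_equal(as.integer(ok$follow_up_end - ok$index_date), 364L)
  # variable-cost dataset censors at the adjudicated-claims cutoff
  vc <- assign_followup(mk("2017-08-01", "2018-06-30"), med0,
                        "variable_cost")
  expect_equal(vc$follow_up_end, as.Date("2017-09-30"))
  expect_equal(nrow(assign_followup(mk("2017-10-15", "2018-06-30"), med0,
                                    "variable_cost")), 0L)
})

test_that("unknown dataset labels are rejected", {
  tabs <- fixture_selection_tables()
  coh <- select_cohort(tabs$enrollment, tabs$pharmacy, tabs$medical)
  expect_error(assign_followup(coh, tabs$medical, "weekly"), "arg")
})
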