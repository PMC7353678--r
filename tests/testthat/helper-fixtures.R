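# Hand-built miniature claims tables used by the cohort tests.

mk_enroll <- function(id, start, end, birth_year = 1950, sex = "M",
                      region = "South") {
  tibble::tibble(patient_id = id, start = as.Date(start), end = as.Date(end),
                 birth_year = birth_year, sex = sex, region = region)
}

mk_rx <- function(id, date, drug = "pirfenidone", days_supply = 30L,
                  quantity = 207L, paid = 8000) {
  tibble::tibble(patient_id = id, service_date = as.Date(date), drug = drug,
                 days_supply = as.integer(days_supply),
                 quantity = as.integer(quantity), paid = paid)
}

mk_med <- function(id, date, dx = "J84.112", setting = "office",
                   claim_type = "standard", proc = NA_character_,
                   death = FALSE, ild_center = FALSE, paid = 150,
                   end = date) {
  tibble::tibble(patient_id = id, svc_start = as.Date(date),
                 svc_end = as.Date(end), setting = setting,
                 claim_type = claim_type, dx = dx, proc = proc,
                 death = death, ild_center = ild_center, paid = paid)
}

or_2x2 <- function(n_a1, n_a0, n_b1, n_b0) {
  tibble::tibble(
    index_drug = rep(c("pirfenidone", "nintedanib"),
                     c(n_a1 + n_a0, n_b1 + n_b0)),
    adherent = c(rep(c(TRUE, FALSE), c(n_a1, n_a0)),
                 rep(c(TRUE, FALSE), c(n_b1, n_b0))))
}

# one violation each of the five selection rules plus five clean patients
fixture_selection_tables <- function() {
  ok_ids <- paste0("ok", 1:5)
  enrollment <- dplyr::bind_rows(
    mk_enroll(ok_ids, "2014-01-01", "2018-06-30"),
    mk_enroll("x_noidx", "2014-01-01", "2018-06-30"),
    mk_enroll("x_age", "2014-01-01", "2018-06-30", birth_year = 1980),
    mk_enroll("x_enr", "2015-12-01", "2018-06-30"),
    mk_enroll("x_ipf", "2014-01-01", "2018-06-30"),
    mk_enroll("x_ild", "2014-01-01", "2018-06-30")
  )
  with_idx <- c(ok_ids, "x_age", "x_enr", "x_ipf", "x_ild")
  pharmacy <- mk_rx(with_idx, "2016-01-10")
  medical <- dplyr::bind_rows(
    mk_med(c(ok_ids, "x_age", "x_enr", "x_ild"), "2015-06-01"),
    mk_med("x_enr", "2016-02-01"),
    mk_med("x_ild", "2016-01-20", dx = "D86.0")
  )
  list(enrollment = enrollment, pharmacy = pharmacy, medical = medical)
}
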