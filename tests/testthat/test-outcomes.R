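test_that("unit-weight 2x2 logistic equals the cross-product odds ratio", {
  df <- or_2x2(50, 50, 25, 75)
  fit <- fit_weighted_logistic(df)
  expect_equal(fit$estimate, (50 * 75) / (50 * 25), tolerance = 1e-6)
  # constant weights do not move the estimate
  fit_c <- fit_weighted_logistic(df, weights = rep(2.7, nrow(df)))
  expect_equal(fit_c$estimate, fit$estimate, tolerance = 1e-8)
  # unit weights match the classical unweighted glm point estimate
  ref <- glm(adherent ~ I(index_drug == "pirfenidone"), binomial, df)
  expect_equal(log(fit$estimate), unname(coef(ref)[2]), tolerance = 1e-8)
  expect_error(fit_weighted_logistic(df, weights = rep(-1, nrow(df))),
               "positive")
})

test_that("perfectly separated adherence data raise an error", {
  df <- or_2x2(50, 0, 0, 50)
  expect_error(suppressWarnings(fit_weighted_logistic(df)), "separation")
})

test_that("weighted cox matches a hand-maximized partial likelihood", {
  df <- tibble::tibble(
    index_drug = c("pirfenidone", "pirfenidone", "nintedanib", "nintedanib"),
    time = c(2, 10, 5, 12),
    event = c(1L, 1L, 1L, 0L))
  fit <- fit_weighted_cox(df, time = "time", event = "event")
  # partial likelihood written out by hand for this ordering of events
  nll <- function(b) {
    th <- exp(b)
    -(log(th / (2 * th + 2)) + log(1 / (th + 2)) + log(th / (th + 1)))
  }
  b_hat <- optimize(nll, c(-5, 5))$minimum
  expect_equal(log(fit$estimate), b_hat, tolerance = 1e-4)
  # unit weights match the reference unweighted coxph
  ref <- survival::coxph(survival::Surv(time, event) ~
                           I(index_drug == "pirfenidone"), data = df,
                         ties = "efron")
  expect_equal(log(fit$estimate), unname(coef(ref)), tolerance = 1e-8)
  # an arm without events is not estimable
  df0 <- df |> dplyr::mutate(event = c(1L, 1L, 0L, 0L))
  expect_error(fit_weighted_cox(df0, time = "time", event = "event"),
               "events")
})

test_that("weighted KM curves are proper survival curves", {
  tabs <- simulate_claims(claims_config(n_patients = 400, seed = 44))
  an <- add_iptw(prepare_analysis(tabs))
  fit <- fit_weighted_cox(an, weights = an$iptw)
  km <- km_curves(fit)
  expect_setequal(unique(km$arm), c("pirfenidone", "comparator"))
  for (a in unique(km$arm)) {
    s <- km$surv[km$arm == a]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("intercept-only gamma glm predicts the weighted mean cost", {
  set.seed(9)
  df <- tibble::tibble(
    index_drug = rep(c("pirfenidone", "nintedanib"), each = 60),
    cost = rgamma(120, 2, rate = 2 / 9000))
  w <- runif(120, 0.5, 2)
  fit <- fit_cost_glm(df, "cost", weights = w)
  # saturated-in-treatment model: fitted arm means are weighted arm means
  rp <- recycled_prediction(fit)
  a <- df$index_drug == "pirfenidone"
  expect_equal(rp$predicted_mean[rp$arm == "pirfenidone"],
               weighted.mean(df$cost[a], w[a]), tolerance = 1e-8)
  expect_equal(rp$predicted_mean[rp$arm == "comparator"],
               weighted.mean(df$cost[!a], w[!a]), tolerance = 1e-8)
  # covariate-free model: predictions differ exactly by the fitted ratio
  expect_equal(rp$predicted_mean[1] / rp$predicted_mean[2], fit$estimate,
               tolerance = 1e-8)
})

test_that("scaling costs shifts the intercept, not the ratio", {
  set.seed(10)
  df <- tibble::tibble(
    index_drug = rep(c("pirfenidone", "nintedanib"), each = 50),
    copd = sample(c(TRUE, FALSE), 100, TRUE),
    cost = rgamma(100, 2, rate = 2 / 9000))
  f1 <- fit_cost_glm(df, "cost", covariates = "copd")
  f2 <- fit_cost_glm(df |> dplyr::mutate(cost = cost * 3.5), "cost",
                     covariates = "copd")
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-8)
  expect_equal(coef(f2$model)[["(Intercept)"]],
               coef(f1$model)[["(Intercept)"]] + log(3.5), tolerance = 1e-8)
  expect_error(fit_cost_glm(df |> dplyr::mutate(cost = cost * 0), "cost"),
               "zero-cost")
})

test_that("duplicating rows with halved weights leaves predictions unchanged", {
  set.seed(11)
  df <- tibble::tibble(
    index_drug = rep(c("pirfenidone", "nintedanib"), each = 40),
    copd = sample(c(TRUE, FALSE), 80, TRUE),
    cost = rgamma(80, 2, rate = 2 / 9000))
  w <- runif(80, 0.5, 2)
  f1 <- recycled_prediction(fit_cost_glm(df, "cost", covariates = "copd",
                                         weights = w))
  f2 <- recycled_prediction(fit_cost_glm(dplyr::bind_rows(df, df), "cost",
                                         covariates = "copd",
                                         weights = c(w, w) / 2))
  expect_equal(f2$predicted_mean, f1$predicted_mean, tolerance = 1e-8)
})

test_that("bootstrap intervals are deterministic and honest about failures", {
  set.seed(12)
  df <- tibble::tibble(x = rnorm(80, 10))
  b1 <- bootstrap_ci(df, function(d) c(m = mean(d$x)), B = 200, seed = 7)
  b2 <- bootstrap_ci(df, function(d) c(m = mean(d$x)), B = 200, seed = 7)
  expect_identical(b1, b2)
  expect_true(b1$conf.low <= b1$estimate & b1$estimate <= b1$conf.high)
  # a constant statistic has a zero-width interval
  b3 <- bootstrap_ci(df, function(d) c(k = 5), B = 50, seed = 1)
  expect_equal(b3$conf.low, 5)
  expect_equal(b3$conf.high, 5)
  # too many failures abort; a few are dropped and counted
  flaky <- function(d) if (runif(1) < 0.5) stop("boom") else c(m = mean(d$x))
  expect_error(bootstrap_ci(df, flaky, B = 100, seed = 3), "failed")
  rare <- function(d) if (runif(1) < 0.03) stop("boom") else c(m = mean(d$x))
  set.seed(5)
  b4 <- bootstrap_ci(df, rare, B = 100, seed = 5)
  expect_lte(attr(b4, "n_failed"), 10)
})

test_that("full-pipeline bootstrap re-estimates weights inside replicates", {
  tabs <- simulate_claims(claims_config(n_patients = 500, seed = 55))
  an <- prepare_analysis(tabs)
  stat <- function(d) {
    d2 <- add_iptw(d)
    fit <- suppressWarnings(fit_weighted_logistic(d2, weights = d2$iptw))
    c(log_or = log(fit$estimate))
  }
  ci <- bootstrap_ci(an, stat, B = 30, seed = 9)
  expect_true(ci$conf.low < ci$estimate & ci$estimate < ci$conf.high)
  expect_identical(bootstrap_ci(an, stat, B = 30, seed = 9), ci)
})

test_that("bootstrap percentile interval for a mean has near-nominal coverage", {
  set.seed(13)
  hits <- vapply(1:100, function(i) {
    x <- tibble::tibble(v = rnorm(40, mean = 3, sd = 1))
    ci <- bootstrap_ci(x, function(d) c(m = mean(d$v)), B = 400, seed = i)
    ci$conf.low <= 3 && ci$conf.high >= 3
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1.0)
})

test_that("type-I error of the robust OR and HR tests is near 0.05", {
  set.seed(14)
  n <- 600
  rej_or <- vapply(1:1000, function(i) {
    df <- tibble::tibble(
      index_drug = rep(c("pirfenidone", "nintedanib"), each = n / 2),
      adherent = runif(n) < 0.5)
    fit_weighted_logistic(df)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej_or), 0.03)
  expect_lte(mean(rej_or), 0.07)
  set.seed(15)
  rej_hr <- vapply(1:1000, function(i) {
    df <- tibble::tibble(
      index_drug = rep(c("pirfenidone", "nintedanib"), each = 200),
      time = rexp(400), event = 1L)
    fit_weighted_cox(df, time = "time", event = "event")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej_hr), 0.03)
  expect_lte(mean(rej_hr), 0.07)
})

test_that("null adherence effect: weighted OR interval covers 1 across seeds", {
  covers <- vapply(1:40, function(s) {
    tabs <- simulate_claims(claims_config(n_patients = 1500, seed = 2000 + s,
                                          true_discontinuation_hr = 1.0))
    an <- add_iptw(prepare_analysis(tabs))
    fit <- suppressWarnings(
      fit_weighted_logistic(an, weights = an$iptw,
                            covariates = propensity_covariates()))
    fit$conf.low <= 1 && fit$conf.high >= 1
  }, logical(1))
  expect_gte(mean(covers), 0.9)
})
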