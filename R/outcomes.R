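new_outcome_fit <- function(estimand, estimate, conf.low, conf.high, p.value,
                            model, robust_vcov, n, treated, extra = list()) {
  structure(c(list(estimand = estimand, estimate = unname(estimate),
                   conf.low = unname(conf.low), conf.high = unname(conf.high),
                   p.value = unname(p.value), model = model,
                   robust_vcov = robust_vcov, n = n, treated = treated),
              extra),
            class = c(paste0(estimand, "_fit"), "outcome_fit"))
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("<%s> %s = %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d\n",
              class(x)[1L], x$estimand, x$estimate, x$conf.low, x$conf.high,
              x$p.value, x$n))
  invisible(x)
}

treat_indicator <- function(data, treatment, treated) {
  tr <- as.character(data[[treatment]])
  lev <- sort(unique(tr))
  if (length(lev) != 2L) abort("both treatment arms must be present")
  treated <- treated %||% (if ("pirfenidone" %in% lev) "pirfenidone" else lev[1L])
  if (!treated %in% lev) abort(sprintf("arm `%s` absent from data", treated))
  list(x = as.integer(tr == treated), treated = treated)
}

build_model_frame <- function(data, treatment, treated, covariates, weights) {
  ti <- treat_indicator(data, treatment, treated)
  covariates <- intersect(covariates %||% character(), names(data))
  df <- data[, covariates, drop = FALSE] |>
    mutate(across(dplyr::where(is.factor), droplevels))
  keep <- vapply(df, function(x) length(unique(x)) > 1L, logical(1))
  covariates <- covariates[keep[covariates]]
  df <- df[, covariates, drop = FALSE]
  df$.treat <- ti$x
  df$.w <- weights %||% rep(1, nrow(data))
  if (any(df$.w <= 0)) abort("weights must be positive")
  rhs <- paste(c(".treat", covariates), collapse = " + ")
  list(df = df, rhs = rhs, treated = ti$treated, covariates = covariates)
}

robust_summary <- function(model, df, level = 0.95) {
  V <- sandwich::vcovHC(model, type = "HC0")
  b <- coef(model)
  se <- sqrt(diag(V))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(term = names(b), estimate = b, robust_se = se,
         statistic = b / se, p.value = 2 * pnorm(-abs(b / se)),
         conf.low = b - z * se, conf.high = b + z * se)
}

#' IPTW-weighted logistic regression for treatment adherence
#'
#' Fits a weighted logistic model of a binary outcome (by default the
#' adherence flag) on treatment and covariates and reports the treated vs
#' comparator odds ratio with a robust (weight-aware, HC0 sandwich) 95%
#' confidence interval. With unit weights and no covariates this reduces to
#' the classical 2x2 odds ratio.
#'
#' @param data Analysis tibble.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param treatment,treated Treatment column and treated level.
#' @param covariates Optional adjustment covariate names.
#' @param weights IPTW weights (unit weights if `NULL`).
#' @return An `odds_ratio_fit` / `outcome_fit`; see [tidy.outcome_fit()].
#' @export
fit_weighted_logistic <- function(data, outcome = "adherent",
                                  treatment = "index_drug", treated = NULL,
                                  covariates = NULL, weights = NULL) {
  mf <- build_model_frame(data, treatment, treated, covariates, weights)
  df <- mf$df
  df$.y <- as.integer(as.logical(data[[outcome]]))
  fml <- as.formula(paste(".y ~", mf$rhs))
  ## quasibinomial: weights are sampling weights, not binomial denominators
  model <- glm(fml, data = df, family = quasibinomial(), weights = df$.w)
  if (!model$converged ||
      any(model$fitted.values < 1e-10 | model$fitted.values > 1 - 1e-10)) {
    abort("perfect separation (or non-convergence) in the adherence model")
  }
  rs <- robust_summary(model, df)
  row <- rs[rs$term == ".treat", ]
  new_outcome_fit("odds_ratio", exp(row$estimate), exp(row$conf.low),
                  exp(row$conf.high), row$p.value, model,
                  sandwich::vcovHC(model, type = "HC0"), nrow(df),
                  mf$treated, list(robust = rs))
}

#' IPTW-weighted Cox model for time to discontinuation or switch
#'
#' Fits a weighted Cox proportional-hazards model (Efron tie handling,
#' robust variance) of the persistence event time on treatment and optional
#' covariates, and attaches weighted Kaplan-Meier curves per arm. For the
#' composite endpoint the event is the earlier of discontinuation and
#' switching, with censoring at transplant or end of follow-up; the subgroup
#' analysis among non-switchers is obtained by filtering `data` first.
#'
#' @param data Analysis tibble.
#' @param time,event Column names of the event time (> 0) and 0/1 indicator.
#' @param treatment,treated,covariates,weights As in
#'   [fit_weighted_logistic()].
#' @return A `hazard_ratio_fit` / `outcome_fit` with a `curves` element
#'   (weighted KM coordinates; see [km_curves()]).
#' @export
fit_weighted_cox <- function(data, time = "persistence_time",
                             event = "event_disc_switch",
                             treatment = "index_drug", treated = NULL,
                             covariates = NULL, weights = NULL) {
  mf <- build_model_frame(data, treatment, treated, covariates, weights)
  df <- mf$df
  df$.time <- as.numeric(data[[time]])
  df$.event <- as.integer(data[[event]])
  if (any(df$.time <= 0)) abort("event times must be positive")
  ev_by_arm <- tapply(df$.event, df$.treat, sum)
  if (any(ev_by_arm == 0)) {
    abort("no events in one treatment arm; hazard ratio is not estimable")
  }
  fml <- as.formula(paste("survival::Surv(.time, .event) ~", mf$rhs))
  model <- survival::coxph(fml, data = df, weights = df$.w,
                           ties = "efron", robust = TRUE)
  sm <- summary(model)
  row <- sm$coefficients[".treat", ]
  se <- row[["robust se"]]
  b <- row[["coef"]]
  z <- qnorm(0.975)
  arm_lab <- ifelse(df$.treat == 1L, mf$treated, "comparator")
  kdf <- df
  kdf$.arm <- arm_lab
  sf <- survival::survfit(survival::Surv(.time, .event) ~ .arm,
                          data = kdf, weights = kdf$.w)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble(arm = sub("^\\.arm=", "", strata), time = sf$time,
                   n_risk = sf$n.risk, surv = sf$surv)
  class(curves) <- c("km_curves", class(curves))
  new_outcome_fit("hazard_ratio", exp(b), exp(b - z * se), exp(b + z * se),
                  2 * pnorm(-abs(b / se)), model, NULL, nrow(df),
                  mf$treated, list(curves = curves))
}

#' Weighted Kaplan-Meier coordinates from a Cox fit
#' @param fit A [fit_weighted_cox()] result.
#' @return A tibble `arm`, `time`, `n_risk`, `surv` (non-increasing per arm,
#'   starting from 1 at time 0).
#' @export
km_curves <- function(fit) fit$curves

#' Kaplan-Meier step plot
#' @param object A `km_curves` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curves <- function(object, ...) {
  base <- object |>
    group_by(.data$arm) |>
    dplyr::reframe(time = c(0, .data$time), surv = c(1, .data$surv))
  ggplot2::ggplot(base, ggplot2::aes(x = .data$time, y = .data$surv,
                                     colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days from index", y = "probability still on therapy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' IPTW-weighted gamma cost model (log link)
#'
#' Fits `cost ~ treatment + covariates` with a gamma family and log link, so
#' the exponentiated treatment coefficient is the adjusted treated vs
#' comparator mean-cost ratio. Costs must be strictly positive; zero costs
#' should be handled upstream (drop the rows, or add a small offset) — the
#' antifibrotic cohorts are structurally positive because every member has at
#' least one index-drug fill.
#'
#' @inheritParams fit_weighted_logistic
#' @param cost Name of the positive cost column (e.g. a PPPM total).
#' @return A `cost_ratio_fit` / `outcome_fit`; the exponentiated treatment
#'   coefficient is in `$estimate` with a robust CI. Use
#'   [recycled_prediction()] for per-arm predicted means.
#' @export
fit_cost_glm <- function(data, cost, treatment = "index_drug",
                         treated = NULL, covariates = NULL, weights = NULL) {
  y <- as.numeric(data[[cost]])
  if (any(is.na(y)) || any(y <= 0)) {
    abort(paste0("non-positive or missing costs in `", cost, "`; ",
                 "drop zero-cost rows or add a small offset before fitting ",
                 "(zero-cost policy)"))
  }
  mf <- build_model_frame(data, treatment, treated, covariates, weights)
  df <- mf$df
  df$.y <- y
  fml <- as.formula(paste(".y ~", mf$rhs))
  model <- glm(fml, data = df, family = Gamma(link = "log"),
               weights = df$.w)
  rs <- robust_summary(model, df)
  row <- rs[rs$term == ".treat", ]
  new_outcome_fit("cost_ratio", exp(row$estimate), exp(row$conf.low),
                  exp(row$conf.high), row$p.value, model,
                  sandwich::vcovHC(model, type = "HC0"), nrow(df),
                  mf$treated,
                  list(robust = rs, data = df, treatment = treatment))
}

#' Recycled (standardized) cost predictions per arm
#'
#' Sets every patient's treatment indicator to each arm in turn, predicts
#' from the fitted cost model on the response scale, and averages with the
#' model weights: covariate-adjusted mean cost per arm over the whole
#' cohort.
#'
#' @param fit A [fit_cost_glm()] result.
#' @return A tibble with `arm` (`treated` level and `"comparator"`) and
#'   `predicted_mean`.
#' @export
recycled_prediction <- function(fit) {
  df <- fit$data
  out <- purrr::map(c(1L, 0L), function(lvl) {
    nd <- df
    nd$.treat <- lvl
    tibble(arm = if (lvl == 1L) fit$treated else "comparator",
           predicted_mean = weighted.mean(
             predict(fit$model, newdata = nd, type = "response"), df$.w))
  })
  bind_rows(out)
}

#' Percentile bootstrap confidence intervals over patients
#'
#' Resamples patient rows with replacement, recomputes a statistic per
#' replicate (typically the whole pipeline: propensity fit, weights, outcome
#' model), and returns percentile confidence intervals. Replicates where the
#' statistic errors are dropped and counted; more than
#' `max_failure_frac * B` failures aborts.
#'
#' @param data Patient-level tibble to resample.
#' @param statistic Function `data -> named numeric vector`.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param conf Confidence level.
#' @param max_failure_frac Maximum tolerated fraction of failed replicates.
#' @return A tibble `term`, `estimate` (full-sample statistic), `conf.low`,
#'   `conf.high`, with attributes `n_failed` and `B`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000L, seed = NULL,
                         conf = 0.95, max_failure_frac = 0.1) {
  if (B < 2) abort("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  full <- tryCatch(statistic(data), error = function(e) {
    abort(paste0("bootstrap statistic failed on the full sample: ",
                 conditionMessage(e)))
  })
  draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  reps <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    reps[[b]] <- tryCatch(statistic(data[draws[, b], , drop = FALSE]),
                          error = function(e) NULL)
    if (is.null(reps[[b]])) failed <- failed + 1L
  }
  if (failed > max_failure_frac * B) {
    abort(sprintf("bootstrap failed in %d of %d replicates", failed, B))
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  alpha <- (1 - conf) / 2
  out <- tibble(
    term = names(full) %||% paste0("stat", seq_along(full)),
    estimate = as.numeric(full),
    conf.low = unname(apply(mat, 2, quantile, probs = alpha, names = FALSE)),
    conf.high = unname(apply(mat, 2, quantile, probs = 1 - alpha,
                             names = FALSE))
  )
  attr(out, "n_failed") <- failed
  attr(out, "B") <- B
  out
}
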