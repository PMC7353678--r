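#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a propensity fit
#'
#' @param x A [fit_propensity()] object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`
#'   (log-odds), `std.error`, `statistic`, `p.value`.
#' @export
tidy.propensity_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' @rdname tidy.propensity_fit
#' @return For `glance()`: one-row tibble with `n`, `n_treated`,
#'   `null.deviance`, `deviance`, `aic`, `converged`.
#' @export
glance.propensity_fit <- function(x, ...) {
  tibble(n = x$n, n_treated = sum(x$model$y == 1L),
         null.deviance = x$model$null.deviance,
         deviance = x$model$deviance, aic = x$model$aic,
         converged = x$model$converged)
}

#' Tidy an outcome fit
#'
#' Coefficients on the link scale with robust (sandwich) standard errors for
#' logistic and cost models, and robust partial-likelihood errors for the
#' Cox model. Set `exponentiate = TRUE` for odds/hazard/cost ratios.
#'
#' @param x An `outcome_fit` from [fit_weighted_logistic()],
#'   [fit_weighted_cox()], or [fit_cost_glm()].
#' @param exponentiate Exponentiate estimates and CI bounds.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.outcome_fit <- function(x, exponentiate = FALSE, ...) {
  if (x$estimand == "hazard_ratio") {
    sm <- summary(x$model)$coefficients
    z <- qnorm(0.975)
    out <- tibble(term = rownames(sm), estimate = sm[, "coef"],
                  std.error = sm[, "robust se"],
                  statistic = sm[, "coef"] / sm[, "robust se"],
                  p.value = 2 * pnorm(-abs(sm[, "coef"] / sm[, "robust se"])),
                  conf.low = sm[, "coef"] - z * sm[, "robust se"],
                  conf.high = sm[, "coef"] + z * sm[, "robust se"])
  } else {
    out <- x$robust |> rename(std.error = "robust_se")
  }
  if (exponentiate) {
    out <- out |> mutate(across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @rdname tidy.outcome_fit
#' @return For `glance()`: one-row tibble with the estimand, point estimate,
#'   CI, p-value and `n`.
#' @export
glance.outcome_fit <- function(x, ...) {
  tibble(estimand = x$estimand, estimate = x$estimate,
         conf.low = x$conf.low, conf.high = x$conf.high,
         p.value = x$p.value, n = x$n, treated = x$treated)
}
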