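#' Default propensity-model covariate list
#'
#' The eight treatment-assignment covariates: six-level age group, sex,
#' region, Charlson index excluding COPD codes (continuous), and the COPD,
#' stroke, recent-pneumonia and ILD-center flags.
#'
#' @return Character vector of column names.
#' @export
propensity_covariates <- function() {
  c("age_group", "sex", "region", "cci_excl_copd", "copd", "stroke",
    "recent_pneumonia", "ild_center_visit")
}

#' Fit the treatment-assignment (propensity) model
#'
#' Maximum-likelihood logistic regression of treatment on baseline
#' covariates. Factor covariates use their first observed level as reference
#' (empty levels are dropped). Non-convergence or separation (fitted
#' probabilities numerically at 0 or 1) raises an error rather than returning
#' unusable scores.
#'
#' @param data Covariate tibble, e.g. from [baseline_covariates()].
#' @param treatment Name of the treatment column.
#' @param treated Level modelled as 1 (defaults to `"pirfenidone"` when
#'   present, otherwise the first sorted level).
#' @param covariates Covariate column names; defaults to
#'   [propensity_covariates()], silently reduced to columns present.
#' @return A `propensity_fit` object: the glm, the scores (strictly inside
#'   (0,1)), and metadata. Supports [tidy()], [glance()], and
#'   [propensity_scores()].
#' @export
fit_propensity <- function(data, treatment = "index_drug", treated = NULL,
                           covariates = propensity_covariates()) {
  tr <- data[[treatment]]
  if (is.null(tr)) abort(sprintf("column `%s` not found", treatment))
  lev <- sort(unique(as.character(tr)))
  if (length(lev) != 2L) abort("both treatment arms must be present")
  treated <- treated %||% (if ("pirfenidone" %in% lev) "pirfenidone" else lev[1L])
  if (!treated %in% lev) abort(sprintf("treated level `%s` absent", treated))
  covariates <- intersect(covariates, names(data))
  df <- data[, covariates, drop = FALSE] |>
    mutate(across(dplyr::where(is.factor), droplevels))
  ## constant columns carry no assignment information; drop them so the fit
  ## degrades gracefully to intercept-only
  constant <- vapply(df, function(x) length(unique(x)) < 2L, logical(1))
  covariates <- covariates[!constant[covariates]]
  df$.y <- as.integer(as.character(tr) == treated)
  if (length(covariates) == 0L) {
    fml <- .y ~ 1
  } else {
    fml <- as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  }
  model <- suppressWarnings(glm(fml, data = df, family = binomial()))
  scores <- as.numeric(model$fitted.values)
  if (!model$converged || any(scores < 1e-10) || any(scores > 1 - 1e-10)) {
    abort(paste0("propensity model failed: ",
                 if (!model$converged) "no convergence"
                 else "separation (fitted probabilities at 0/1)",
                 "; check for perfectly predictive covariates"))
  }
  structure(list(model = model, scores = scores, treatment = treatment,
                 treated = treated, covariates = covariates,
                 n = nrow(data)),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> n =", x$n, " treated level:", x$treated, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Extract propensity scores
#' @param fit A `propensity_fit`.
#' @return Numeric vector of estimated treatment probabilities.
#' @export
propensity_scores <- function(fit) fit$scores

#' Inverse-probability-of-treatment weights
#'
#' ATE weights: `1/p` for treated patients and `1/(1-p)` for the comparator,
#' optionally stabilized by the marginal arm shares and/or truncated at
#' percentiles of the weight distribution (both off by default).
#'
#' @param scores Propensity scores strictly inside (0,1).
#' @param treatment Treatment vector.
#' @param treated Level receiving `1/p` weights.
#' @param stabilize Multiply by marginal arm probabilities.
#' @param truncate_quantiles Length-2 numeric (e.g. `c(0.01, 0.99)`) to cap
#'   weights at those weight quantiles, or `NULL`.
#' @return Numeric weight vector.
#' @export
compute_iptw <- function(scores, treatment, treated = "pirfenidone",
                         stabilize = FALSE, truncate_quantiles = NULL) {
  if (any(scores <= 0 | scores >= 1)) {
    abort("propensity scores must be strictly inside (0, 1)")
  }
  is_tr <- as.character(treatment) == treated
  w <- ifelse(is_tr, 1 / scores, 1 / (1 - scores))
  if (stabilize) {
    p_tr <- mean(is_tr)
    w <- w * ifelse(is_tr, p_tr, 1 - p_tr)
  }
  if (!is.null(truncate_quantiles)) {
    qs <- quantile(w, truncate_quantiles)
    w <- pmin(pmax(w, qs[1L]), qs[2L])
  }
  w
}

#' Standardized mean difference between arms
#'
#' `(m_T - m_C) / sqrt((v_T + v_C) / 2)` with (optionally weighted) means and
#' variances; binary variables use the proportion variance `p(1-p)`. When the
#' pooled variance is zero the SMD is 0 if the means agree and an error
#' otherwise.
#'
#' @param x Numeric or logical covariate vector.
#' @param treatment Treatment vector.
#' @param treated Level treated as the first arm.
#' @param weights Optional weights (unit weights if `NULL`).
#' @return The standardized mean difference (signed).
#' @export
smd <- function(x, treatment, treated = "pirfenidone", weights = NULL) {
  x <- as.numeric(x)
  w <- weights %||% rep(1, length(x))
  is_tr <- as.character(treatment) == treated
  binary <- all(x %in% c(0, 1))
  m1 <- wmean(x[is_tr], w[is_tr])
  m0 <- wmean(x[!is_tr], w[!is_tr])
  if (binary) {
    v1 <- m1 * (1 - m1)
    v0 <- m0 * (1 - m0)
  } else {
    v1 <- wvar(x[is_tr], w[is_tr])
    v0 <- wvar(x[!is_tr], w[!is_tr])
  }
  pool <- (v1 + v0) / 2
  if (pool <= 0) {
    if (isTRUE(all.equal(m1, m0))) return(0)
    abort("zero pooled variance with unequal means")
  }
  (m1 - m0) / sqrt(pool)
}

#' Covariate balance before and after weighting
#'
#' Expands factor covariates into one indicator per level and reports the
#' standardized mean difference for every term, unweighted and IPTW-weighted.
#' The conventional balance criterion flags the table as balanced when the
#' maximum absolute weighted SMD is at most `threshold`.
#'
#' @param data Covariate tibble including the treatment column.
#' @param weights IPTW weights.
#' @param treatment,treated,covariates As in [fit_propensity()].
#' @param threshold Balance threshold on |SMD| (default 0.1).
#' @return A `balance_table` tibble with columns `term`, `smd_unweighted`,
#'   `smd_weighted`, and attributes `max_smd_weighted` and `balanced`.
#'   Plot with [ggplot2::autoplot()].
#' @export
balance_table <- function(data, weights, treatment = "index_drug",
                          treated = "pirfenidone",
                          covariates = propensity_covariates(),
                          threshold = 0.1) {
  covariates <- intersect(covariates, names(data))
  tr <- data[[treatment]]
  terms <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.factor(x) || is.character(x)) {
      x <- droplevels(factor(x))
      for (lv in levels(x)) {
        terms[[paste0(cv, ":", lv)]] <- as.numeric(x == lv)
      }
    } else {
      terms[[cv]] <- as.numeric(x)
    }
  }
  res <- purrr::imap(terms, function(x, nm) {
    tibble(term = nm,
           smd_unweighted = smd(x, tr, treated),
           smd_weighted = smd(x, tr, treated, weights))
  }) |> bind_rows()
  attr(res, "max_smd_weighted") <- max(abs(res$smd_weighted))
  attr(res, "balanced") <- max(abs(res$smd_weighted)) <= threshold
  attr(res, "threshold") <- threshold
  class(res) <- c("balance_table", class(res))
  res
}

#' Love plot of covariate balance
#'
#' @param object A [balance_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.balance_table <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.1
  df <- object |>
    pivot_longer(c("smd_unweighted", "smd_weighted"),
                 names_to = "stage", values_to = "smd_value") |>
    mutate(stage = ifelse(.data$stage == "smd_weighted",
                          "weighted", "unweighted"))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$smd_value),
                                   y = .data$term,
                                   colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
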