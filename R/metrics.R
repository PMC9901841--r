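check_obs_pred <- function(observed, predicted, min_n = 1) {
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length",
          class = "permstack_value_error")
  }
  if (length(observed) < min_n) {
    abort(sprintf("need at least %d observations", min_n),
          class = "permstack_value_error")
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    abort("non-finite values in observed/predicted",
          class = "permstack_value_error")
  }
  invisible(TRUE)
}

#' Coefficient of determination (residual form)
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Unbounded below: a model
#' whose predictions are shifted or worse than the mean predictor scores
#' negative.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single number, at most 1.
#' @export
r_squared <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("observed vector is constant; R^2 undefined",
          class = "permstack_value_error")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Coefficient of determination (squared-correlation form)
#'
#' The squared Pearson correlation `(cov(y, yhat) / sqrt(var(y) var(yhat)))^2`,
#' always in 0-1 and invariant under affine transforms of the predictions.
#'
#' @inheritParams r_squared
#' @return A single number in \[0, 1\].
#' @export
r_squared_cov <- function(observed, predicted) {
  pearson_r(observed, predicted)^2
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 1)
  sqrt(mean((observed - predicted)^2))
}

#' Mean absolute error
#'
#' @inheritParams r_squared
#' @return `mean(abs(observed - predicted))`; never exceeds [rmse()].
#' @export
mae <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 1)
  mean(abs(observed - predicted))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that rejects constant vectors instead of
#' returning `NA`.
#'
#' @inheritParams r_squared
#' @return A single number in \[-1, 1\].
#' @export
pearson_r <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 2)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    abort("constant vector; Pearson correlation undefined",
          class = "permstack_value_error")
  }
  stats::cor(observed, predicted)
}

#' Gain-curve relative Gini score
#'
#' Measures how well the predictions sort the molecules by their observed
#' outcome. Items are ranked by decreasing prediction and the cumulative
#' share of the (minimum-shifted) outcome total is accumulated into a gain
#' curve; the area between that curve and the diagonal, divided by the same
#' area for the ideal outcome-sorted ordering, is the relative Gini score.
#' Any strictly order-preserving predictor scores exactly 1; random
#' orderings score near 0; anti-sorted predictors score negative.
#'
#' Outcomes are shifted by their minimum before accumulation so the curve is
#' well defined for all-negative logPe values. Tied predictions are pooled
#' into a single curve segment, which equals the average over all orderings
#' of the tied items; a fully tied (constant) predictor therefore scores 0.
#'
#' @inheritParams r_squared
#' @return A single number, 1 for perfect ranking.
#' @export
relative_gini <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 2)
  v <- observed - min(observed)
  total <- sum(v)
  if (total == 0) {
    abort("observed vector is constant; relative Gini undefined",
          class = "permstack_value_error")
  }
  a_model <- gain_curve_area(predicted, v, total)
  a_ideal <- gain_curve_area(v, v, total)
  (a_model - 0.5) / (a_ideal - 0.5)
}

# Area under the gain curve for items sorted by decreasing score; tied
# scores advance the curve as one pooled segment (trapezoid rule).
gain_curve_area <- function(scores, v, total) {
  n <- length(v)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  vv <- v[o]
  grp <- cumsum(!duplicated(s))
  dx <- tapply(rep(1, n), grp, sum) / n
  dy <- tapply(vv, grp, sum) / total
  y_prev <- c(0, cumsum(dy)[-length(dy)])
  sum(dx * (y_prev + dy / 2))
}

#' Summarise regression performance
#'
#' Computes the package's full metric set on one observed/predicted pair and
#' tags it with its evaluation context (`"cv"` statistics come from held-out
#' folds, `"resubstitution"` from predicting the training data itself,
#' `"holdout"` from an untouched test or external set).
#'
#' @inheritParams r_squared
#' @param context One of `"resubstitution"`, `"cv"`, `"holdout"`.
#' @return One-row tibble with `r2`, `r2_cov`, `rmse`, `mae`, `pearson`,
#'   `gini`, `n`, `context`.
#' @export
summarize_metrics <- function(observed, predicted,
                              context = c("resubstitution", "cv", "holdout")) {
  context <- match.arg(context)
  tibble::tibble(
    r2 = r_squared(observed, predicted),
    r2_cov = r_squared_cov(observed, predicted),
    rmse = rmse(observed, predicted),
    mae = mae(observed, predicted),
    pearson = pearson_r(observed, predicted),
    gini = relative_gini(observed, predicted),
    n = length(observed),
    context = context
  )
}
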