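#' Motor-averaging safety-margin prediction
#'
#' Predicted 2-target movement direction as a weighted average of the
#' motor plans for the obstacle-obstructed and unobstructed targets:
#' `mu2_hat = alpha * mu1A + (1 - alpha) * mu1B`. The baseline model uses
#' equal weights (`alpha = 1/2`). Inputs are frame-signed movement
#' directions.
#'
#' @param mu1A obstructed-target mean deflection(s), deg (frame-signed).
#' @param mu1B unobstructed-target mean deflection(s), deg.
#' @param alpha weight on the obstructed-target plan, in [0, 1].
#' @return predicted direction(s), deg.
#' @export
ma_safety_margin <- function(mu1A, mu1B, alpha = 0.5) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  alpha * mu1A + (1 - alpha) * mu1B
}

#' Performance-optimization safety-margin prediction
#'
#' Predicted 2-target direction balancing two objectives: movement timing
#' (fully satisfied at 0 deg, straight ahead) and obstacle avoidance,
#' whose full prioritization is the variability-scaled 1-target safety
#' margin minus the obstacle's 15 deg angular offset:
#' `mu2_hat = beta * 0 + (1 - beta) * (mu1A * sigma2/sigma1A - 15)`.
#' When the scaled margin does not exceed the offset the straight-ahead
#' movement already satisfies both objectives and the prediction is
#' floored at 0 deg (the floor is the baseline model's conditional branch;
#' it is piecewise-linear and continuous at the boundary).
#'
#' @param mu1A obstructed-target safety margin(s), deg, positive (use
#'   [variant_margin()] to map frame-signed deflections).
#' @param ratio variability ratio `sigma2 / sigma1A` (> 0). Population-
#'   level calls use the ratio of cohort means.
#' @param beta weight on the movement-timing objective, in [0, 1].
#' @param offset obstacle angular offset (deg).
#' @param floor apply the 0 deg floor when the scaled margin is at or
#'   below the offset.
#' @return predicted direction(s), deg.
#' @export
po_safety_margin <- function(mu1A, ratio, beta = 0.5, offset = 15,
                             floor = TRUE) {
  if (!is.finite(beta) || beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]")
  stopifnot(all(ratio > 0))
  x <- mu1A * ratio - offset
  pred <- beta * 0 + (1 - beta) * x
  if (floor) pred <- ifelse(x <= 0, 0, pred)
  pred
}

#' @rdname ma_safety_margin
#' @export
ma_baseline <- function(mu1A, mu1B) ma_safety_margin(mu1A, mu1B, 0.5)

#' @rdname po_safety_margin
#' @export
po_baseline <- function(mu1A, ratio) po_safety_margin(mu1A, ratio, 0.5)

#' Population-level variability ratio
#'
#' Ratio of the cohort mean of `sigma2` to the cohort mean of `sigma1A`
#' (ratio of means, not mean of ratios).
#'
#' @param summary cohort summary data.frame with `sigma2`, `sigma1A`.
#' @return scalar ratio.
#' @export
variability_ratio <- function(summary) {
  mean(summary$sigma2) / mean(summary$sigma1A)
}

## constrained no-intercept slope of y on x, clipped to [0, 1]
clipped_slope <- function(x, y) {
  if (max(abs(x)) < 1e-8) stop("zero variance in regressor")
  min(max(sum(x * y) / sum(x^2), 0), 1)
}

#' Fit the motor-averaging weight
#'
#' Estimates `alpha` by regressing the per-participant difference between
#' 2-target and unobstructed 1-target directions onto the difference
#' between obstructed and unobstructed 1-target directions (the form the
#' refined model implies: `mu2 - mu1B = alpha (mu1A - mu1B)`), with the
#' constrained least-squares solution projected onto [0, 1].
#'
#' @param summary cohort summary with `mu1A`, `mu1B`, `mu2` (>= 3 rows).
#' @return alpha in [0, 1].
#' @export
fit_alpha <- function(summary) {
  stopifnot(nrow(summary) >= 3)
  clipped_slope(summary$mu1A - summary$mu1B, summary$mu2 - summary$mu1B)
}

#' Fit the performance-optimization weight
#'
#' Estimates `beta` by regressing per-participant 2-target directions
#' onto the variability-scaled obstructed-target safety margins minus the
#' 15 deg offset (the regressor the refined model multiplies by
#' `1 - beta`), using per-participant variability ratios; the slope is
#' projected onto [0, 1] and `beta = 1 - slope`.
#'
#' @param summary cohort summary with `mu1A`, `sigma1A`, `sigma2`, `mu2`,
#'   `variant`.
#' @param offset obstacle angular offset (deg).
#' @return beta in [0, 1].
#' @export
fit_beta <- function(summary, offset = 15) {
  stopifnot(nrow(summary) >= 3)
  margin <- variant_margin(summary$mu1A, summary$variant)
  x <- margin * summary$sigma2 / summary$sigma1A - offset
  1 - clipped_slope(x, summary$mu2)
}

#' Fit a safety-margin model to a cohort
#'
#' Fits the baseline (parameter-free) or refined (one weight in [0, 1])
#' motor-averaging or performance-optimization model and evaluates its
#' population-level prediction against each participant's observed mean
#' 2-target direction, reporting per-participant squared errors and their
#' mean +/- SEM.
#'
#' @param summary cohort summary data.frame (see
#'   [simulate_obstacle_cohort()]).
#' @param model `"ma"` or `"po"`.
#' @param refined fit the weighting parameter (`TRUE`) or use equal
#'   weighting (`FALSE`).
#' @param weight optional fixed weight overriding the fit (used for
#'   cross-validation and weight sweeps).
#' @return object of class `safety_margin_fit`.
#' @export
fit_safety_margin <- function(summary, model = c("ma", "po"),
                              refined = TRUE, weight = NULL) {
  model <- match.arg(model)
  if (is.null(weight)) {
    weight <- if (!refined) 0.5
    else if (model == "ma") fit_alpha(summary) else fit_beta(summary)
  }
  fit <- structure(
    list(model = model, refined = refined, weight = weight,
         n = nrow(summary), offset = 15),
    class = "safety_margin_fit")
  pred <- predict(fit, summary)
  sq <- (summary$mu2 - pred)^2
  fit$prediction <- pred
  fit$squared_errors <- sq
  fit$mse <- mean(sq)
  fit$mse_sem <- stats::sd(sq) / sqrt(length(sq))
  fit
}

#' @export
predict.safety_margin_fit <- function(object, newdata, ...) {
  if (object$model == "ma") {
    ma_safety_margin(mean(newdata$mu1A), mean(newdata$mu1B), object$weight)
  } else {
    margin <- variant_margin(newdata$mu1A, newdata$variant)
    po_safety_margin(mean(margin), variability_ratio(newdata),
                     object$weight, object$offset,
                     floor = !object$refined)
  }
}

#' @export
coef.safety_margin_fit <- function(object, ...) {
  stats::setNames(object$weight,
                  if (object$model == "ma") "alpha" else "beta")
}

#' @export
print.safety_margin_fit <- function(x, ...) {
  cat(sprintf("%s %s safety-margin model (n = %d)\n",
              if (x$refined) "Refined" else "Baseline",
              toupper(x$model), x$n))
  cat(sprintf("  weight (%s) = %.3f%s\n",
              if (x$model == "ma") "alpha" else "beta", x$weight,
              if (x$refined) "" else " [fixed]"))
  cat(sprintf("  population prediction = %.2f deg, MSE = %.2f +/- %.2f deg^2\n",
              x$prediction, x$mse, x$mse_sem))
  invisible(x)
}

#' Cross-validate a safety-margin model between cohorts
#'
#' Fits the refined model weight on one cohort, applies the resulting
#' population-level prediction to the other cohort, and reports the
#' held-out mean squared error and its percentage increase relative to
#' the evaluation cohort's own fitted model.
#'
#' @param fit_cohort,eval_cohort summary data.frames.
#' @param model `"ma"` or `"po"`.
#' @return list with `weight`, `mse_crossval`, `mse_own`,
#'   `pct_increase`, and the per-participant held-out squared errors.
#' @export
cross_validate <- function(fit_cohort, eval_cohort, model = c("ma", "po")) {
  model <- match.arg(model)
  f_a <- fit_safety_margin(fit_cohort, model, refined = TRUE)
  cross <- fit_safety_margin(eval_cohort, model, weight = f_a$weight)
  own <- fit_safety_margin(eval_cohort, model, refined = TRUE)
  list(weight = f_a$weight, mse_crossval = cross$mse,
       mse_crossval_sem = cross$mse_sem, mse_own = own$mse,
       mse_own_sem = own$mse_sem,
       pct_increase = 100 * (cross$mse - own$mse) / own$mse,
       squared_errors = cross$squared_errors)
}

#' Direction-space prediction index for a cohort
#'
#' Applies the prediction index to mean movement directions: each
#' participant's observed 2-target direction is located between the
#' population-level PO and MA predictions, and the per-participant
#' indices are averaged.
#'
#' @param summary cohort summary data.frame.
#' @param mu_po,mu_ma population-level model predictions (deg); computed
#'   from the baseline models when omitted.
#' @return list with `pi` (mean), `pi_i` (per participant), `mu_po`,
#'   `mu_ma`.
#' @export
direction_prediction_index <- function(summary, mu_po = NULL,
                                       mu_ma = NULL) {
  if (is.null(mu_ma))
    mu_ma <- predict(fit_safety_margin(summary, "ma", refined = FALSE),
                     summary)
  if (is.null(mu_po))
    mu_po <- predict(fit_safety_margin(summary, "po", refined = FALSE),
                     summary)
  pis <- vapply(summary$mu2, function(m2)
    prediction_index(m2, mu_po, mu_ma)$pi, 0)
  list(pi = mean(pis), pi_i = pis, mu_po = mu_po, mu_ma = mu_ma)
}

#' Sweep model weights over a grid
#'
#' Sensitivity analysis of the safety-margin models to their weighting
#' parameter: evaluates the population-level prediction and cohort MSE on
#' a grid of weights (e.g. 1:2 and 2:1 weightings at 1/3 and 2/3).
#'
#' @param summary cohort summary data.frame.
#' @param model `"ma"` or `"po"`.
#' @param weights numeric weights in [0, 1].
#' @return data.frame with `weight`, `prediction`, `mse`.
#' @export
weight_sweep <- function(summary, model = c("ma", "po"),
                         weights = c(1 / 3, 1 / 2, 2 / 3)) {
  model <- match.arg(model)
  rows <- lapply(weights, function(w) {
    f <- fit_safety_margin(summary, model, weight = w)
    data.frame(weight = w, prediction = f$prediction, mse = f$mse)
  })
  do.call(rbind, rows)
}
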