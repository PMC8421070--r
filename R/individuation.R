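#' Individuation models of inter-participant differences
#'
#' The performance-optimization prediction for participant i's mean
#' 2-target direction uses that participant's own safety margin and
#' variabilities. The individuation models interpolate between the
#' group-averaged and individual inputs with indices in [0, 1]:
#' \deqn{\hat\mu_{2i} - \bar\mu_2 = \tfrac12
#'   (k_\mu \mu_{1Ai} + (1-k_\mu)\bar\mu_{1A}) \cdot
#'   (k_{\sigma 2} \sigma_{2i} + (1-k_{\sigma 2})\bar\sigma_2) \cdot
#'   (k_{\sigma 1}/\sigma_{1Ai} + (1-k_{\sigma 1})/\bar\sigma_{1A}) - K_0}
#' The one-parameter form ties the three indices to a single `k`; `k = 1`
#' is full individuation, `k = 0` none. `K_0` is a free offset that keeps
#' the variance decomposition well-posed. Group averages (bar quantities)
#' are unweighted cohort means of the per-participant values; safety
#' margins enter as positive magnitudes via [variant_margin()].
#'
#' The model is a product of affine terms in the indices, hence nonconvex;
#' fitting uses a dense grid plus multi-start bounded optimization with
#' the offset profiled out exactly, followed by coordinate-wise polish.
#'
#' @param summary cohort summary data.frame with `mu1A`, `sigma1A`,
#'   `sigma2`, `mu2`, `variant`.
#' @param type `"one"` (single index) or `"three"` (per-variable
#'   indices).
#' @return object of class `individuation_fit` with elements `indices`
#'   (named, in [0, 1]), `K0`, `fitted`, `residuals`, `sse`, `r_squared`,
#'   `n`, `type`, `data`, `means`.
#' @export
fit_individuation <- function(summary, type = c("one", "three")) {
  type <- match.arg(type)
  n <- nrow(summary)
  if (n < ifelse(type == "one", 4L, 6L))
    stop("too few participants for the requested model")
  d <- individuation_inputs(summary)
  if (max(abs(d$y)) < 1e-12)
    stop("degenerate cohort: no inter-participant variance in mu2")

  if (type == "one") {
    sse_k <- function(k) individuation_sse(rep(k, 3), d)
    grid <- seq(0, 1, by = 1e-3)
    vals <- vapply(grid, sse_k, 0)
    i <- which.min(vals)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    k <- if (lo < hi) stats::optimize(sse_k, c(lo, hi), tol = 1e-9)$minimum
    else grid[i]
    if (sse_k(grid[i]) < sse_k(k)) k <- grid[i]
    indices <- c(k = k)
    kk <- rep(k, 3)
  } else {
    coarse <- as.matrix(expand.grid(k1 = seq(0, 1, 0.1),
                                    k2 = seq(0, 1, 0.1),
                                    k3 = seq(0, 1, 0.1)))
    vals <- apply(coarse, 1, individuation_sse, d = d)
    starts <- coarse[order(vals)[1:5], , drop = FALSE]
    one <- fit_individuation(summary, "one")
    starts <- rbind(starts, rep(one$indices[["k"]], 3))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], individuation_sse, d = d,
                        method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(factr = 1e4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    kk <- unname(best$par)
    # coordinate-wise polish (two sweeps)
    for (sweep in 1:2) for (j in 1:3) {
      f1 <- function(x) { v <- kk; v[j] <- x; individuation_sse(v, d) }
      g <- seq(0, 1, by = 1e-3)
      vg <- vapply(g, f1, 0)
      i <- which.min(vg)
      lo <- g[max(i - 1L, 1L)]; hi <- g[min(i + 1L, length(g))]
      cand <- if (lo < hi) stats::optimize(f1, c(lo, hi), tol = 1e-9)$minimum
      else g[i]
      for (x in c(cand, g[i])) if (f1(x) <= f1(kk[j])) kk[j] <- x
    }
    indices <- c(k_mu = kk[1], k_sigma2 = kk[2], k_sigma1 = kk[3])
  }
  individuation_result(indices, kk, d, type, summary)
}

## shared inputs: margins, variabilities, centered response, cohort means
individuation_inputs <- function(summary) {
  m1A <- variant_margin(summary$mu1A, summary$variant)
  list(m1A = m1A, s2 = summary$sigma2, s1A = summary$sigma1A,
       y = summary$mu2 - mean(summary$mu2),
       m1A_bar = mean(m1A), s2_bar = mean(summary$sigma2),
       s1A_bar = mean(summary$sigma1A), mu2_bar = mean(summary$mu2))
}

## product term (before the offset) for index triple kk
individuation_product <- function(kk, d) {
  0.5 * (kk[1] * d$m1A + (1 - kk[1]) * d$m1A_bar) *
    (kk[2] * d$s2 + (1 - kk[2]) * d$s2_bar) *
    (kk[3] / d$s1A + (1 - kk[3]) / d$s1A_bar)
}

## SSE with the offset K0 profiled out (linear given the indices)
individuation_sse <- function(kk, d) {
  p <- individuation_product(kk, d)
  K0 <- mean(p) - mean(d$y)
  sum((d$y - (p - K0))^2)
}

individuation_result <- function(indices, kk, d, type, summary) {
  p <- individuation_product(kk, d)
  K0 <- mean(p) - mean(d$y)
  fitted <- p - K0
  res <- d$y - fitted
  sse <- sum(res^2)
  sst <- sum((d$y - mean(d$y))^2)
  structure(list(indices = indices, K0 = K0, fitted = fitted,
                 residuals = res, sse = sse,
                 r_squared = if (sst == 0) NA_real_ else 1 - sse / sst,
                 n = length(d$y), type = type, data = d,
                 summary = summary),
            class = "individuation_fit")
}

## number of fitted parameters (indices + offset)
individuation_npar <- function(fit) {
  if (fit$type == "one") 2L else 4L
}

#' @export
coef.individuation_fit <- function(object, ...) {
  c(object$indices, K0 = object$K0)
}

#' @export
fitted.individuation_fit <- function(object, ...) {
  object$fitted + object$data$mu2_bar
}

#' @export
residuals.individuation_fit <- function(object, ...) object$residuals

#' @export
predict.individuation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  d <- object$data
  m1A <- variant_margin(newdata$mu1A, newdata$variant)
  kk <- if (object$type == "one") rep(object$indices[["k"]], 3)
  else unname(object$indices)
  p <- 0.5 * (kk[1] * m1A + (1 - kk[1]) * d$m1A_bar) *
    (kk[2] * newdata$sigma2 + (1 - kk[2]) * d$s2_bar) *
    (kk[3] / newdata$sigma1A + (1 - kk[3]) / d$s1A_bar)
  p - object$K0 + d$mu2_bar
}

#' @export
print.individuation_fit <- function(x, ...) {
  cat(sprintf("%s-index individuation model (n = %d)\n",
              if (x$type == "one") "Single" else "Three", x$n))
  for (nm in names(x$indices))
    cat(sprintf("  %s = %.3f\n", nm, x$indices[[nm]]))
  cat(sprintf("  K0 = %.3f deg, R-squared = %.3f\n", x$K0, x$r_squared))
  invisible(x)
}

#' @export
summary.individuation_fit <- function(object, ...) {
  out <- list(fit = object)
  if (object$type == "three") {
    out$partial <- do.call(rbind, lapply(
      c("mu1A", "sigma2", "sigma1A"), function(v) {
        pr <- partial_r2(object, v)
        data.frame(variable = v, partial_r2 = pr$partial_r2, F = pr$F,
                   p = pr$p, df1 = pr$df[1], df2 = pr$df[2])
      }))
  }
  class(out) <- "summary.individuation_fit"
  out
}

#' @export
print.summary.individuation_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$partial)) {
    cat("Partial R-squared (index-at-zero nested comparisons):\n")
    print(x$partial, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Partial R-squared of one input variable
#'
#' Contribution of one input variable's individuation to the explained
#' variance: the model is refit with that variable's index fixed at zero
#' (the others free), and
#' `partial R^2 = (SSE_reduced - SSE_full) / SSE_reduced`, with an F-test
#' on (1, n - p) degrees of freedom where p counts the full model's
#' indices plus the offset.
#'
#' For a one-index fit the reduced model is the offset-only model, so the
#' statistic tests the model's overall explained variance.
#'
#' @param fit an `individuation_fit`.
#' @param variable `"mu1A"`, `"sigma2"` or `"sigma1A"` (ignored for
#'   one-index fits).
#' @return list with `partial_r2`, `F`, `p`, `df`, `sse_full`,
#'   `sse_reduced`.
#' @export
partial_r2 <- function(fit, variable = c("mu1A", "sigma2", "sigma1A")) {
  stopifnot(inherits(fit, "individuation_fit"))
  d <- fit$data
  n <- fit$n
  p_full <- individuation_npar(fit)
  if (fit$type == "one") {
    sse_red <- sum((d$y - mean(d$y))^2)
  } else {
    variable <- match.arg(variable)
    j <- match(variable, c("mu1A", "sigma2", "sigma1A"))
    sse_red <- individuation_refit_fixed(d, j)
  }
  sse_full <- fit$sse
  if (sse_red <= 0) {
    warning("reduced model has zero residual; partial R-squared undefined")
    return(list(partial_r2 = NA_real_, F = NA_real_, p = NA_real_,
                df = c(1L, n - p_full), sse_full = sse_full,
                sse_reduced = sse_red))
  }
  pr2 <- max((sse_red - sse_full) / sse_red, 0)
  df2 <- n - p_full
  Fstat <- max(sse_red - sse_full, 0) / (sse_full / df2)
  list(partial_r2 = pr2, F = Fstat,
       p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
       df = c(1L, df2), sse_full = sse_full, sse_reduced = sse_red)
}

## minimum SSE with index j fixed at 0, the other two free
individuation_refit_fixed <- function(d, j) {
  free <- setdiff(1:3, j)
  obj <- function(par) {
    kk <- numeric(3)
    kk[free] <- par
    individuation_sse(kk, d)
  }
  coarse <- as.matrix(expand.grid(a = seq(0, 1, 0.05), b = seq(0, 1, 0.05)))
  vals <- apply(coarse, 1, obj)
  starts <- coarse[order(vals)[1:3], , drop = FALSE]
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                      lower = 0, upper = 1, control = list(factr = 1e4))
    best <- min(best, o$value)
  }
  best
}

#' Partial-residual dataset for one input variable
#'
#' The visualization dataset behind per-variable effect plots: predictions
#' of the nested model in which the other two variables' indices are set
#' to zero (population means drive those factors), plus the residuals of
#' the full three-index fit, mean-subtracted, paired with the variable's
#' individual values.
#'
#' @param fit a three-index `individuation_fit`.
#' @param variable `"mu1A"`, `"sigma2"` or `"sigma1A"`.
#' @return data.frame with one row per participant: `participant`, `x`
#'   (the variable's individual values; safety-margin magnitude for
#'   `mu1A`), `y` (mean-subtracted partial residual, deg).
#' @export
partial_residual_data <- function(fit,
                                  variable = c("mu1A", "sigma2",
                                               "sigma1A")) {
  stopifnot(inherits(fit, "individuation_fit"), fit$type == "three")
  variable <- match.arg(variable)
  j <- match(variable, c("mu1A", "sigma2", "sigma1A"))
  d <- fit$data
  kk <- numeric(3)
  kk[j] <- unname(fit$indices[j])
  pred <- individuation_product(kk, d) - fit$K0
  y <- pred + fit$residuals
  y <- y - mean(y)
  x <- switch(variable, mu1A = d$m1A, sigma2 = d$s2, sigma1A = d$s1A)
  data.frame(participant = fit$summary$participant, x = x, y = y)
}
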