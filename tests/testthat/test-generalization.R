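test_that("generalization function evaluates the four-term sum", {
  expect_equal(
    evaluate_generalization(0, c(A1 = 0, A2 = 1, A0 = 0, sigma = 15)), 1)
  p <- c(A1 = 0.4, A2 = 1.2, A0 = -0.2, sigma = 11)
  expect_equal(evaluate_generalization(17, p),
               evaluate_generalization(-17, p))
  # direct numeric evaluation at a trained direction
  expect_equal(
    evaluate_generalization(30, c(A1 = 1, A2 = 0, A0 = 0, sigma = 15)),
    -1 - exp(-3600 / 450))
  expect_error(
    evaluate_generalization(0, c(A1 = 0, A2 = 1, A0 = 0, sigma = 0)))
})

test_that("noiseless generalization data is refit exactly", {
  p <- c(A1 = 0.8, A2 = 1.1, A0 = -0.3, sigma = 14)
  th <- seq(-42.5, 42.5, by = 7.5)
  fit <- fit_generalization(th, evaluate_generalization(th, p))
  expect_lt(max(abs(coef(fit) - p)), 1e-6)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_generalization(c(-30, 0, 30), c(1, 2, 1)), "distinct")
  # degenerate constant data: amplitude-free solution, zero residual
  fitc <- fit_generalization(seq(-30, 30, by = 7.5), rep(0.4, 9))
  expect_equal(unname(coef(fitc)[["A0"]]), 0.4, tolerance = 1e-8)
  expect_equal(fitc$r_squared, 1)
})

test_that("parameter recovery is nearly unbiased at small noise", {
  p <- c(A1 = 0.7, A2 = 1.0, A0 = -0.25, sigma = 15)
  th <- seq(-42.5, 42.5, by = 2.5)
  g0 <- evaluate_generalization(th, p)
  set.seed(77)
  est <- t(vapply(1:100, function(r)
    coef(fit_generalization(th, g0 + stats::rnorm(length(th), 0, 0.02))),
    numeric(4)))
  bias <- abs(colMeans(est) - p) / abs(p)
  expect_lt(max(bias), 0.05)
})

test_that("direction-variability refinement scales as expected", {
  p <- c(A1 = 0.7, A2 = 1.0, A0 = -0.25, sigma = 15)
  prof <- force_profile(seq(-0.05, 0.2, by = 1 / 200),
                        rep(1, 51))
  # point mass at the nominal direction: no change
  same <- refine_prediction(prof, rep(0, 10), p, nominal = 0)
  expect_equal(same$force, prof$force)
  # symmetric spread around the central maximum shrinks the prediction,
  # by the amount a numeric integral over the direction density gives
  sd <- 6
  grid <- seq(-42.5, 42.5, by = 0.01)
  dens <- stats::dnorm(grid, 0, sd)
  oracle <- sum(evaluate_generalization(grid, p) * dens) / sum(dens) /
    evaluate_generalization(0, p)
  expect_lt(oracle, 1)
  set.seed(9)
  dirs <- stats::rnorm(20000, 0, sd)
  ref <- refine_prediction(1, dirs, p, nominal = 0)
  expect_lt(ref, 1)
  expect_equal(ref, oracle, tolerance = 0.01)
  expect_error(refine_prediction(prof, 0,
                                 c(A1 = 0, A2 = 0, A0 = 0, sigma = 15)),
               "zero")
})
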