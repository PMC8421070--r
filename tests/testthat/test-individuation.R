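test_that("individuation indices are recovered from generative cohorts", {
  # full individuation, vanishing noise
  s1 <- simulate_individuation_cohort(26, k = 1, noise_sd = 1e-9, seed = 1)
  f1 <- fit_individuation(s1, "one")
  expect_equal(unname(f1$indices[["k"]]), 1, tolerance = 1e-3)
  expect_gt(f1$r_squared, 0.999)
  # no individuation: inter-participant variation is pure noise
  s0 <- simulate_individuation_cohort(26, k = 0, noise_sd = 1.3, seed = 2)
  f0 <- fit_individuation(s0, "one")
  expect_lt(f0$r_squared, 0.2)
  # three-index recovery
  s3 <- simulate_individuation_cohort(40, k = c(0.6, 0.5, 0),
                                      noise_sd = 1e-6, seed = 3)
  f3 <- fit_individuation(s3, "three")
  expect_equal(unname(f3$indices), c(0.6, 0.5, 0), tolerance = 0.02)
  # equal generating indices: three-index fit adds nothing
  se <- simulate_individuation_cohort(26, k = 0.4, noise_sd = 0.5,
                                      seed = 4)
  fe1 <- fit_individuation(se, "one")
  fe3 <- fit_individuation(se, "three")
  expect_lt(fe3$r_squared - fe1$r_squared, 0.1)
})

test_that("nesting inequalities hold on random cohorts", {
  for (r in 1:10) {
    s <- simulate_individuation_cohort(15, k = stats::runif(3),
                                       noise_sd = 1.5, seed = 100 + r)
    f1 <- fit_individuation(s, "one")
    f3 <- fit_individuation(s, "three")
    sse0 <- sum((s$mu2 - mean(s$mu2))^2)
    expect_lte(f3$sse, f1$sse + 1e-8)
    expect_lte(f1$sse, sse0 + 1e-8)
    expect_gte(f3$r_squared, f1$r_squared - 1e-8)
  }
})

test_that("index estimates match the dense grid-search oracle", {
  for (r in 1:10) {
    s <- simulate_individuation_cohort(14, k = stats::runif(1),
                                       noise_sd = 1.5, seed = 200 + r)
    f1 <- fit_individuation(s, "one")
    k_grid <- grid_k(s)
    expect_lt(abs(unname(f1$indices[["k"]]) - k_grid), 1e-3)
    # three-index fit: coordinate-wise optimal against a dense 1-D grid
    f3 <- fit_individuation(s, "three")
    kk <- unname(f3$indices)
    for (j in 1:3) {
      g <- seq(0, 1, by = 1e-3)
      sse_j <- vapply(g, function(x) {
        v <- kk; v[j] <- x; indiv_sse(s, v)
      }, 0)
      expect_lte(indiv_sse(s, kk), min(sse_j) + 1e-8)
    }
  }
})

test_that("partial R-squared isolates the variable that carries signal", {
  # only the safety margin varies across participants
  set.seed(31)
  n <- 20
  s <- data.frame(participant = 1:n, variant = "expt2a",
                  mu1A = stats::runif(n, 12, 34), mu1B = 0,
                  sigma1A = 4, sigma2 = 4, mu2 = NA)
  s$mu2 <- 0.5 * (s$mu1A * 4 * (1 / 4)) - 7 +
    stats::rnorm(n, 0, 0.05)
  f3 <- fit_individuation(s, "three")
  pr_mu <- partial_r2(f3, "mu1A")
  pr_s2 <- partial_r2(f3, "sigma2")
  pr_s1 <- partial_r2(f3, "sigma1A")
  expect_gt(pr_mu$partial_r2, 0.95)
  expect_lt(pr_s2$partial_r2, 0.05)
  expect_lt(pr_s1$partial_r2, 0.05)
  expect_equal(unname(pr_mu$df), c(1, n - 4))
  # a variable with no inter-participant spread has no leverage
  expect_lt(pr_s1$F, 1e-3)
})

test_that("partial residual data lies on the effect line for noise-free cohorts", {
  s <- simulate_individuation_cohort(24, k = c(0.7, 0.4, 0.2),
                                     noise_sd = 1e-9, seed = 41)
  f3 <- fit_individuation(s, "three")
  for (v in c("mu1A", "sigma2", "sigma1A")) {
    d <- partial_residual_data(f3, v)
    expect_equal(nrow(d), 24)
    expect_equal(mean(d$y), 0, tolerance = 1e-9)
  }
  d <- partial_residual_data(f3, "mu1A")
  # reduced-model prediction is affine in mu1A when the other factors are
  # population constants, so the points fall on a line
  lf <- stats::lm(y ~ x, data = d)
  expect_lt(max(abs(stats::residuals(lf))), 1e-4)
  # a variable with zero fitted index gives a flat partial-residual line
  s0 <- simulate_individuation_cohort(24, k = c(0.7, 0.4, 0),
                                      noise_sd = 1e-9, seed = 42)
  f0 <- fit_individuation(s0, "three")
  d0 <- partial_residual_data(f0, "sigma1A")
  expect_lt(stats::sd(d0$y), 1e-3)
})
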