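test_that("baseline safety-margin models reproduce the printed arithmetic", {
  expect_equal(ma_baseline(20, 0), 10)
  expect_equal(ma_baseline(7, 7), 7)
  expect_equal(ma_baseline(-11, 1), -5)

  expect_equal(po_baseline(30, 1), 7.5)
  expect_equal(po_baseline(25, 1.2), 7.5)
  expect_equal(po_baseline(12, 1), 0)     # scaled margin below the offset
  # continuity at the floor boundary
  eps <- 1e-9
  expect_equal(po_baseline(15 + eps, 1), po_baseline(15, 1),
               tolerance = 1e-8)
  # piecewise linear above the floor
  expect_equal(po_baseline(19, 1) - po_baseline(17, 1),
               po_baseline(21, 1) - po_baseline(19, 1))
})

test_that("refined models honor their weight constraint and nest the baselines", {
  expect_equal(ma_safety_margin(10, 4, alpha = 0), 4)
  expect_equal(ma_safety_margin(10, 4, alpha = 1), 10)
  expect_equal(po_safety_margin(30, 1, beta = 1), 0)
  expect_equal(po_safety_margin(30, 1, beta = 0.5), po_baseline(30, 1))
  expect_error(ma_safety_margin(10, 4, alpha = 1.2), "\\[0, 1\\]")
  expect_error(po_safety_margin(30, 1, beta = -0.1), "\\[0, 1\\]")
})

test_that("constrained weight fits match boundary cases and recover truth", {
  # mu2 = mu1B exactly: alpha at the 0 boundary
  s <- simulate_margin_cohort(12, "ma", weight = 0.4, noise_sd = 0,
                              seed = 1)
  s$mu2 <- s$mu1B
  expect_equal(fit_alpha(s), 0)
  # generative recovery at vanishing noise
  s_po <- simulate_margin_cohort(26, "po", weight = 0.3, noise_sd = 1e-9,
                                 seed = 2)
  expect_equal(fit_beta(s_po), 0.3, tolerance = 1e-6)
  s_ma <- simulate_margin_cohort(26, "ma", weight = 0.7, noise_sd = 1e-9,
                                 seed = 3)
  expect_equal(fit_alpha(s_ma), 0.7, tolerance = 1e-6)
  # degenerate regressor
  s_deg <- s_po
  s_deg$mu1A <- 15
  s_deg$sigma2 <- s_deg$sigma1A
  expect_error(fit_beta(s_deg), "zero variance")
})

test_that("weight fits equal the dense grid-search oracle", {
  set.seed(4)
  for (r in 1:50) {
    s <- simulate_margin_cohort(10, if (r %% 2) "po" else "ma",
                                weight = stats::runif(1), noise_sd = 2,
                                seed = 400 + r)
    expect_lt(abs(fit_alpha(s) - grid_alpha(s)), 1e-4)
    expect_lt(abs(fit_beta(s) - grid_beta(s)), 1e-4)
  }
})

test_that("cross-validation is null on identical cohorts and orders models", {
  s <- simulate_obstacle_cohort(obstacle_cohort_spec("expt2b",
                                                     seed = 5))$summary
  cv <- cross_validate(s, s, "po")
  expect_equal(cv$pct_increase, 0)
  # a PO-generated pair: the PO model transfers, the MA model does not
  sa <- simulate_obstacle_cohort(obstacle_cohort_spec(
    "expt2a", ground_truth = "po", seed = 6))$summary
  sb <- simulate_obstacle_cohort(obstacle_cohort_spec(
    "expt2b", ground_truth = "po", seed = 7))$summary
  cv_po <- cross_validate(sa, sb, "po")
  cv_ma <- cross_validate(sa, sb, "ma")
  expect_lt(cv_po$mse_crossval, cv_ma$mse_crossval)
})

test_that("direction prediction index dissociates the generating model", {
  s_po <- simulate_obstacle_cohort(obstacle_cohort_spec(
    "expt2b", ground_truth = "po", seed = 8))$summary
  s_ma <- simulate_obstacle_cohort(obstacle_cohort_spec(
    "expt2b", ground_truth = "ma", seed = 9))$summary
  expect_gt(direction_prediction_index(s_po)$pi, 0)
  expect_lt(direction_prediction_index(s_ma)$pi, 0)
  # definitional anchors on explicit predictions
  expect_equal(direction_prediction_index(
    within(s_po, mu2 <- 4), mu_po = 4, mu_ma = -6)$pi, 1)
  expect_equal(direction_prediction_index(
    within(s_po, mu2 <- -6), mu_po = 4, mu_ma = -6)$pi, -1)
  expect_equal(direction_prediction_index(
    within(s_po, mu2 <- -1), mu_po = 4, mu_ma = -6)$pi, 0)
})

test_that("mirroring the raw data leaves fitted parameters unchanged", {
  spec <- obstacle_cohort_spec("expt2b", ground_truth = "po", seed = 10)
  sim <- simulate_obstacle_cohort(spec)
  tr <- sim$trials
  tr$direction <- -tr$direction
  tr$side <- ifelse(tr$side == "left", "right", "left")
  resum <- do.call(rbind, lapply(split(tr, tr$participant), function(b) {
    pool <- function(cond) {
      sel <- b$condition == cond
      mirror_and_pool(b$direction[sel], b$side[sel])
    }
    p1A <- pool("one_target_obstructed")
    p1B <- pool("one_target_unobstructed")
    p2 <- pool("two_target_obstacle")
    data.frame(participant = b$participant[1], variant = spec$variant,
               mu1A = p1A$mean, mu1B = p1B$mean, sigma1A = p1A$sd,
               sigma2 = p2$sd, mu2 = p2$mean)
  }))
  expect_equal(fit_beta(resum), fit_beta(sim$summary), tolerance = 1e-12)
  expect_equal(fit_alpha(resum), fit_alpha(sim$summary),
               tolerance = 1e-12)
})

test_that("weight sweep evaluates the grid it is given", {
  s <- simulate_obstacle_cohort(obstacle_cohort_spec("expt2b",
                                                     seed = 11))$summary
  sw <- weight_sweep(s, "po", weights = c(1 / 3, 1 / 2, 2 / 3))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$prediction) < 0))  # more timing weight, less margin
})
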