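test_that("adaptation coefficient is the no-intercept slope with the stated anchors", {
  sp <- min_jerk_speed(seq(0, 0.5, by = 1 / 200), 0.2, 0.5)
  ideal <- ideal_compensation(sp, B = 15)
  expect_equal(adaptation_coefficient(ideal, ideal), 1)
  expect_equal(adaptation_coefficient(rep(0, length(ideal)), ideal), 0)
  expect_equal(adaptation_coefficient(-0.5 * ideal, ideal), -0.5)
  # scale equivariance
  set.seed(21)
  for (c in stats::runif(10, -2, 2))
    expect_equal(adaptation_coefficient(c * ideal, ideal), c)
  # baseline subtraction
  expect_equal(adaptation_coefficient(ideal + 3, ideal, baseline = 3), 1)
  expect_error(adaptation_coefficient(ideal, ideal * 0), "zero")
})

test_that("aligned normalized profiles recover planned adaptation", {
  mk <- function(a, mt = 0.5) straight_trial(0, mt = mt, adaptation = a,
                                             clamp = "full")
  p <- align_and_normalize(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(max(p$force), 0.7, tolerance = 1e-6)
  expect_equal(p$n_trials, 3)
  # identical trials: profile equals any single normalized trial
  p1 <- align_and_normalize(list(mk(0.7)))
  expect_equal(p$force, p1$force, tolerance = 1e-12)
  # normalization contract: rescaling speed (movement time) leaves the
  # normalized peak unchanged when force is adaptation x ideal
  p_fast <- align_and_normalize(list(mk(0.7, mt = 0.4)))
  expect_equal(max(p_fast$force), max(p1$force), tolerance = 1e-6)
  # time zero is the 3 cm cue event
  expect_lt(min(abs(p$time)), 1 / 200)
  expect_error(align_and_normalize(list(straight_trial(0))), "clamp")
})

test_that("model force predictions combine profiles as specified", {
  t0 <- seq(-0.05, 0.3, by = 1 / 200)
  prof <- function(v) force_profile(t0, rep(v, length(t0)))
  f <- function(shape) force_profile(t0, shape)
  shape <- sin(seq(0, pi, length.out = length(t0)))

  ma <- ma_force_prediction(f(shape), f(shape))
  expect_equal(ma$force, shape)
  ma0 <- ma_force_prediction(f(shape), f(-shape))
  expect_equal(ma0$force, rep(0, length(t0)))
  expect_equal(ma_force_prediction(prof(2), prof(4))$force[1], 3)

  for (v in c(-1, 0.3, 2)) {
    po <- po_force_prediction(prof(v))
    expect_equal(po$force, prof(v)$force)
    expect_equal(po$meta$model, "PO")
  }
})

test_that("prediction index anchors at +1/-1/0 and is affine invariant", {
  expect_equal(prediction_index(7, po = 7, ma = 3)$pi, 1)
  expect_equal(prediction_index(3, po = 7, ma = 3)$pi, -1)
  expect_equal(prediction_index(5, po = 7, ma = 3)$pi, 0)
  expect_error(prediction_index(5, po = 3, ma = 3), "coincide")

  t0 <- seq(-0.05, 0.2, by = 1 / 200)
  set.seed(33)
  for (i in 1:20) {
    obs <- force_profile(t0, stats::rnorm(length(t0)))
    po <- force_profile(t0, stats::rnorm(length(t0)))
    ma <- force_profile(t0, stats::rnorm(length(t0)))
    pi0 <- prediction_index(obs, po, ma, interval_end = 0.1)$pi
    a <- stats::runif(1, 0.1, 3)
    b <- stats::rnorm(1)
    tf <- function(p) { p$force <- a * p$force + b; p }
    pi1 <- prediction_index(tf(obs), tf(po), tf(ma),
                            interval_end = 0.1)$pi
    expect_equal(pi1, pi0, tolerance = 1e-9)
  }
  # profile anchors: observed equal to a prediction
  po <- force_profile(t0, sin(t0 * 10) + 1)
  ma <- force_profile(t0, -sin(t0 * 10) - 1)
  expect_equal(prediction_index(po, po, ma, 0.1)$pi, 1)
  expect_equal(prediction_index(ma, po, ma, 0.1)$pi, -1)
})

test_that("feedback-response detection finds an injected divergence", {
  t0 <- seq(-0.05, 0.3, by = 1 / 200)
  n <- 8
  base <- matrix(stats::rnorm(n * length(t0), 0, 0.01), n)
  # identical left/right profiles: no detection
  expect_true(is.na(detect_t_resp(base, base, t0)))
  # strong divergence from exactly 150 ms after the cue
  effect <- outer(rep(1, n), pmax(t0 - 0.15, 0)) * 20
  got <- detect_t_resp(base + effect, base - effect, t0)
  expect_lt(abs(got - 0.15), 2 / 200 + 1e-9)
  expect_error(detect_t_resp(base[1:2, ], base[1:2, ], t0), "participants")
})
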