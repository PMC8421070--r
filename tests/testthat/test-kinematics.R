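test_that("movement direction matches analytic geometry", {
  expect_equal(movement_direction(straight_trial(0)), 0, tolerance = 1e-9)
  # chord angle of a circular arc at the 10 cm crossing is phi/2
  tr <- arc_trial(radius = 0.3)
  phi_ref <- 2 * asin(0.1 / (2 * 0.3))
  i0 <- movement_onset_index(tr)
  s <- tr$series
  onset_angle <- atan2(s$x[i0], s$y[i0])
  expected <- (phi_ref / 2 - onset_angle) * 180 / pi
  expect_equal(movement_direction(tr), expected, tolerance = 0.1)

  # mirror reflection negates the angle
  tr_m <- tr
  tr_m$series$x <- -tr_m$series$x
  tr_m$series$vx <- -tr_m$series$vx
  expect_equal(movement_direction(tr_m), -movement_direction(tr),
               tolerance = 1e-9)

  # trajectory that never reaches the reference displacement is flagged
  short <- straight_trial(0, D = 0.05)
  expect_true(is.na(movement_direction(short)))
})

test_that("trial filtering enforces the printed bounds and is idempotent", {
  mk <- function(mt) straight_trial(0, mt = mt)
  trials <- c(lapply(c(0.2, 0.5, 0.5, 2.5), mk),
              list(straight_trial(0, mt = 0.5, D = 0.05)))  # slow peak
  res <- filter_trials(trials, check_peak_speed = TRUE)
  expect_equal(res$report$n_input, 5)
  expect_equal(res$report$n_kept, 2)
  expect_equal(unname(res$report$rejected[["movement_time"]]), 2)
  expect_equal(unname(res$report$rejected[["peak_speed"]]), 1)
  # boundary values are kept (inclusive bounds)
  expect_equal(filter_trials(list(mk(0.225), mk(2)))$report$n_kept, 2)
  expect_equal(filter_trials(list(mk(0.2)))$report$n_kept, 0)
  # idempotent
  res2 <- filter_trials(res$kept, check_peak_speed = TRUE)
  expect_equal(res2$report$n_kept, res$report$n_kept)
  expect_equal(sum(res2$report$rejected), 0)
  # empty input
  empty <- filter_trials(list())
  expect_equal(empty$report$n_input, 0)
  expect_equal(empty$report$n_kept, 0)
})

test_that("movement-time threshold is the type-7 70th percentile of 18", {
  expect_equal(movement_time_threshold(rep(0.4, 18)), 0.4)
  expect_equal(movement_time_threshold(1:18), 12.9)
  # only the most recent 18 of a longer history are used
  expect_equal(movement_time_threshold(c(rep(100, 12), 1:18)),
               movement_time_threshold(1:18))
  expect_equal(movement_time_threshold(numeric(0), initial = 0.6), 0.6)
})

test_that("trajectory averaging matches analytic means", {
  tr <- straight_trial(5)
  avg <- average_trajectory(list(tr, tr))
  s <- tr$series[tr$series$y > 0, ]
  expect_equal(stats::approx(avg$y, avg$x, xout = s$y[10])$y, s$x[10],
               tolerance = 1e-6)

  # two straight lines at +/- theta average to the 0 deg line
  avg2 <- average_trajectory(list(straight_trial(10), straight_trial(-10)))
  expect_lt(max(abs(avg2$x)), 1e-12)

  # quadratic paths: pointwise mean is the mean-coefficient parabola
  quad <- function(a) {
    y <- seq(0, 0.2, by = 1 / 200 * 0.4)
    reach_trial(participant = "Q", epoch = "test",
                trial_type = "one_target", target_set = 0,
                cued_target = 0, sample_rate = 200, movement_time = 0.5,
                series = data.frame(t = seq_along(y) / 200 - 1 / 200,
                                    x = a * y^2, y = y, vx = 0, vy = 0.4,
                                    f_lat = 0))
  }
  avg3 <- average_trajectory(list(quad(0.5), quad(1.5)))
  # agreement to the linear-interpolation error bound f'' h^2 / 8
  expect_lt(max(abs(avg3$x - 1 * avg3$y^2)), 2 * 1.5 * 0.002^2 / 8)

  # non-monotone y is dropped with a warning
  bad <- quad(1)
  bad$series$y[10] <- bad$series$y[12]
  expect_warning(average_trajectory(list(quad(1), bad)), "non-monotone")
})

test_that("mirroring and pooling respects the left-side convention", {
  res <- mirror_and_pool(c(5, 5, -5, -5), c("left", "left", "right",
                                            "right"))
  expect_equal(res$mean, 5)
  expect_equal(res$sd, 0)
  expect_equal(mirror_and_pool(rep(0, 4), rep("left", 4))$mean, 0)

  set.seed(5)
  dirs <- stats::rnorm(40, 3, 2)
  sides <- sample(c("left", "right"), 40, replace = TRUE)
  spatial <- ifelse(sides == "right", -dirs, dirs)
  res <- mirror_and_pool(spatial, sides)
  expect_equal(res$mean, mean(dirs))
  expect_equal(res$sd, stats::sd(dirs))
  # reflection invariance: flip all sides and signs
  flipped <- mirror_and_pool(-spatial,
                             ifelse(sides == "left", "right", "left"))
  expect_equal(flipped$mean, res$mean)
  expect_equal(flipped$sd, res$sd)
})
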