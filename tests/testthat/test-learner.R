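test_that("single-direction training follows the scalar closed form", {
  l <- ss_learner(retention = 0.98, rate = 0.01)
  n <- 300
  sched <- data.frame(epoch = "training", trial_type = "one_target",
                      target = 0, ff_sign = 1, clamp = "none",
                      stringsAsFactors = FALSE)[rep(1, n), ]
  r <- simulate_ff_participant(sched, l, dir_noise_sd = 0,
                               force_noise_sd = 0, seed = 1)
  b <- drop(primitive_basis(0, l$centers, l$width))
  b_eff <- l$rate * sum(b^2)
  y <- 0
  curve <- numeric(n)
  for (i in seq_len(n)) {
    y <- l$retention * y
    y <- y + b_eff * (1 - y)
    curve[i] <- y
  }
  out <- drop(r$history %*% b)
  expect_lt(max(abs(out - curve)), 1e-10)
  # fixed point of the recursion, reached to 3 decimal places by n = 300
  expect_equal(out[n], ss_asymptote(l, 0, 1), tolerance = 1e-3)
})

test_that("zero learning leaves adaptation at zero everywhere", {
  l <- ss_learner(retention = 0.99, rate = 1e-12)
  r <- simulate_ff_participant(small_ff_schedule(), l, seed = 2,
                               force_noise_sd = 0)
  tab <- ff_adaptation_table(r$trials)
  expect_lt(max(abs(tab$ac)), 1e-6)
})

test_that("schedule has the 1:2:1 training ratio and no adjacent clamps", {
  set.seed(3)
  sched <- ff_schedule()
  expect_equal(nrow(sched), 1305)
  train <- sched[sched$epoch == "training", ]
  counts <- table(train$target)
  expect_equal(unname(counts[["0"]]),
               unname(counts[["-30"]]) + unname(counts[["30"]]))
  is_clamp <- sched$clamp != "none"
  expect_false(any(is_clamp[-1] & is_clamp[-length(is_clamp)]))
  # training epoch: 80% field / 20% clamp
  expect_equal(mean(train$clamp == "full"), 0.2, tolerance = 0.01)
})

test_that("cohort simulation is reproducible and shows balanced adaptation", {
  r1 <- simulate_ff_cohort(n = 2, seed = 7, schedule = small_ff_schedule())
  r2 <- simulate_ff_cohort(n = 2, seed = 7, schedule = small_ff_schedule())
  expect_identical(r1[[1]]$history, r2[[1]]$history)
  expect_identical(r1[[2]]$trials[[5]]$series, r2[[2]]$trials[[5]]$series)

  coh <- simulate_ff_cohort(n = 4, seed = 11)
  tabs <- do.call(rbind, lapply(coh, function(r)
    ff_adaptation_table(r$trials)))
  acs <- stats::aggregate(ac ~ target, tabs, mean)
  ac <- stats::setNames(acs$ac, acs$target)
  # opposite sign for center vs lateral targets
  expect_gt(ac[["0"]], 0.5)
  expect_lt(ac[["-30"]], -0.5)
  expect_lt(ac[["30"]], -0.5)
  # similar magnitudes across the three targets
  mags <- abs(ac)
  expect_lt((max(mags) - min(mags)) / max(mags), 0.15)
})
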