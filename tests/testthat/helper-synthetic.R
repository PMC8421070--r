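# Synthetic fixtures built in code: straight and arc reaches with
# minimum-jerk speed profiles, plus a brute-force collision oracle.

straight_trial <- function(direction = 0, mt = 0.5, D = 0.2,
                           rate = 200, adaptation = 0, B = 15,
                           clamp = "none", trial_type = "one_target",
                           epoch = "test", participant = "S1") {
  tt <- seq(0, mt, by = 1 / rate)
  tau <- tt / mt
  disp <- D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  sp <- D * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / mt
  th <- direction * pi / 180
  reach_trial(
    participant = participant, epoch = epoch, trial_type = trial_type,
    target_set = if (trial_type == "two_target") c(-30, 30) else direction,
    cued_target = direction,
    ff = if (clamp == "none" && adaptation == 0) NULL
    else ff_condition(B = B, clamp = clamp),
    sample_rate = rate, movement_time = mt,
    series = data.frame(t = tt, x = disp * sin(th), y = disp * cos(th),
                        vx = sp * sin(th), vy = sp * cos(th),
                        f_lat = adaptation * B * sp),
    direction = direction)
}

# circular-arc path (center on the +x side for curvature > 0); the hand
# direction at arc angle phi is the chord angle phi/2
arc_trial <- function(radius = 0.3, mt = 0.5, rate = 200, D = 0.2) {
  tt <- seq(0, mt, by = 1 / rate)
  tau <- tt / mt
  s <- D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)  # arc length
  v <- D * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / mt
  phi <- s / radius
  x <- radius * (1 - cos(phi))
  y <- radius * sin(phi)
  reach_trial(participant = "A1", epoch = "test",
              trial_type = "one_target", target_set = 0, cued_target = 0,
              sample_rate = rate, movement_time = mt,
              series = data.frame(t = tt, x = x, y = y,
                                  vx = v * sin(phi), vy = v * cos(phi),
                                  f_lat = 0))
}

# dense point-in-rectangle oracle for collision detection
collision_oracle <- function(xy, geom, step = 1e-4) {
  dense <- list()
  for (i in seq_len(nrow(xy) - 1L)) {
    seg <- xy[c(i, i + 1L), ]
    len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
    k <- max(2L, ceiling(len / step))
    dense[[i]] <- cbind(seq(seg[1, 1], seg[2, 1], length.out = k),
                        seq(seg[1, 2], seg[2, 2], length.out = k))
  }
  pts <- do.call(rbind, dense)
  rel <- sweep(pts, 2, geom$center)
  a <- rel %*% geom$u
  b <- rel %*% geom$n
  tol <- 1e-9
  any(a >= -geom$width / 2 - tol & a <= geom$width / 2 + tol &
        b >= -geom$away - tol & b <= geom$toward + tol)
}

# small, fast schedule for cohort-level force-pipeline tests
small_ff_schedule <- function() {
  ff_schedule(n_baseline_null = 0, n_baseline_2t = 40, n_baseline_1t = 30,
              n_training = 150, n_test_ff = 60, n_test_ec = 24,
              n_test_partial = 16)
}

# dense grid-search oracles for the constrained 1-D fits
grid_alpha <- function(summary, step = 1e-4) {
  g <- seq(0, 1, by = step)
  sse <- vapply(g, function(a)
    sum((summary$mu2 - ma_safety_margin(summary$mu1A, summary$mu1B, a))^2),
    0)
  g[which.min(sse)]
}

grid_beta <- function(summary, step = 1e-4) {
  margin <- variant_margin(summary$mu1A, summary$variant)
  x <- margin * summary$sigma2 / summary$sigma1A - 15
  g <- seq(0, 1, by = step)
  sse <- vapply(g, function(b) sum((summary$mu2 - (1 - b) * x)^2), 0)
  g[which.min(sse)]
}

# profiled-offset SSE of the individuation model at an index triple
indiv_sse <- function(summary, kk) {
  m1A <- variant_margin(summary$mu1A, summary$variant)
  y <- summary$mu2 - mean(summary$mu2)
  p <- 0.5 * (kk[1] * m1A + (1 - kk[1]) * mean(m1A)) *
    (kk[2] * summary$sigma2 + (1 - kk[2]) * mean(summary$sigma2)) *
    (kk[3] / summary$sigma1A + (1 - kk[3]) / mean(summary$sigma1A))
  K0 <- mean(p) - mean(y)
  sum((y - (p - K0))^2)
}

grid_k <- function(summary, step = 1e-3) {
  g <- seq(0, 1, by = step)
  sse <- vapply(g, function(k) indiv_sse(summary, rep(k, 3)), 0)
  g[which.min(sse)]
}
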