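#' Gaussian motor-primitive basis
#'
#' Direction-local basis underlying the trial-by-trial learner: Gaussian
#' bumps of common width placed on a regular grid of movement directions.
#' Basis values lie in [0, 1] (peak 1 at each center).
#'
#' @param theta movement direction(s), deg.
#' @param centers primitive centers, deg.
#' @param width Gaussian width (deg).
#' @return matrix `length(theta) x length(centers)` of basis activations.
#' @export
primitive_basis <- function(theta, centers = seq(-45, 45, by = 7.5),
                            width = 15) {
  stopifnot(width > 0, all(is.finite(theta)))
  outer(theta, centers, function(th, c) exp(-(th - c)^2 / (2 * width^2)))
}

#' State-space learner parameters
#'
#' Linear state-space model with local motor primitives. On every trial the
#' state first decays by the retention factor; the movement then expresses
#' the decayed state, and the observed compensation error updates the
#' state along the basis activation of the movement direction:
#' \deqn{w \leftarrow A w; \quad w \leftarrow w + B_l \, e \, b(\theta)}
#' with `e = target - w'b(theta)` on field trials and `e = 0` on clamp
#' trials (the clamp suppresses error). Adaptation is expressed in units of
#' the center-target field: full compensation of the center (lateral)
#' target field corresponds to output +1 (-1).
#'
#' Behavioral data do not pin down the retention, learning rate or
#' primitive width; these are free parameters with defaults chosen to
#' give asymptotic adaptation near the 0.7-0.8 range under the 1:2:1
#' composite training schedule.
#'
#' @param retention per-trial retention factor in (0, 1].
#' @param rate learning rate (> 0).
#' @param centers,width basis layout, see [primitive_basis()].
#' @return a list of class `ss_learner`.
#' @export
ss_learner <- function(retention = 0.995, rate = 0.08,
                       centers = seq(-45, 45, by = 7.5), width = 15) {
  stopifnot(is.finite(retention), retention > 0, retention <= 1,
            is.finite(rate), rate > 0, width > 0)
  structure(list(retention = retention, rate = rate, centers = centers,
                 width = width),
            class = "ss_learner")
}

#' Closed-form asymptote of single-direction training
#'
#' For training confined to one direction the learner collapses to a scalar
#' recursion in the output `y`: `y_next = A y + B_eff (target - A y)` with
#' effective rate `B_eff = rate * ||b(theta)||^2`. Its fixed point is
#' `target * B_eff / (1 - A (1 - B_eff))`, i.e. `rate/(1 - retention*(1 -
#' rate))` in the scalar (single-primitive, unit-target) case. Used as an
#' independent check on the simulator.
#'
#' @param learner an [ss_learner()].
#' @param theta trained direction (deg).
#' @param target asymptotic compensation target (+1 or -1).
#' @return the fixed-point output level.
#' @export
ss_asymptote <- function(learner, theta = 0, target = 1) {
  b <- drop(primitive_basis(theta, learner$centers, learner$width))
  b_eff <- learner$rate * sum(b^2)
  target * b_eff / (1 - learner$retention * (1 - b_eff))
}

#' Training schedule for the multi-field experiment
#'
#' Builds the trial list of the composite-field paradigm: a baseline epoch
#' (null familiarization, 2-target trials with interspersed partial error
#' clamps, and 1-target trials with interspersed error clamps), a training
#' epoch of 1-target field trials with 20% error clamps and a 1:2:1
#' left:center:right direction ratio, and a test epoch mixing 1-target
#' field trials, 1-target error clamps and 2-target partial error clamps.
#' Error clamps are placed so that no two clamp trials are consecutive.
#'
#' Defaults reproduce the full paradigm (1305 reaches); pass smaller counts
#' for quick simulations. `gen_probes` switches the test-epoch 2-target
#' probes to 1-target error clamps spread over a dense direction grid, as
#' in the generalization variant of the experiment.
#'
#' @param n_baseline_null,n_baseline_2t,n_baseline_1t baseline trial counts.
#' @param n_training training-epoch trial count (80% field, 20% clamp).
#' @param n_test_ff,n_test_ec,n_test_partial test-epoch composition.
#' @param gen_probes if `TRUE`, replace 2-target probes with 1-target
#'   error clamps on `gen_directions`.
#' @param gen_directions probe directions (deg) for the generalization
#'   variant.
#' @return a `data.frame` with one row per trial: `epoch, trial_type,
#'   target, ff_sign, clamp`. `ff_sign` is the canonical compensation sign
#'   (+1 center-target field, -1 lateral-target field, NA null trial).
#' @export
ff_schedule <- function(n_baseline_null = 120, n_baseline_2t = 200,
                        n_baseline_1t = 85, n_training = 500,
                        n_test_ff = 300, n_test_ec = 50,
                        n_test_partial = 50, gen_probes = FALSE,
                        gen_directions = seq(-30, 30, by = 7.5)) {
  lateral <- c(-30, 30)
  one <- function(epoch, target, ff_sign, clamp) {
    data.frame(epoch = epoch, trial_type = "one_target", target = target,
               ff_sign = ff_sign, clamp = clamp, stringsAsFactors = FALSE)
  }
  spread_clamps <- function(n, frac) {
    # boolean clamp mask with no two TRUE adjacent (clamp fraction <= 1/2)
    n_clamp <- round(n * frac)
    if (n_clamp == 0) return(rep(FALSE, n))
    stopifnot(2 * n_clamp <= n + 1)
    gaps <- diff(floor(seq(0, n - n_clamp, length.out = n_clamp + 1)))
    mask <- unlist(lapply(gaps, function(g) c(rep(FALSE, g), TRUE)))
    mask[seq_len(n)]
  }
  dirs_121 <- function(n) {
    # 1:2:1 left:center:right, shuffled
    n_lat <- floor(n / 4)
    sample(c(rep(-30, n_lat), rep(30, n_lat),
             rep(0, n - 2 * n_lat)))
  }
  dirs_equal <- function(n) sample(rep_len(c(-30, 0, 30), n))

  sched <- list()
  if (n_baseline_null > 0)
    sched$b_null <- one("baseline", dirs_equal(n_baseline_null), NA, "none")
  if (n_baseline_2t > 0) {
    cl <- spread_clamps(n_baseline_2t, 0.2)
    sched$b_2t <- data.frame(
      epoch = "baseline", trial_type = "two_target", target = 0,
      ff_sign = NA_real_, clamp = ifelse(cl, "partial", "none"),
      stringsAsFactors = FALSE)
  }
  if (n_baseline_1t > 0) {
    cl <- spread_clamps(n_baseline_1t, 0.2)
    sched$b_1t <- one("baseline", dirs_equal(n_baseline_1t), NA,
                      ifelse(cl, "full", "none"))
  }
  if (n_training > 0) {
    cl <- spread_clamps(n_training, 0.2)
    tg <- dirs_121(n_training)
    sched$train <- one("training", tg, ifelse(tg == 0, 1, -1),
                       ifelse(cl, "full", "none"))
  }
  n_test <- n_test_ff + n_test_ec + n_test_partial
  if (n_test > 0) {
    is_probe <- spread_clamps(n_test, (n_test_ec + n_test_partial) / n_test)
    n_probe <- sum(is_probe)
    probe_partial <- rep(FALSE, n_probe)
    probe_partial[sample(n_probe, min(n_test_partial, n_probe))] <- TRUE
    test <- one("test", 0, NA_real_, "none")[rep(1, n_test), ]
    tg_ff <- dirs_121(n_test - n_probe)
    test$target[!is_probe] <- tg_ff
    test$ff_sign[!is_probe] <- ifelse(tg_ff == 0, 1, -1)
    if (gen_probes) {
      test$clamp[is_probe] <- "full"
      test$target[is_probe] <- sample(rep_len(gen_directions, n_probe))
    } else {
      test$clamp[is_probe] <- ifelse(probe_partial, "partial", "full")
      test$trial_type[is_probe][probe_partial] <- "two_target"
      tg_ec <- dirs_121(sum(!probe_partial))
      test$target[is_probe][!probe_partial] <- tg_ec
    }
    rownames(test) <- NULL
    sched$test <- test
  }
  out <- do.call(rbind, sched)
  rownames(out) <- NULL
  out
}

#' Simulate one participant of the multi-field experiment
#'
#' Runs the state-space learner through a schedule and emits trial records.
#' Field and null trials update the learner; on (partial) error-clamp
#' trials the error is clamped to zero and the planned lateral force is
#' measured instead. Clamp trials carry a full time series with a
#' minimum-jerk speed profile and `lateral force = planned adaptation x
#' ideal center-field compensation + noise`; non-clamp trials carry
#' metadata only (movement time, peak speed, realized direction) unless
#' `series = "all"`.
#'
#' On 2-target partial-clamp trials the planned adaptation follows the
#' ground-truth planning rule: under `"po"` it is the learner's output for
#' the realized intermediate direction (near 0 deg); under `"ma"` it is the
#' mean of the outputs for the two potential target directions. After the
#' target cue (3 cm excursion) plus `feedback_latency`, a cued-side
#' corrective force ramps in, which is what makes the feedback response
#' detectable downstream.
#'
#' @param schedule a data.frame from [ff_schedule()].
#' @param learner an [ss_learner()].
#' @param planning ground-truth planning rule for 2-target trials.
#' @param B field gain (N·s/m).
#' @param dir_noise_sd per-trial movement-direction noise SD (deg).
#' @param force_noise_sd measurement noise SD on lateral force (N).
#' @param feedback_latency time after target cue at which corrective
#'   forces begin (s).
#' @param corr_gain size of the corrective force, as a fraction of the
#'   ideal compensation amplitude.
#' @param participant participant id stored on each trial.
#' @param series `"clamp"` (default) or `"all"`: which trials get time
#'   series.
#' @param seed optional integer seed (set before any draws).
#' @return list with `trials` (list of [reach_trial()]) and `history`
#'   (matrix of primitive weights after each trial).
#' @export
simulate_ff_participant <- function(schedule, learner = ss_learner(),
                                    planning = c("po", "ma"), B = 15,
                                    dir_noise_sd = 6, force_noise_sd = 0.25,
                                    feedback_latency = 0.15,
                                    corr_gain = 0.5,
                                    participant = "P1",
                                    series = c("clamp", "all"),
                                    seed = NULL) {
  planning <- match.arg(planning)
  series <- match.arg(series)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(schedule) == 0) stop("empty schedule")
  stopifnot(all(abs(schedule$target) <= 42.5))
  if (!all(is.finite(c(learner$retention, learner$rate))))
    stop("non-finite learner parameters")

  m <- length(learner$centers)
  w <- numeric(m)
  history <- matrix(NA_real_, nrow(schedule), m)
  trials <- vector("list", nrow(schedule))
  dt <- 1 / 200

  for (i in seq_len(nrow(schedule))) {
    s <- schedule[i, ]
    w <- learner$retention * w
    theta_act <- s$target + stats::rnorm(1, 0, dir_noise_sd)
    b_act <- drop(primitive_basis(theta_act, learner$centers, learner$width))
    a_out <- sum(w * b_act)

    is_clamp <- s$clamp != "none"
    if (!is_clamp) {
      target_comp <- if (is.na(s$ff_sign)) 0 else s$ff_sign
      e <- target_comp - a_out
      w <- w + learner$rate * e * b_act
    }
    history[i, ] <- w

    mt <- min(max(stats::rnorm(1, 0.5, 0.05), 0.35), 0.7)
    peak <- 15 * 0.2 / (8 * mt)
    ff <- if (is.na(s$ff_sign) && !is_clamp) NULL else
      ff_condition(B = B, k = 1L, clamp = s$clamp)

    ser <- NULL
    a_plan <- a_out
    cue <- s$target
    if (is_clamp || series == "all") {
      if (s$trial_type == "two_target") {
        if (planning == "ma") {
          thL <- 30 + stats::rnorm(1, 0, dir_noise_sd)
          thR <- -30 + stats::rnorm(1, 0, dir_noise_sd)
          bb <- primitive_basis(c(thL, thR), learner$centers, learner$width)
          a_plan <- mean(drop(bb %*% w))
        } else {
          a_plan <- a_out
        }
      }
      tt <- seq(0, mt, by = dt)
      sp <- min_jerk_speed(tt, 0.2, mt)
      disp <- min_jerk_displacement(tt, 0.2, mt)
      th_r <- theta_act * pi / 180
      f <- a_plan * ideal_compensation(sp, B) +
        stats::rnorm(length(tt), 0, force_noise_sd)
      if (s$trial_type == "two_target" && is_clamp) {
        t_on <- stats::approx(disp, tt, xout = 0.03)$y
        cue <- sample(c(-30, 30), 1)
        ramp <- pmin(pmax((tt - t_on - feedback_latency) / 0.1, 0), 1)
        f <- f + sign(cue) * corr_gain * ideal_compensation(sp, B) * ramp
      }
      ser <- data.frame(
        t = tt, x = disp * sin(th_r), y = disp * cos(th_r),
        vx = sp * sin(th_r), vy = sp * cos(th_r), f_lat = f)
    }
    trials[[i]] <- reach_trial(
      participant = participant, epoch = s$epoch,
      trial_type = s$trial_type,
      target_set = if (s$trial_type == "two_target") c(-30, 30) else s$target,
      cued_target = cue,
      ff = ff, sample_rate = 200, movement_time = mt, series = ser,
      direction = theta_act, peak_speed = peak, planned_adaptation = a_plan,
      ff_sign = s$ff_sign)
  }
  list(trials = trials, history = history)
}

#' Simulate a cohort of the multi-field experiment
#'
#' Convenience wrapper running [simulate_ff_participant()] for `n`
#' participants with per-participant seeds split from one root seed by
#' counter, giving reproducible, participant-independent streams.
#'
#' @param n number of participants.
#' @param seed root integer seed.
#' @param schedule schedule data.frame shared by all participants (the
#'   clamp placement is rebuilt per participant from the seeded stream if
#'   `NULL`).
#' @param ... passed to [simulate_ff_participant()].
#' @return list of per-participant results.
#' @export
simulate_ff_cohort <- function(n = 16, seed = 1, schedule = NULL, ...) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    set.seed((seed * 1000L + i) %% .Machine$integer.max)
    sched <- if (is.null(schedule)) ff_schedule() else schedule
    simulate_ff_participant(sched, participant = sprintf("P%02d", i), ...)
  })
}
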