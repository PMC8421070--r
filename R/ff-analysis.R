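#' Force profile container
#'
#' Lateral force against time aligned to the target-cue onset (time 0 =
#' cue; negative times precede it, back to movement onset). Values are
#' normalized so that +1 equals the amplitude of the maximum force of the
#' ideal adaptive response for the center-target field.
#'
#' @param time time base (s), uniform, aligned to the cue.
#' @param force normalized lateral force values.
#' @param n_trials number of trials averaged.
#' @param meta optional named list (participant, target, model id, ...).
#' @return object of class `force_profile`.
#' @export
force_profile <- function(time, force, n_trials = 1L, meta = list()) {
  stopifnot(length(time) == length(force), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-8)
    stop("force profile time base must be uniform and increasing")
  structure(list(time = time, force = force, n_trials = n_trials,
                 meta = meta),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf(
    "<force_profile> %d samples, t in [%.3f, %.3f] s, %d trial(s)\n",
    length(x$time), min(x$time), max(x$time), x$n_trials))
  invisible(x)
}

#' Adaptation coefficient
#'
#' Slope of the no-intercept least-squares regression of the
#' baseline-subtracted measured lateral force onto the ideal compensatory
#' force. With the ideal profile expressed in center-target-field units,
#' +1 means full compensation of the center-target field and -1 full
#' compensation of the lateral-target field. Baseline subtraction removes
#' any force offset, which is why the regression carries no intercept.
#'
#' @param measured measured lateral force (N).
#' @param ideal ideal compensatory force (N), same length; must not be
#'   identically zero.
#' @param baseline baseline force profile to subtract (N); scalar 0 by
#'   default.
#' @return dimensionless slope.
#' @export
adaptation_coefficient <- function(measured, ideal, baseline = 0) {
  stopifnot(length(measured) == length(ideal))
  denom <- sum(ideal^2)
  if (denom == 0) stop("ideal compensation is identically zero")
  sum(ideal * (measured - baseline)) / denom
}

## time of the target-cue event (3 cm excursion) within a trial series
cue_onset_time <- function(trial, cue_displacement = 0.03) {
  s <- trial$series
  disp <- sqrt(s$x^2 + s$y^2)
  if (max(disp) < cue_displacement) stop("trial never reaches cue distance")
  stats::approx(disp, s$t, xout = cue_displacement, ties = "ordered")$y
}

#' Align clamp-trial force profiles to the cue and normalize
#'
#' For each (partial) error-clamp trial, the lateral force is expressed in
#' units of the peak ideal center-target compensation for that trial
#' (`B * peak speed`), the time base is shifted so 0 is the target-cue
#' onset (the 3 cm excursion event, 40-50 ms after movement onset), an
#' optional baseline profile on the same aligned base is subtracted, and
#' profiles are averaged on the largest aligned span common to all trials.
#'
#' @param trials list of clamp [reach_trial()]s with series.
#' @param baseline optional [force_profile()] subtracted after alignment.
#' @param span optional numeric length-2 `c(pre, post)` seconds around the
#'   cue to restrict the output to (defaults to the common span).
#' @return a [force_profile()].
#' @export
align_and_normalize <- function(trials, baseline = NULL, span = NULL) {
  trials <- Filter(function(tr) !is.null(tr$series) &&
                     !is.null(tr$ff) && tr$ff$clamp != "none", trials)
  if (length(trials) == 0) stop("no clamp trials with series")
  dt <- 1 / trials[[1L]]$sample_rate
  aligned <- lapply(trials, function(tr) {
    t_on <- cue_onset_time(tr)
    i0 <- movement_onset_index(tr)
    sp <- trial_speed(tr)
    divisor <- tr$ff$B * max(sp)
    if (divisor <= 0) stop("normalization divisor must be positive")
    list(t = tr$series$t - t_on, f = tr$series$f_lat / divisor,
         t_min = tr$series$t[i0] - t_on)
  })
  t_pre <- max(vapply(aligned, function(a) a$t_min, 0))
  t_post <- min(vapply(aligned, function(a) max(a$t), 0))
  if (!is.null(span)) {
    t_pre <- max(t_pre, -abs(span[1]))
    t_post <- min(t_post, abs(span[2]))
  }
  if (t_post <= t_pre) stop("no common aligned span across trials")
  grid <- seq(t_pre, t_post, by = dt)
  fs <- vapply(aligned,
               function(a) stats::approx(a$t, a$f, xout = grid)$y,
               numeric(length(grid)))
  fs <- matrix(fs, nrow = length(grid))
  prof <- force_profile(grid, rowMeans(fs), n_trials = length(trials))
  if (!is.null(baseline)) {
    bl <- stats::approx(baseline$time, baseline$force, xout = grid,
                        rule = 2)$y
    prof$force <- prof$force - bl
  }
  prof
}

## restrict two or more profiles to their common time grid
common_grid <- function(profiles) {
  t0 <- max(vapply(profiles, function(p) min(p$time), 0))
  t1 <- min(vapply(profiles, function(p) max(p$time), 0))
  if (t1 <= t0) stop("profiles share no common time span")
  dt <- diff(profiles[[1L]]$time[1:2])
  grid <- seq(t0, t1, by = dt)
  vals <- lapply(profiles, function(p)
    stats::approx(p$time, p$force, xout = grid)$y)
  list(time = grid, values = vals)
}

#' Motor-averaging force prediction
#'
#' The pointwise mean of the adaptive responses (1-target clamp profiles)
#' for the left and right potential targets.
#'
#' @param left,right [force_profile()]s on a common sampling rate.
#' @return a [force_profile()] with `meta$model = "MA"`.
#' @export
ma_force_prediction <- function(left, right) {
  cg <- common_grid(list(left, right))
  force_profile(cg$time, (cg$values[[1L]] + cg$values[[2L]]) / 2,
                n_trials = left$n_trials + right$n_trials,
                meta = list(model = "MA"))
}

#' Performance-optimization force prediction
#'
#' The adaptive response for the center target, relabeled: under
#' performance optimization the intermediate movement is planned as a
#' center-directed movement, so its appropriate compensation is the
#' center-target response itself.
#'
#' @param center a [force_profile()].
#' @return the same profile with `meta$model = "PO"`.
#' @export
po_force_prediction <- function(center) {
  center$meta$model <- "PO"
  center
}

#' Prediction index between two model predictions
#'
#' Locates an observation between the performance-optimization and
#' motor-averaging predictions: with `mu_C = (mu_PO + mu_MA)/2` and
#' `mu_D = (mu_PO - mu_MA)/2`, `PI = (mu_2 - mu_C) / mu_D`. +1 means the
#' observation equals the PO prediction, -1 the MA prediction, 0 halfway.
#' For profiles, the `mu` are means over the interval from movement onset
#' (the profile start) to `interval_end` seconds relative to the cue. The
#' index is invariant under any common affine rescaling of all three
#' inputs.
#'
#' @param observed,po,ma [force_profile()]s, or plain numbers (e.g. mean
#'   movement directions).
#' @param interval_end end of the averaging interval (s, cue-aligned;
#'   0 = cue onset, ~0.15 = feedback-response onset); ignored for scalar
#'   input.
#' @return list of class `prediction_result`: `mu2, muPO, muMA, muC, muD,
#'   pi`.
#' @export
prediction_index <- function(observed, po, ma, interval_end = 0) {
  if (inherits(observed, "force_profile")) {
    cg <- common_grid(list(observed, po, ma))
    sel <- cg$time <= interval_end + 1e-12
    if (!any(sel)) stop("empty averaging interval")
    mu2 <- mean(cg$values[[1L]][sel])
    muPO <- mean(cg$values[[2L]][sel])
    muMA <- mean(cg$values[[3L]][sel])
  } else {
    mu2 <- observed; muPO <- po; muMA <- ma
  }
  muC <- (muPO + muMA) / 2
  muD <- (muPO - muMA) / 2
  if (muD == 0) stop("MA and PO predictions coincide; index undefined")
  structure(list(mu2 = mu2, muPO = muPO, muMA = muMA, muC = muC,
                 muD = muD, pi = (mu2 - muC) / muD),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction index: %+.3f (mu2 = %.3f, PO = %.3f, MA = %.3f)\n",
              x$pi, x$mu2, x$muPO, x$muMA))
  invisible(x)
}

#' Detect the onset of target-specific feedback responses
#'
#' Earliest time after the cue at which left-cued and right-cued 2-target
#' partial-clamp force profiles differ across participants: a two-sided
#' paired t-test of (left - right) at every sample, requiring p < alpha
#' sustained over `sustain` consecutive samples to suppress isolated false
#' positives.
#'
#' @param left,right numeric matrices, participants x time, of per-
#'   participant mean normalized force profiles by cued side.
#' @param time cue-aligned time base (s) matching the columns.
#' @param alpha significance level.
#' @param sustain required run length of significant samples.
#' @return detection time (s after the cue), or `NA` if never detected.
#' @export
detect_t_resp <- function(left, right, time, alpha = 0.01, sustain = 3) {
  stopifnot(is.matrix(left), dim(left)[1] == dim(right)[1],
            ncol(left) == length(time), ncol(right) == length(time))
  n <- nrow(left)
  if (n < 3) stop("at least 3 participants required")
  d <- left - right
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  sig <- !is.na(p) & p < alpha & time > 0
  run <- 0L
  for (j in seq_along(sig)) {
    run <- if (sig[j]) run + 1L else 0L
    if (run >= sustain) return(time[j - sustain + 1L])
  }
  NA_real_
}
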