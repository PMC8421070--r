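#' Movement-onset sample of a trial
#'
#' Onset is the first sample where hand speed exceeds 5 cm/s or
#' displacement from the start exceeds 3 cm, whichever occurs first,
#' mirroring the online detection rule used during the experiments.
#'
#' @param trial a [reach_trial()] with a time series.
#' @return integer sample index.
#' @export
movement_onset_index <- function(trial) {
  stopifnot(!is.null(trial$series))
  sp <- trial_speed(trial)
  disp <- with(trial$series, sqrt(x^2 + y^2))
  idx <- which(sp > 0.05 | disp > 0.03)
  if (length(idx) == 0) stop("no movement detected")
  idx[1L]
}

#' Initial movement direction of a trial
#'
#' Signed angle (deg, positive = leftward/counter-clockwise) between the
#' hand direction at movement onset and the hand direction at a reference
#' displacement: 10 cm from the start (`at_10cm`) or half of the reach
#' amplitude (`at_midpoint`, the axis of the obstacle protrusion for 20 cm
#' reaches). Hand direction is the direction of the vector from the start
#' position to the hand. The crossing of the reference displacement is
#' located by linear interpolation between samples.
#'
#' @param trial a [reach_trial()] with a time series.
#' @param mode reference-displacement rule.
#' @param amplitude reach amplitude (m), used by `at_midpoint`.
#' @return direction (deg), or `NA` (with attribute `reason`) if the
#'   trajectory never reaches the reference displacement.
#' @export
movement_direction <- function(trial, mode = c("at_10cm", "at_midpoint"),
                               amplitude = 0.2) {
  mode <- match.arg(mode)
  ref <- if (mode == "at_10cm") 0.10 else amplitude / 2
  s <- trial$series
  disp <- sqrt(s$x^2 + s$y^2)
  if (max(disp) < ref) {
    out <- NA_real_
    attr(out, "reason") <- "reference displacement not reached"
    return(out)
  }
  i0 <- movement_onset_index(trial)
  cross <- which(disp >= ref)[1L]
  if (cross == 1L) {
    xr <- s$x[1L]; yr <- s$y[1L]
  } else {
    a <- (ref - disp[cross - 1L]) / (disp[cross] - disp[cross - 1L])
    xr <- s$x[cross - 1L] + a * (s$x[cross] - s$x[cross - 1L])
    yr <- s$y[cross - 1L] + a * (s$y[cross] - s$y[cross - 1L])
  }
  ang <- function(x, y) atan2(x, y)  # 0 = +y (straight ahead), + = left
  d <- ang(xr, yr) - ang(s$x[i0], s$y[i0])
  d <- (d + pi) %% (2 * pi) - pi
  d * 180 / pi
}

#' Filter trials on movement time and peak speed
#'
#' Keeps trials whose movement time lies in `[0.225, 2]` s; when
#' `check_peak_speed = TRUE` (force-field-style data) additionally requires
#' peak speed in `[0.2, 1]` m/s. Each rejected trial is counted once, under
#' the first bound it violates.
#'
#' @param trials list of [reach_trial()] objects.
#' @param check_peak_speed apply the peak-speed bounds as well.
#' @param mt_bounds,speed_bounds numeric length-2 inclusive bounds.
#' @return list with `kept` (trial list) and `report` (a `filter_report`:
#'   `n_input`, `n_kept`, named rejection counts).
#' @export
filter_trials <- function(trials, check_peak_speed = FALSE,
                          mt_bounds = c(0.225, 2),
                          speed_bounds = c(0.2, 1)) {
  reasons <- c(movement_time = 0L, peak_speed = 0L)
  keep <- logical(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    mt <- tr$movement_time
    if (!is.finite(mt) || mt < mt_bounds[1] || mt > mt_bounds[2]) {
      reasons["movement_time"] <- reasons["movement_time"] + 1L
      next
    }
    if (check_peak_speed) {
      ps <- trial_peak_speed(tr)
      if (!is.finite(ps) || ps < speed_bounds[1] || ps > speed_bounds[2]) {
        reasons["peak_speed"] <- reasons["peak_speed"] + 1L
        next
      }
    }
    keep[i] <- TRUE
  }
  report <- structure(
    list(n_input = length(trials), n_kept = sum(keep), rejected = reasons),
    class = "filter_report")
  list(kept = trials[keep], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: kept %d / %d trials\n", x$n_kept, x$n_input))
  for (r in names(x$rejected))
    if (x$rejected[[r]] > 0)
      cat(sprintf("  rejected (%s): %d\n", r, x$rejected[[r]]))
  invisible(x)
}

#' Adaptive movement-time threshold
#'
#' The 'too-slow' threshold used for reward feedback: the 70th percentile
#' (linear-interpolation percentile, quantile type 7) of the movement
#' times of the most recent (up to) 18 trials of the same type.
#'
#' @param history numeric vector of recent movement times (s), oldest
#'   first.
#' @param window number of most recent trials considered.
#' @param probs percentile level.
#' @param initial threshold returned for an empty history (s).
#' @return threshold (s).
#' @export
movement_time_threshold <- function(history, window = 18, probs = 0.7,
                                    initial = 0.6) {
  if (length(history) == 0) return(initial)
  recent <- utils::tail(history, window)
  unname(stats::quantile(recent, probs = probs, type = 7))
}

#' Average trajectory over trials
#'
#' Resamples each trial's x-position onto a common grid of y-positions
#' spaced every 0.254 mm and averages pointwise, controlling for
#' variations in hand velocity. Trials whose y-progression is not strictly
#' increasing over the averaged span are dropped with a warning.
#'
#' @param trials list of [reach_trial()] objects with series.
#' @param dy y-grid spacing (m).
#' @return data.frame with columns `y`, `x` (mean path) and `n` (trials
#'   contributing).
#' @export
average_trajectory <- function(trials, dy = 0.254e-3) {
  stopifnot(length(trials) >= 1)
  paths <- list()
  for (tr in trials) {
    s <- tr$series
    if (any(diff(s$y) <= 0)) {
      warning(sprintf("trial dropped from average: non-monotone y (%s)",
                      tr$participant))
      next
    }
    paths[[length(paths) + 1L]] <- s
  }
  if (length(paths) == 0) stop("no trials with monotone y progression")
  y_max <- min(vapply(paths, function(s) max(s$y), 0))
  y_min <- max(vapply(paths, function(s) min(s$y), 0))
  grid <- seq(y_min, y_max, by = dy)
  xs <- vapply(paths, function(s) stats::approx(s$y, s$x, xout = grid)$y,
               numeric(length(grid)))
  xs <- matrix(xs, nrow = length(grid))
  data.frame(y = grid, x = rowMeans(xs), n = length(paths))
}

#' Mirror right-side-condition directions and pool
#'
#' Obstacle experiments are balanced within participants across left- and
#' right-side obstacle placements. This folds both onto the left-side
#' convention by sign-flipping right-side directions, so that positive
#' always means the same thing relative to the obstacle, then pools and
#' returns the mean and sample SD.
#'
#' @param directions per-trial directions (deg).
#' @param sides character vector, `"left"` or `"right"`, same length.
#' @return list with `mean`, `sd`, `n` of the pooled (mirrored) sample.
#' @export
mirror_and_pool <- function(directions, sides) {
  stopifnot(length(directions) == length(sides),
            all(sides %in% c("left", "right")))
  pooled <- ifelse(sides == "right", -directions, directions)
  list(mean = mean(pooled),
       sd = if (length(pooled) > 1) stats::sd(pooled) else 0,
       n = length(pooled))
}
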