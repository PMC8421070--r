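#' Construct a reach trial record
#'
#' A trial couples per-trial metadata with an optional uniformly sampled
#' kinematic/force time series. Angles follow the convention 0 deg =
#' straight ahead, positive = leftward; the workspace frame has x lateral
#' (positive left) and y forward, with reaches starting at the origin.
#'
#' @param participant participant identifier.
#' @param epoch `"baseline"`, `"training"` or `"test"`.
#' @param trial_type `"one_target"` or `"two_target"`.
#' @param target_set numeric vector of potential target directions (deg).
#' @param cued_target final target direction (deg).
#' @param ff an [ff_condition()], or `NULL` for unperturbed trials.
#' @param obstacle_side `"none"`, `"left"` or `"right"`.
#' @param sample_rate sampling rate (Hz).
#' @param movement_time movement duration (s).
#' @param series optional `data.frame` with columns `t, x, y, vx, vy,
#'   f_lat` sampled uniformly at `sample_rate`.
#' @param ... further metadata fields stored verbatim (e.g. the planned
#'   movement direction a generator used).
#' @return an object of class `reach_trial`.
#' @export
reach_trial <- function(participant, epoch, trial_type, target_set,
                        cued_target, ff = NULL, obstacle_side = "none",
                        sample_rate = 200, movement_time = NA_real_,
                        series = NULL, ...) {
  stopifnot(epoch %in% c("baseline", "training", "test"),
            trial_type %in% c("one_target", "two_target"),
            obstacle_side %in% c("none", "left", "right"))
  if (trial_type == "two_target" && length(target_set) != 2L)
    stop("two_target trials must carry exactly 2 potential targets")
  if (!is.null(series)) {
    stopifnot(all(c("t", "x", "y", "vx", "vy", "f_lat") %in% names(series)))
    dt <- diff(series$t)
    if (any(dt <= 0) || max(abs(dt - 1 / sample_rate)) > 1e-9)
      stop("series must be strictly increasing and uniform at sample_rate")
  }
  structure(
    c(list(participant = participant, epoch = epoch, trial_type = trial_type,
           target_set = target_set, cued_target = cued_target, ff = ff,
           obstacle_side = obstacle_side, sample_rate = sample_rate,
           movement_time = movement_time, series = series),
      list(...)),
    class = "reach_trial")
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("<reach_trial> participant %s, %s %s, targets [%s] deg\n",
              x$participant, x$epoch, x$trial_type,
              paste(x$target_set, collapse = ", ")))
  if (!is.null(x$ff))
    cat(sprintf("  FF: B = %g N.s/m, k = %+d, clamp = %s\n",
                x$ff$B, x$ff$k, x$ff$clamp))
  if (!is.null(x$series))
    cat(sprintf("  series: %d samples @ %g Hz\n",
                nrow(x$series), x$sample_rate))
  invisible(x)
}

## speed series (m/s) of a trial
trial_speed <- function(trial) {
  with(trial$series, sqrt(vx^2 + vy^2))
}

## peak speed: from series if present, else recorded metadata
trial_peak_speed <- function(trial) {
  if (!is.null(trial$series)) return(max(trial_speed(trial)))
  if (!is.null(trial$peak_speed)) return(trial$peak_speed)
  NA_real_
}

## one-row metadata view used when assembling trial tables
trial_meta <- function(trial) {
  data.frame(
    participant = trial$participant, epoch = trial$epoch,
    type = trial$trial_type,
    target = trial$cued_target,
    ff_k = if (is.null(trial$ff)) NA_integer_ else trial$ff$k,
    ff_B = if (is.null(trial$ff)) NA_real_ else trial$ff$B,
    clamp = if (is.null(trial$ff)) "none" else trial$ff$clamp,
    obstacle = trial$obstacle_side,
    movement_time = trial$movement_time,
    stringsAsFactors = FALSE)
}
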