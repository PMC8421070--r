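## select trials by metadata
ff_select <- function(trials, epoch = NULL, clamp = NULL, type = NULL,
                      target = NULL) {
  Filter(function(tr) {
    cl <- if (is.null(tr$ff)) "none" else tr$ff$clamp
    (is.null(epoch) || tr$epoch %in% epoch) &&
      (is.null(clamp) || cl %in% clamp) &&
      (is.null(type) || tr$trial_type %in% type) &&
      (is.null(target) || isTRUE(all.equal(tr$target_set[1], target)) ||
         (length(tr$target_set) == 1 && tr$target_set == target))
  }, trials)
}

## adaptation coefficient of one clamp trial against the canonical
## (center-field) ideal compensation, with optional normalized baseline
ff_adaptation_coefficient <- function(trial, baseline = NULL) {
  sp <- trial_speed(trial)
  ideal <- ideal_compensation(sp, trial$ff$B)
  bl <- 0
  if (!is.null(baseline)) {
    t_on <- cue_onset_time(trial)
    bl <- stats::approx(baseline$time, baseline$force,
                        xout = trial$series$t - t_on, rule = 2)$y
    bl <- bl * trial$ff$B * max(sp)  # back to Newtons
  }
  adaptation_coefficient(trial$series$f_lat, ideal, bl)
}

#' Adaptation coefficients for a simulated participant
#'
#' Computes per-trial adaptation coefficients on 1-target error-clamp
#' trials of the chosen epoch, baseline-subtracted per direction using the
#' participant's baseline-epoch clamp profiles.
#'
#' @param trials list of [reach_trial()]s (one participant).
#' @param epoch epoch to measure in.
#' @return data.frame with `target`, `ac`, one row per clamp trial.
#' @export
ff_adaptation_table <- function(trials, epoch = "test") {
  rows <- list()
  for (d in c(-30, 0, 30)) {
    bl_trials <- ff_select(trials, epoch = "baseline", clamp = "full",
                           target = d)
    bl <- if (length(bl_trials) > 0) align_and_normalize(bl_trials) else NULL
    for (tr in ff_select(trials, epoch = epoch, clamp = "full", target = d))
      rows[[length(rows) + 1L]] <- data.frame(
        target = d, ac = ff_adaptation_coefficient(tr, bl))
  }
  do.call(rbind, rows)
}

#' Analyze a simulated multi-field cohort
#'
#' Full force-profile pipeline for a cohort from [simulate_ff_cohort()]:
#' per participant, baseline-epoch clamp profiles are subtracted from
#' test-epoch cue-aligned normalized profiles for the three 1-target
#' directions and the 2-target partial clamps; the motor-averaging
#' prediction averages the left and right responses, the
#' performance-optimization prediction is the center response; profiles
#' are averaged across participants; the feedback-response onset is
#' detected from cued-side differences; and the prediction index is
#' computed from movement onset to the cue and to the feedback-response
#' onset. When `gen_fit` is supplied, predictions are refined per
#' participant by the expected generalization over that participant's
#' realized movement directions.
#'
#' @param cohort list of per-participant results from
#'   [simulate_ff_cohort()].
#' @param gen_fit optional [fit_generalization()] result (or parameter
#'   set) used to refine the predictions.
#' @param t_resp feedback-response onset (s after the cue); detected from
#'   the data when `NULL`, falling back to 0.15 s if undetectable.
#' @return list with population `observed`, `ma`, `po` profiles, the
#'   per-interval [prediction_index()] results `pi_ton` and `pi_tresp`,
#'   `t_resp`, per-participant indices `pi_i_ton`/`pi_i_tresp`, and the
#'   pooled adaptation-coefficient table.
#' @export
analyze_ff_cohort <- function(cohort, gen_fit = NULL, t_resp = NULL) {
  obs_l <- list(); ma_l <- list(); po_l <- list()
  cued_left <- list(); cued_right <- list()
  ac_l <- list()
  for (i in seq_along(cohort)) {
    trials <- cohort[[i]]$trials
    bl_of <- function(d) {
      tr <- ff_select(trials, epoch = "baseline", clamp = "full",
                      target = d)
      if (length(tr) > 0) align_and_normalize(tr) else NULL
    }
    prof_of <- function(d) {
      align_and_normalize(
        ff_select(trials, epoch = "test", clamp = "full", target = d),
        baseline = bl_of(d))
    }
    left <- prof_of(30); right <- prof_of(-30); center <- prof_of(0)
    bl2 <- ff_select(trials, epoch = "baseline", clamp = "partial")
    bl2_prof <- if (length(bl2) > 0) align_and_normalize(bl2) else NULL
    partial <- ff_select(trials, epoch = "test", clamp = "partial")
    obs <- align_and_normalize(partial, baseline = bl2_prof)

    ma <- ma_force_prediction(left, right)
    po <- po_force_prediction(center)
    if (!is.null(gen_fit)) {
      dir_of <- function(sel) vapply(sel, function(tr) tr$direction, 0)
      lat_dirs <- dir_of(ff_select(trials, epoch = "test", clamp = "none",
                                   type = "one_target"))
      lat_dirs <- lat_dirs[abs(lat_dirs) > 15]  # lateral-target trials
      two_dirs <- dir_of(ff_select(trials, clamp = c("none", "partial"),
                                   type = "two_target"))
      scale_lat <- mean(c(
        refine_prediction(1, lat_dirs[lat_dirs > 0], gen_fit, nominal = 30),
        refine_prediction(1, lat_dirs[lat_dirs < 0], gen_fit,
                          nominal = -30)))
      ma$force <- ma$force * scale_lat
      po <- refine_prediction(po, two_dirs, gen_fit, nominal = 0)
    }
    obs_l[[i]] <- obs; ma_l[[i]] <- ma; po_l[[i]] <- po
    by_cue <- function(side) {
      sel <- Filter(function(tr) sign(tr$cued_target) == side, partial)
      if (length(sel) > 0) align_and_normalize(sel, baseline = bl2_prof)
      else NULL
    }
    cued_left[[i]] <- by_cue(1)
    cued_right[[i]] <- by_cue(-1)
    ac_l[[i]] <- cbind(participant = i, ff_adaptation_table(trials))
  }
  pop <- function(profiles) {
    cg <- common_grid(profiles)
    force_profile(cg$time, rowMeans(do.call(cbind, cg$values)),
                  n_trials = length(profiles))
  }
  observed <- pop(obs_l); ma <- pop(ma_l); po <- pop(po_l)

  if (is.null(t_resp)) {
    ok <- !vapply(cued_left, is.null, TRUE) &
      !vapply(cued_right, is.null, TRUE)
    t_resp <- NA_real_
    if (sum(ok) >= 3) {
      cg <- common_grid(c(cued_left[ok], cued_right[ok]))
      nl <- sum(ok)
      lmat <- t(vapply(cg$values[seq_len(nl)], identity,
                       numeric(length(cg$time))))
      rmat <- t(vapply(cg$values[nl + seq_len(nl)], identity,
                       numeric(length(cg$time))))
      t_resp <- detect_t_resp(lmat, rmat, cg$time)
    }
    if (!is.finite(t_resp)) t_resp <- 0.15
  }
  pi_of <- function(end) prediction_index(observed, po, ma, end)
  pi_i_of <- function(end) vapply(seq_along(obs_l), function(i)
    prediction_index(obs_l[[i]], po, ma, end)$pi, 0)
  list(observed = observed, ma = ma, po = po,
       pi_ton = pi_of(0), pi_tresp = pi_of(t_resp),
       pi_i_ton = pi_i_of(0), pi_i_tresp = pi_i_of(t_resp),
       t_resp = t_resp, adaptation = do.call(rbind, ac_l))
}

#' Generalization curve from a probe-variant cohort
#'
#' Population-averaged adaptation coefficients for every probed test-epoch
#' clamp direction of a cohort simulated with `gen_probes = TRUE`, ready
#' for [fit_generalization()].
#'
#' @param cohort list of per-participant results.
#' @return data.frame with `theta` (probe direction, deg) and `ac`
#'   (population-mean adaptation coefficient).
#' @export
generalization_curve <- function(cohort) {
  rows <- lapply(seq_along(cohort), function(i) {
    trials <- cohort[[i]]$trials
    probes <- ff_select(trials, epoch = "test", clamp = "full")
    data.frame(
      theta = vapply(probes, function(tr) tr$target_set[1], 0),
      ac = vapply(probes, ff_adaptation_coefficient, 0))
  })
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(ac ~ theta, data = all, FUN = mean)
  agg[order(agg$theta), ]
}
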