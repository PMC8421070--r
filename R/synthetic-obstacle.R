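#' Specification of a synthetic obstacle-avoidance cohort
#'
#' Distributional description of a cohort for the obstacle experiments.
#' All angles live in the mirrored left-obstacle frame in which positive
#' is the direction of increasing 2-target safety margin (rightward for a
#' left-side obstacle). In that frame the mean obstructed-target
#' deflection `mu1A` is positive for the `expt2a` obstacle (deflections
#' toward the midline) and negative for the `expt2b` obstacle (deflections
#' away from the midline); the safety-margin magnitude is recovered via
#' [variant_margin()].
#'
#' Defaults emulate the corresponding experiment: 8 participants with
#' `mu1A` around +28 deg for `expt2a`, 26 participants with `mu1A` around
#' -22 deg for `expt2b`; direction variabilities are lognormal around 4
#' deg so that 1- and 2-target variabilities share one distribution; 50
#' trials per condition.
#'
#' @param variant `"expt2a"` or `"expt2b"`.
#' @param n participants (overrides the variant default).
#' @param ground_truth planning rule generating 2-target means: `"ma"`
#'   (equal-weight motor average) or `"po"` (equal-weight safety-margin
#'   optimization).
#' @param mu1A_mean,mu1A_sd distribution of per-participant mean
#'   obstructed-target deflections (deg, frame-signed).
#' @param mu1B_mean,mu1B_sd distribution of unobstructed-target
#'   deflections (deg).
#' @param sigma_meanlog,sigma_sdlog lognormal parameters for the direction
#'   variabilities `sigma1A` and `sigma2` (deg).
#' @param n_trials trials per condition per participant (>= 2).
#' @param weight optional ground-truth weighting parameter: when given,
#'   2-target means follow the refined model (`alpha = weight` for MA,
#'   `beta = weight` for PO, without the baseline floor) instead of the
#'   equal-weight baseline.
#' @param seed root integer seed.
#' @return list of class `obstacle_cohort_spec`.
#' @export
obstacle_cohort_spec <- function(variant = c("expt2b", "expt2a"), n = NULL,
                                 ground_truth = c("po", "ma"),
                                 mu1A_mean = NULL, mu1A_sd = 4,
                                 mu1B_mean = 0, mu1B_sd = 1,
                                 sigma_meanlog = log(4), sigma_sdlog = 0.12,
                                 n_trials = 50, weight = NULL, seed = 1L) {
  variant <- match.arg(variant)
  ground_truth <- match.arg(ground_truth)
  if (is.null(n)) n <- if (variant == "expt2a") 8L else 26L
  if (is.null(mu1A_mean)) mu1A_mean <- if (variant == "expt2a") 28 else -22
  stopifnot(n >= 2, n_trials >= 2, mu1A_sd >= 0, mu1B_sd >= 0,
            sigma_sdlog >= 0)
  if (!is.null(weight))
    stopifnot(is.finite(weight), weight >= 0, weight <= 1)
  structure(list(variant = variant, n = n, ground_truth = ground_truth,
                 mu1A_mean = mu1A_mean, mu1A_sd = mu1A_sd,
                 mu1B_mean = mu1B_mean, mu1B_sd = mu1B_sd,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 n_trials = n_trials, weight = weight,
                 seed = as.integer(seed)),
            class = "obstacle_cohort_spec")
}

#' Safety-margin magnitude from a frame-signed deflection
#'
#' Maps the frame-signed obstructed-target deflection onto the (positive)
#' safety margin around the obstacle: the margin grows with the deflection
#' for the `expt2a` obstacle and against it for the `expt2b` obstacle.
#'
#' @param mu1A frame-signed deflection(s), deg.
#' @param variant `"expt2a"` or `"expt2b"`.
#' @return margin(s), deg.
#' @export
variant_margin <- function(mu1A, variant) {
  stopifnot(all(variant %in% c("expt2a", "expt2b")))
  ifelse(variant == "expt2b", -mu1A, mu1A)
}

#' Simulate an obstacle-avoidance cohort
#'
#' Draws per-participant condition means and variabilities from the spec,
#' generates per-trial initial movement directions under the ground-truth
#' planning rule, splits them across left- and right-side obstacle
#' conditions (right-side trials carry mirrored signs, and obstacle-free
#' 2-target trials get a seeded random side label), and recovers
#' mirrored-and-pooled summaries with [mirror_and_pool()]. Participant
#' streams are split from the root seed by counter.
#'
#' @param spec an [obstacle_cohort_spec()].
#' @return list with `summary` (one row per participant: `participant,
#'   variant, mu1A, mu1B, sigma1A, sigma2, mu2, mu2_free, n_trials`),
#'   `trials` (long table: `participant, condition, side, direction`), and
#'   `truth` (the generating per-participant parameters).
#' @export
simulate_obstacle_cohort <- function(spec) {
  stopifnot(inherits(spec, "obstacle_cohort_spec"))
  summ <- vector("list", spec$n)
  trials <- vector("list", spec$n)
  truth <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    set.seed((spec$seed * 1000L + i) %% .Machine$integer.max)
    mu1A <- stats::rnorm(1, spec$mu1A_mean, spec$mu1A_sd)
    mu1B <- stats::rnorm(1, spec$mu1B_mean, spec$mu1B_sd)
    s1A <- stats::rlnorm(1, spec$sigma_meanlog, spec$sigma_sdlog)
    s2 <- stats::rlnorm(1, spec$sigma_meanlog, spec$sigma_sdlog)
    margin <- variant_margin(mu1A, spec$variant)
    mu2 <- if (spec$ground_truth == "ma") {
      ma_safety_margin(mu1A, mu1B, alpha = spec$weight %||% 0.5)
    } else if (is.null(spec$weight)) {
      po_safety_margin(margin, s2 / s1A)
    } else {
      po_safety_margin(margin, s2 / s1A, beta = spec$weight, floor = FALSE)
    }
    nt <- spec$n_trials
    draw <- function(mean, sd, n) stats::rnorm(n, mean, sd)
    cond <- function(condition, mean, sd) {
      dirs <- draw(mean, sd, nt)
      side <- rep(c("left", "right"), length.out = nt)
      data.frame(participant = i, condition = condition, side = side,
                 direction = ifelse(side == "right", -dirs, dirs),
                 stringsAsFactors = FALSE)
    }
    tr <- rbind(
      cond("one_target_obstructed", mu1A, s1A),
      cond("one_target_unobstructed", mu1B, s1A),
      cond("two_target_obstacle", mu2, s2))
    free <- draw(0, s2, nt)
    free_side <- sample(c("left", "right"), nt, replace = TRUE)
    tr <- rbind(tr, data.frame(
      participant = i, condition = "two_target_free", side = free_side,
      direction = ifelse(free_side == "right", -free, free),
      stringsAsFactors = FALSE))
    pool <- function(condition) {
      sel <- tr$condition == condition
      mirror_and_pool(tr$direction[sel], tr$side[sel])
    }
    p1A <- pool("one_target_obstructed")
    p1B <- pool("one_target_unobstructed")
    p2 <- pool("two_target_obstacle")
    p2f <- pool("two_target_free")
    summ[[i]] <- data.frame(
      participant = i, variant = spec$variant,
      mu1A = p1A$mean, mu1B = p1B$mean, sigma1A = p1A$sd, sigma2 = p2$sd,
      mu2 = p2$mean, mu2_free = p2f$mean, n_trials = nt,
      stringsAsFactors = FALSE)
    trials[[i]] <- tr
    truth[[i]] <- data.frame(participant = i, mu1A = mu1A, mu1B = mu1B,
                             sigma1A = s1A, sigma2 = s2, mu2 = mu2)
  }
  list(summary = do.call(rbind, summ), trials = do.call(rbind, trials),
       truth = do.call(rbind, truth))
}

#' Summary-level cohorts for parameter-recovery studies
#'
#' Generates per-participant summaries directly at the level the model
#' fits consume, without trial resampling, so that the only noise is the
#' stated residual noise on the 2-target mean. `simulate_margin_cohort()`
#' draws safety margins uniformly and builds `mu2` from the refined MA or
#' PO model with a known weight; `simulate_individuation_cohort()` builds
#' `mu2` from the individuation model with known indices.
#'
#' @param n participants.
#' @param model generating model family.
#' @param weight generating weight (`alpha` for MA, `beta` for PO).
#' @param margin_range range of the uniform per-participant safety
#'   margin (deg).
#' @param ratio_sdlog lognormal sd of the per-participant variability
#'   ratio around 1.
#' @param noise_sd SD of the additive direction noise on `mu2` (deg).
#' @param seed integer seed.
#' @return a summary data.frame (variant `"expt2a"`, so `mu1A` equals the
#'   safety margin) with attribute `"truth"` holding the generating
#'   parameters.
#' @export
simulate_margin_cohort <- function(n = 26, model = c("po", "ma"),
                                   weight = 0.5,
                                   margin_range = c(10, 35),
                                   ratio_sdlog = 0.05, noise_sd = 0.5,
                                   seed = 1L) {
  model <- match.arg(model)
  stopifnot(weight >= 0, weight <= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  mu1A <- stats::runif(n, margin_range[1], margin_range[2])
  mu1B <- stats::rnorm(n, 0, 1)
  sigma1A <- stats::rlnorm(n, log(4), 0.2)
  ratio <- stats::rlnorm(n, 0, ratio_sdlog)
  sigma2 <- sigma1A * ratio
  mu2 <- if (model == "ma") {
    ma_safety_margin(mu1A, mu1B, weight)
  } else {
    po_safety_margin(mu1A, ratio, beta = weight, floor = FALSE)
  }
  mu2 <- mu2 + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(participant = seq_len(n), variant = "expt2a",
                    mu1A = mu1A, mu1B = mu1B, sigma1A = sigma1A,
                    sigma2 = sigma2, mu2 = mu2,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(model = model, weight = weight)
  out
}

#' @rdname simulate_margin_cohort
#' @param k generating individuation indices: a single value, or three
#'   values `(k_mu, k_sigma2, k_sigma1)`.
#' @param mu1A_mean,mu1A_sd distribution of per-participant safety
#'   margins (deg).
#' @param sigma_sdlog lognormal spread of the direction variabilities.
#' @export
simulate_individuation_cohort <- function(n = 26, k = 0.5, noise_sd = 1.3,
                                          mu1A_mean = 22, mu1A_sd = 4,
                                          sigma_sdlog = 0.2, seed = 1L) {
  stopifnot(length(k) %in% c(1L, 3L), all(k >= 0), all(k <= 1),
            noise_sd >= 0)
  kk <- if (length(k) == 1L) rep(k, 3) else k
  set.seed(as.integer(seed))
  mu1A <- stats::rnorm(n, mu1A_mean, mu1A_sd)
  sigma1A <- stats::rlnorm(n, log(4), sigma_sdlog)
  sigma2 <- stats::rlnorm(n, log(4), sigma_sdlog)
  prod <- 0.5 * (kk[1] * mu1A + (1 - kk[1]) * mean(mu1A)) *
    (kk[2] * sigma2 + (1 - kk[2]) * mean(sigma2)) *
    (kk[3] / sigma1A + (1 - kk[3]) / mean(sigma1A))
  # center the product and re-anchor near the baseline population level
  mu2 <- po_safety_margin(mean(mu1A), mean(sigma2) / mean(sigma1A)) +
    (prod - mean(prod)) + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(participant = seq_len(n), variant = "expt2a",
                    mu1A = mu1A, mu1B = stats::rnorm(n, 0, 1),
                    sigma1A = sigma1A, sigma2 = sigma2, mu2 = mu2,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(k = kk)
  out
}
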