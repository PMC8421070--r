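#' Obstacle geometry for the avoidance experiments
#'
#' A rectangular obstacle centered midway between the start position and
#' the obstructed target, with its long axis perpendicular to the direct
#' path. It protrudes 2 cm towards the midline in both variants; away from
#' the midline it extends 10 cm in the `expt2a` variant (forcing
#' deflections toward the midline) and 0 cm in the `expt2b` variant
#' (promoting deflections away from the midline). The tip of the 2 cm
#' protrusion sits at a nominal 15 deg angular offset from the straight-
#' ahead direction; that constant enters the safety-margin models, not the
#' geometry.
#'
#' @param variant `"expt2a"` or `"expt2b"`.
#' @param side obstacle side, `"left"` or `"right"` (which lateral target
#'   is obstructed).
#' @param target_deg direction of the obstructed target (deg); defaults to
#'   +30 for a left-side obstacle, -30 for a right-side one.
#' @param amplitude reach amplitude (m).
#' @param width obstacle width along the movement direction (m).
#' @param toward,away protrusion lengths toward/away from the midline (m);
#'   `away` defaults by variant.
#' @return an object of class `obstacle_geometry` holding the center, the
#'   along-path unit vector `u`, the toward-midline unit vector `n`, and
#'   the extents.
#' @export
obstacle_geometry <- function(variant = c("expt2a", "expt2b"),
                              side = c("left", "right"),
                              target_deg = NULL, amplitude = 0.2,
                              width = 0.01, toward = 0.02, away = NULL) {
  variant <- match.arg(variant)
  side <- match.arg(side)
  if (is.null(target_deg)) target_deg <- if (side == "left") 30 else -30
  if (is.null(away)) away <- if (variant == "expt2a") 0.10 else 0
  if (width <= 0 || toward < 0 || away < 0 || toward + away <= 0)
    stop("degenerate obstacle rectangle")
  th <- target_deg * pi / 180
  u <- c(sin(th), cos(th))              # along the direct path
  center <- amplitude / 2 * u
  n <- c(cos(th), -sin(th))             # perpendicular
  if (n[1] * (-center[1]) < 0) n <- -n  # orient towards the midline
  structure(list(variant = variant, side = side, target_deg = target_deg,
                 center = center, u = u, n = n, width = width,
                 toward = toward, away = away, angular_offset = 15),
            class = "obstacle_geometry")
}

#' Detect a collision between a trajectory and an obstacle
#'
#' True if any interpolated segment of the sampled hand path intersects
#' the closed obstacle rectangle (touching an edge counts as a hit).
#'
#' @param trial a [reach_trial()] with a time series, or a data.frame /
#'   matrix of x, y positions.
#' @param geom an [obstacle_geometry()].
#' @return logical.
#' @export
detect_collision <- function(trial, geom) {
  stopifnot(inherits(geom, "obstacle_geometry"))
  xy <- if (inherits(trial, "reach_trial")) {
    cbind(trial$series$x, trial$series$y)
  } else if (is.data.frame(trial)) {
    cbind(trial$x, trial$y)
  } else as.matrix(trial)
  if (nrow(xy) < 1) return(FALSE)
  # coordinates in the obstacle frame: a along the path, b toward midline
  rel <- sweep(xy, 2, geom$center)
  a <- rel %*% geom$u
  b <- rel %*% geom$n
  lo <- c(-geom$width / 2, -geom$away)
  hi <- c(geom$width / 2, geom$toward)
  inside <- a >= lo[1] & a <= hi[1] & b >= lo[2] & b <= hi[2]
  if (any(inside)) return(TRUE)
  if (nrow(xy) < 2) return(FALSE)
  # slab clipping of each segment against the closed rectangle
  p <- cbind(a, b)
  for (i in seq_len(nrow(p) - 1L)) {
    p0 <- p[i, ]; d <- p[i + 1L, ] - p0
    t0 <- 0; t1 <- 1; hit <- TRUE
    for (ax in 1:2) {
      if (d[ax] == 0) {
        if (p0[ax] < lo[ax] || p0[ax] > hi[ax]) { hit <- FALSE; break }
      } else {
        ta <- (lo[ax] - p0[ax]) / d[ax]
        tb <- (hi[ax] - p0[ax]) / d[ax]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) { hit <- FALSE; break }
      }
    }
    if (hit) return(TRUE)
  }
  FALSE
}
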