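#' Curl force-field condition
#'
#' A viscous curl field pushes the hand orthogonally to its velocity with a
#' force proportional to speed. `k` selects the rotation sense (+1 =
#' counter-clockwise under the convention of [curl_force()], -1 = clockwise,
#' 0 = null field); `B` is the viscous gain in N·s/m. Error-clamp trials are
#' flagged through `clamp`: a full clamp channels the whole movement
#' (1-target trials), a partial clamp releases after 11 cm so that
#' corrections to the cued target remain possible (2-target trials).
#'
#' The clamp stiffness/damping constants (6000 N/m, 250 N·s/m) and the
#' 11 cm partial-clamp release distance are carried as metadata; clamp
#' trials are modeled as direct measurements of planned lateral force, not
#' as an integrated spring-damper system.
#'
#' @param B viscous gain (N·s/m), non-negative.
#' @param k sign switch in {-1, 0, +1}.
#' @param clamp one of `"none"`, `"full"`, `"partial"`.
#' @return an object of class `ff_condition`.
#' @export
ff_condition <- function(B = 15, k = 1L, clamp = c("none", "full", "partial")) {
  clamp <- match.arg(clamp)
  stopifnot(is.finite(B), B >= 0, k %in% c(-1, 0, 1))
  structure(
    list(B = B, k = as.integer(k), clamp = clamp,
         clamp_stiffness = 6000, clamp_damping = 250,
         partial_release_m = 0.11),
    class = "ff_condition")
}

#' Curl-field force for a hand velocity
#'
#' Returns `k * B * R %*% v`, where `R` is the 90-degree counter-clockwise
#' rotation `[[0, -1], [1, 0]]`. The force is always orthogonal to the
#' velocity, with magnitude `B * ||v||`. The rotation convention is exposed
#' here once; only the sign pairing between center- and lateral-target
#' fields matters downstream, and that is carried by `k`.
#'
#' @param v numeric length-2 hand velocity (m/s).
#' @param ff an [ff_condition()] with `clamp = "none"`.
#' @return numeric length-2 force (N).
#' @export
curl_force <- function(v, ff) {
  stopifnot(inherits(ff, "ff_condition"), length(v) == 2L)
  if (!all(is.finite(v))) stop("non-finite velocity")
  if (ff$clamp != "none") stop("curl force undefined on clamp trials")
  ff$k * ff$B * c(-v[2L], v[1L])
}

#' Ideal lateral compensation for a curl field
#'
#' The lateral force that exactly cancels a curl field of gain `B` at each
#' instant is `B * speed(t)` in magnitude. On the canonical lateral axis
#' (chosen so that full compensation of the center-target field is
#' positive), the ideal compensation is `k * B * speed(t)` with `k = +1`
#' for the center-target field and `k = -1` for the lateral-target field.
#'
#' @param speed numeric vector of hand speeds (m/s).
#' @param B viscous gain (N·s/m).
#' @param k canonical compensation sign (+1 center, -1 lateral).
#' @return numeric vector of lateral forces (N).
#' @export
ideal_compensation <- function(speed, B = 15, k = 1) {
  stopifnot(all(is.finite(speed)), is.finite(B), B >= 0)
  k * B * speed
}

#' Minimum-jerk speed profile
#'
#' Bell-shaped speed profile of a point-to-point reach of amplitude `D`
#' and duration `MT`: `v(t) = D * (30 tau^2 - 60 tau^3 + 30 tau^4) / MT`
#' with `tau = t / MT`. Peak speed is `15 D / (8 MT)`.
#'
#' @param t time (s) since movement onset; values outside [0, MT] give 0.
#' @param D movement amplitude (m).
#' @param MT movement time (s).
#' @return speeds (m/s).
#' @export
min_jerk_speed <- function(t, D = 0.2, MT = 0.5) {
  tau <- pmin(pmax(t / MT, 0), 1)
  D * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / MT
}

## displacement along the path for the same profile
min_jerk_displacement <- function(t, D = 0.2, MT = 0.5) {
  tau <- pmin(pmax(t / MT, 0), 1)
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}
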