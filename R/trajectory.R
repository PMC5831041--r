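#' Commanded foot trajectory as a function of oscillator phase
#'
#' During stance the foot tip moves backward along a line segment from the
#' anterior extreme position (AEP, `+s/2`) to the posterior extreme position
#' (PEP, `-s/2`); during swing it returns forward along an arc of height
#' `d`.  The trajectory is continuous and periodic in the phase.  Phases
#' outside `[0, 2*pi)` are wrapped.
#'
#' @param phi Oscillator phase(s) (rad); vectorized.
#' @param params A [gait_params()] object.
#' @return A tibble with columns `phi` (wrapped), `dx` (fore-aft foot offset
#'   relative to the leg root resting position) and `height` (foot height
#'   above ground), in the length units of `params`.
#' @export
#' @examples
#' p <- gait_params(beta = 0.5)
#' foot_trajectory(c(0, pi, 1.5 * pi), p)
foot_trajectory <- function(phi, params) {
  if (!inherits(params, "gait_params")) {
    abort("`params` must be a gait_params object")
  }
  phi <- wrap_phase(phi)
  beta <- params$beta
  bp2 <- 2 * beta * pi
  st <- phi < bp2
  u <- (phi - bp2) / (2 * (1 - beta))
  tibble::tibble(
    phi = phi,
    dx = ifelse(st, params$s * (0.5 - phi / bp2),
                params$s * (-0.5 + u / pi)),
    height = ifelse(st, 0, params$d * sin(u))
  )
}

#' Spring-leg kinematics commanded by the oscillator phase
#'
#' Dimensionless counterpart of [foot_trajectory()] for the quasi-static
#' body model: the spring's neutral length `L_star` (1 in stance, shortened
#' by the swing arc in swing) and the leg root offset `dx_star`.
#'
#' @param phi Oscillator phase(s) (rad); wrapped to `[0, 2*pi)`.
#' @param geom A [body_geometry()] object.
#' @return A tibble with columns `phi`, `L_star` and `dx_star`.
#' @export
#' @examples
#' g <- body_geometry(beta = 0.55)
#' spring_kinematics(c(0, (1 + 0.55) * pi), g)
spring_kinematics <- function(phi, geom) {
  if (!inherits(geom, "body_geometry")) {
    abort("`geom` must be a body_geometry object")
  }
  phi <- wrap_phase(phi)
  beta <- geom$beta
  bp2 <- 2 * beta * pi
  st <- phi < bp2
  u <- (phi - bp2) / (2 * (1 - beta))
  tibble::tibble(
    phi = phi,
    L_star = ifelse(st, 1, 1 - geom$d_star * sin(u)),
    dx_star = ifelse(st, geom$s_star * (0.5 - phi / bp2),
                     geom$s_star * (-0.5 + u / pi))
  )
}
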