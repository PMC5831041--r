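#' Controller timing and geometry of the leg cycle
#'
#' Bundles the parameters of the oscillator-driven leg trajectory.  The foot
#' follows a line segment of length `s` during stance
#' (`0 <= phi < 2*beta*pi`) and an arc of height `d` during swing
#' (`2*beta*pi <= phi < 2*pi`); the swing duration `T_sw` is held constant,
#' so the duty factor `beta` alone sets the locomotion speed.
#'
#' @param beta Duty factor: fraction of the step cycle spent in stance,
#'   strictly between 0 and 1.  The closed-form gait analysis additionally
#'   assumes `1/2 < beta < 2/3` (the event order of the wave gaits); values
#'   outside are allowed here and flagged downstream.
#' @param T_sw Swing duration (s).
#' @param s Stance line length: AEP-to-PEP distance (cm).
#' @param d Swing arc height (cm).
#' @param k_c Contralateral coupling gain (1/s).  A large value pins the
#'   left-right phase difference at `pi`.
#' @param tau Time constant of the first-order lag through which foot-contact
#'   feedback enters the oscillator (s).  `tau = 0` applies resets as
#'   instantaneous phase jumps.
#' @param body_length Optional body length (cm) for reporting speed in body
#'   lengths per second.
#' @return An object of class `gait_params`.
#' @seealso [derived_timing()], [foot_trajectory()]
#' @export
#' @examples
#' p <- gait_params(beta = 0.5)
#' derived_timing(p)
gait_params <- function(beta, T_sw = 10, s = 6, d = 6, k_c = 10, tau = 1,
                        body_length = NULL) {
  stop_if_not_scalar(beta, "beta")
  stop_if_not_scalar(T_sw, "T_sw")
  stop_if_not_scalar(s, "s")
  stop_if_not_scalar(d, "d")
  stop_if_not_scalar(k_c, "k_c")
  stop_if_not_scalar(tau, "tau")
  if (beta <= 0 || beta >= 1) {
    abort("degenerate duty factor: `beta` must satisfy 0 < beta < 1")
  }
  if (T_sw <= 0) abort("`T_sw` must be positive")
  if (s <= 0) abort("`s` must be positive")
  if (d <= 0) abort("`d` must be positive")
  if (k_c < 0) abort("`k_c` must be non-negative")
  if (tau < 0) abort("`tau` must be non-negative")
  if (!is.null(body_length)) stop_if_not_scalar(body_length, "body_length")
  structure(
    list(beta = beta, T_sw = T_sw, s = s, d = d, k_c = k_c, tau = tau,
         body_length = body_length),
    class = "gait_params"
  )
}

#' @export
print.gait_params <- function(x, ...) {
  cat("<gait_params>\n")
  cat(sprintf("  duty factor beta = %.4g, T_sw = %.4g s\n", x$beta, x$T_sw))
  cat(sprintf("  stance line s = %.4g, swing height d = %.4g\n", x$s, x$d))
  cat(sprintf("  coupling k_c = %.4g 1/s, feedback lag tau = %.4g s\n",
              x$k_c, x$tau))
  if (!is.null(x$body_length)) {
    cat(sprintf("  body length = %.4g\n", x$body_length))
  }
  invisible(x)
}

#' Dimensionless mechanical parameters of the spring-leg body
#'
#' The body is a rigid plate of half length `a_star` and half width `b_star`
#' standing on six massless vertical springs of relative stiffness
#' `K_star = K L / (M g)`; all lengths are normalized by the neutral leg
#' length `L`.  The commanded stance line length `s_star` and swing height
#' `d_star` mirror the controller's foot trajectory.
#'
#' The quasi-static analysis assumes `a_star`, `b_star`, `d_star` of order
#' one, `1/K_star` small, and `s_star` small compared to `a_star`
#' (propulsion is a perturbation); violations are warned about, not
#' rejected.
#'
#' @param beta Duty factor (shared with the controller).
#' @param K_star Relative spring stiffness `K L / (M g)` (dimensionless).
#'   The default together with `d_star = 1` gives the stiff-leg setting
#'   `d_star * K_star = 50`.
#' @param a_star Half body length = leg root spacing, in units of `L`.
#' @param b_star Half body width, in units of `L`.
#' @param d_star Swing arc height, in units of `L`.
#' @param s_star Stance line length, in units of `L`.  May be 0 (marching in
#'   place) or negative (backward walking; used by the gait symmetry
#'   checks).
#' @param L Physical neutral leg length (only a normalization constant).
#' @return An object of class `body_geometry`.
#' @export
#' @examples
#' body_geometry(beta = 0.55)
body_geometry <- function(beta, K_star = 50, a_star = 1, b_star = 1,
                          d_star = 1, s_star = 0.3, L = 1) {
  stop_if_not_scalar(beta, "beta")
  stop_if_not_scalar(K_star, "K_star")
  stop_if_not_scalar(a_star, "a_star")
  stop_if_not_scalar(b_star, "b_star")
  stop_if_not_scalar(d_star, "d_star")
  stop_if_not_scalar(s_star, "s_star")
  if (beta <= 0 || beta >= 1) {
    abort("degenerate duty factor: `beta` must satisfy 0 < beta < 1")
  }
  if (K_star <= 0 || a_star <= 0 || b_star <= 0 || d_star <= 0 || L <= 0) {
    abort("`K_star`, `a_star`, `b_star`, `d_star` and `L` must be positive")
  }
  if (d_star * K_star < 5) {
    warn("d_star * K_star < 5: the stiff-spring approximation is unreliable")
  }
  if (abs(s_star) > 0.75 * a_star) {
    warn("|s_star| is not small relative to a_star; propulsion is no longer a perturbation")
  }
  structure(
    list(beta = beta, K_star = K_star, a_star = a_star, b_star = b_star,
         d_star = d_star, s_star = s_star, L = L),
    class = "body_geometry"
  )
}

#' @export
print.body_geometry <- function(x, ...) {
  cat("<body_geometry>\n")
  cat(sprintf("  beta = %.4g, K* = %.4g (d*K* = %.4g)\n",
              x$beta, x$K_star, x$d_star * x$K_star))
  cat(sprintf("  a* = %.4g, b* = %.4g, d* = %.4g, s* = %.4g (s*/a* = %.4g)\n",
              x$a_star, x$b_star, x$d_star, x$s_star, x$s_star / x$a_star))
  invisible(x)
}

# engine-facing plain list
as_engine_geom <- function(geom) {
  if (!inherits(geom, "body_geometry")) {
    abort("`geom` must be a body_geometry object")
  }
  list(a_star = geom$a_star, b_star = geom$b_star, d_star = geom$d_star,
       K_star = geom$K_star, beta = geom$beta, s_star = geom$s_star)
}

warn_beta_range <- function(beta) {
  if (beta <= 0.5 || beta >= 2 / 3) {
    warn(sprintf(
      "beta = %.3g lies outside (1/2, 2/3); the wave-gait event order assumed by the closed-form analysis may not hold",
      beta
    ))
  }
}
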