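#' Contralateral antiphase coupling terms
#'
#' Each oscillator interacts only with its contralateral partner (legs 1-4,
#' 2-5, 3-6) through `g_i = -k_c * sin(phi_i - phi_j - pi)`, which pins the
#' left-right phase difference at `pi` for large `k_c`.  There is no direct
#' coupling between ipsilateral oscillators.
#'
#' @param phi Numeric vector of 6 oscillator phases (rad).
#' @param k_c Coupling gain (1/s).
#' @return Numeric vector of 6 coupling terms (rad/s).
#' @export
#' @examples
#' contralateral_coupling(c(0, 1, 2, pi, 1 + pi, 2 + pi), k_c = 10)
contralateral_coupling <- function(phi, k_c) {
  if (length(phi) != 6L) abort("`phi` must have length 6")
  partner <- c(4L, 5L, 6L, 1L, 2L, 3L)
  -k_c * sin(phi - phi[partner] - pi)
}

#' Phase-resetting amount for a foot contact
#'
#' When a foot touches the ground during its swing phase the oscillator
#' phase is reset to zero (stance onset), an advance of `2*pi - phi_td`.
#' Contact during the stance phase is ignored.  The branch boundary
#' `phi_td = 2*beta*pi` belongs to the swing branch.
#'
#' @param phi_td Phase(s) at touchdown (rad); wrapped to `[0, 2*pi)`.
#' @param beta Duty factor.
#' @return Reset amount(s) (rad): `0` for stance-phase contact,
#'   `2*pi - phi_td` for swing-phase contact.
#' @export
#' @examples
#' phase_reset_feedback(2 * pi - 0.1, beta = 0.5)
phase_reset_feedback <- function(phi_td, beta) {
  phi_td <- wrap_phase(phi_td)
  ifelse(phi_td >= 2 * beta * pi, 2 * pi - phi_td, 0)
}

#' State of the six-oscillator network
#'
#' @param phi Numeric vector of 6 oscillator phases (rad).
#' @param y Numeric vector of 6 feedback lag states (rad/s); decays toward 0
#'   in the absence of contact events.
#' @param t Time (s).
#' @param contact Logical vector of 6 foot-contact flags.  Contact detection
#'   is the plant's job, not this module's; the flags are carried as inputs.
#' @return An object of class `network_state`.
#' @export
network_state <- function(phi, y = rep(0, 6), t = 0, contact = rep(FALSE, 6)) {
  if (length(phi) != 6L || length(y) != 6L || length(contact) != 6L) {
    abort("`phi`, `y` and `contact` must have length 6")
  }
  structure(
    list(t = t, phi = wrap_phase(phi), y = as.numeric(y),
         contact = as.logical(contact)),
    class = "network_state"
  )
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> t = %.4g s\n", x$t))
  cat("  phi:", paste(sprintf("%.3f", x$phi), collapse = " "), "\n")
  cat("  y:  ", paste(sprintf("%.3f", x$y), collapse = " "), "\n")
  cat("  contact:", paste(ifelse(x$contact, "1", "0"), collapse = " "), "\n")
  invisible(x)
}

#' Advance the oscillator network by one time step
#'
#' Integrates `dphi_i/dt = omega + g_i + y_i` and `tau * dy_i/dt = -y_i`
#' with one fixed-step RK4 step.  Touchdown events listed in
#' `touchdown_legs` are applied before the step: the Dirac impulse of the
#' foot-contact feedback becomes an instantaneous jump `y_i <- y_i +
#' reset / tau`, whose integrated effect on the phase equals the reset
#' amount.  With `tau = 0` the reset is applied as a direct phase jump.
#'
#' @param state A [network_state()] object.
#' @param dt Time step (s); should be small relative to `1/k_c` and `tau`.
#' @param params A [gait_params()] object.
#' @param touchdown_legs Integer vector of legs (1-6) touching down at the
#'   start of this step.
#' @return The updated `network_state`.
#' @export
step_network <- function(state, dt, params, touchdown_legs = integer(0)) {
  if (!inherits(state, "network_state")) {
    abort("`state` must be a network_state object")
  }
  if (!inherits(params, "gait_params")) {
    abort("`params` must be a gait_params object")
  }
  if (dt <= 0) abort("`dt` must be positive")
  beta <- params$beta
  omega <- 2 * (1 - beta) * pi / params$T_sw
  phi <- state$phi
  y <- state$y
  contact <- state$contact
  bp2 <- 2 * beta * pi

  for (leg in touchdown_legs) {
    amt <- phase_reset_feedback(phi[leg], beta)
    if (params$tau > 0) {
      y[leg] <- y[leg] + amt / params$tau
    } else {
      phi[leg] <- wrap_phase(phi[leg] + amt)
    }
    contact[leg] <- TRUE
  }

  k_c <- params$k_c
  tau <- params$tau
  dphi <- function(p, yy) omega + contralateral_coupling(p, k_c) + yy
  dy <- if (tau > 0) function(yy) -yy / tau else function(yy) 0 * yy

  k1p <- dphi(phi, y);                         k1y <- dy(y)
  k2p <- dphi(phi + dt / 2 * k1p, y + dt / 2 * k1y); k2y <- dy(y + dt / 2 * k1y)
  k3p <- dphi(phi + dt / 2 * k2p, y + dt / 2 * k2y); k3y <- dy(y + dt / 2 * k2y)
  k4p <- dphi(phi + dt * k3p, y + dt * k3y);   k4y <- dy(y + dt * k3y)

  phi_new <- wrap_phase(phi + dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p))
  y_new <- y + dt / 6 * (k1y + 2 * k2y + 2 * k3y + k4y)

  # a leg whose commanded phase crosses into the swing branch lifts off
  contact[phi < bp2 & phi_new >= bp2] <- FALSE

  network_state(phi_new, y_new, state$t + dt, contact)
}

#' Simulate the oscillator network over a time span
#'
#' Convenience wrapper around [step_network()] for open-loop runs: touchdown
#' events are supplied as a table of times and legs (the plant's job in the
#' closed loop).  Returns a long trajectory table ready for CSV export.
#'
#' @param params A [gait_params()] object.
#' @param phi0 Initial phases (6, rad).
#' @param duration Simulated time (s).
#' @param dt Integrator step (s).
#' @param touchdowns Optional data frame with columns `t` and `leg`; each
#'   event is applied at the first step boundary at or after `t`.
#' @param record_every Record state every this many steps.
#' @return A tibble with columns `t`, `leg`, `phi`, `y`, `dx`, `height`,
#'   `contact`.
#' @export
#' @examples
#' p <- gait_params(beta = 0.5, T_sw = 1)
#' out <- simulate_network(p, phi0 = runif(6, 0, 2 * pi), duration = 0.1,
#'                         dt = 1e-3, record_every = 10)
simulate_network <- function(params, phi0, duration, dt = 1e-3,
                             touchdowns = NULL, record_every = 10L) {
  if (!inherits(params, "gait_params")) {
    abort("`params` must be a gait_params object")
  }
  n_steps <- max(1L, ceiling(duration / dt))
  state <- network_state(phi0)
  ev_step <- integer(0)
  ev_leg <- integer(0)
  if (!is.null(touchdowns)) {
    ev_step <- pmax(0L, ceiling(touchdowns$t / dt))
    ev_leg <- as.integer(touchdowns$leg)
  }
  rec <- vector("list", n_steps %/% record_every + 2L)
  ri <- 1L
  snap <- function(st) {
    tr <- foot_trajectory(st$phi, params)
    tibble::tibble(t = st$t, leg = 1:6, phi = st$phi, y = st$y,
                   dx = tr$dx, height = tr$height, contact = st$contact)
  }
  rec[[ri]] <- snap(state)
  for (k in seq_len(n_steps)) {
    legs <- ev_leg[ev_step == (k - 1L)]
    state <- step_network(state, dt, params, touchdown_legs = legs)
    if (k %% record_every == 0L || k == n_steps) {
      ri <- ri + 1L
      rec[[ri]] <- snap(state)
    }
  }
  dplyr::bind_rows(rec[seq_len(ri)])
}
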