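#' Locate a wave-gait fixed point of the Poincare map
#'
#' Newton iteration on `P(psi) - psi` (torus-aware), initialized at the
#' closed-form fixed point unless `init` is given.  The direct wave gait
#' (swing propagating from hind to front legs) sits near
#' `psi1 = psi2 = 2*(1-beta)*pi`; the retrograde wave gait near `2*beta*pi`.
#'
#' @param gait `"direct"` or `"retrograde"`.
#' @param geom A [body_geometry()] object; `1/2 < beta < 2/3` is assumed by
#'   the initialization (other values are flagged).
#' @param init Optional numeric `c(psi1, psi2)` starting point.
#' @param tol Convergence tolerance on the map residual (rad).
#' @param max_iter Newton iteration cap.
#' @param jac_step Finite-difference step for the Newton Jacobian (rad).
#' @return An object of class `gait_fixed_point` with elements `psi1`,
#'   `psi2`, `phi_td` (common touchdown phase), `label`, `jacobian`
#'   (full-cycle map Jacobian), `eigenvalues` (sorted by modulus,
#'   decreasing), `residual` and `iterations`.  If Newton does not converge
#'   within `max_iter` the last iterate is returned with a warning.
#' @export
#' @examples
#' g <- body_geometry(beta = 0.55)
#' fp <- find_fixed_point("direct", g)
#' tidy(fp)
find_fixed_point <- function(gait = c("direct", "retrograde"), geom,
                             init = NULL, tol = 1e-10, max_iter = 50L,
                             jac_step = 1e-6) {
  gait <- match.arg(gait)
  warn_beta_range(geom$beta)
  psi <- if (is.null(init)) {
    analytic_fp_point(gait, geom)
  } else {
    wrap_phase(as.numeric(init))
  }
  res <- Inf
  iter <- 0L
  for (i in seq_len(max_iter)) {
    iter <- i
    G <- torus_diff(map_point(psi, geom), psi)
    res <- max(abs(G))
    if (res < tol) break
    J <- map_jacobian(psi, geom, jac_step)
    step <- solve(J - diag(2), G)
    psi <- wrap_phase(psi - step)
  }
  if (res >= tol) {
    warn(sprintf(
      "fixed-point iteration did not reach tol = %.1e in %d iterations (residual %.2e); returning last iterate",
      tol, max_iter, res
    ))
  }
  J <- map_jacobian(psi, geom, jac_step)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  # common touchdown phase from one converged cycle
  sim <- run_engine(section_state(psi[1], psi[2], geom), geom, 1L)
  structure(
    list(psi1 = psi[1], psi2 = psi[2],
         phi_td = sim$poincare$phi_td[nrow(sim$poincare)],
         label = gait, jacobian = J, eigenvalues = ev,
         residual = res, iterations = iter, geom = geom),
    class = "gait_fixed_point"
  )
}

# finite-difference Jacobian of the full-cycle map
map_jacobian <- function(psi, geom, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (k in 1:2) {
    e <- c(0, 0)
    e[k] <- h
    fp <- map_point(wrap_phase(psi + e), geom)
    fm <- map_point(wrap_phase(psi - e), geom)
    J[, k] <- torus_diff(fp, fm) / (2 * h)
  }
  J
}

#' Numerical Jacobian and stability multipliers of the Poincare map
#'
#' Central-difference Jacobian of the full-cycle map at a point (typically a
#' fixed point); its eigenvalue moduli are the gait's stability multipliers.
#'
#' @param fp A `gait_fixed_point` or numeric `c(psi1, psi2)`.
#' @param geom A [body_geometry()] object; taken from `fp` when omitted.
#' @param h Finite-difference step (rad).  Steps at or below the event
#'   tolerance (1e-10) are rejected: the derivative would be dominated by
#'   root-finder noise.
#' @return A list with `jacobian` (2 x 2) and `eigenvalues` (sorted by
#'   modulus, decreasing).
#' @export
numerical_jacobian <- function(fp, geom = NULL, h = 1e-6) {
  if (inherits(fp, "gait_fixed_point")) {
    psi <- c(fp$psi1, fp$psi2)
    geom <- geom %||% fp$geom
  } else {
    psi <- wrap_phase(as.numeric(fp))
  }
  if (is.null(geom)) abort("`geom` is required when `fp` is a bare point")
  if (h <= 1e-9) {
    warn("finite-difference step `h` is near the event tolerance; the Jacobian will be dominated by root-finder noise")
  }
  J <- map_jacobian(psi, geom, h)
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev[order(Mod(ev), decreasing = TRUE)])
}

#' @export
print.gait_fixed_point <- function(x, ...) {
  cat(sprintf("<gait_fixed_point> %s wave gait (beta = %.3g)\n",
              x$label, x$geom$beta))
  cat(sprintf("  psi1 = %.8f, psi2 = %.8f, phi_td = %.8f\n",
              x$psi1, x$psi2, x$phi_td))
  cat(sprintf("  |eigenvalues| = %.5f, %.5f; residual %.1e (%d iterations)\n",
              Mod(x$eigenvalues[1]), Mod(x$eigenvalues[2]),
              x$residual, x$iterations))
  invisible(x)
}

#' @export
tidy.gait_fixed_point <- function(x, ...) {
  tibble::tibble(
    gait = x$label,
    beta = x$geom$beta,
    psi1 = x$psi1,
    psi2 = x$psi2,
    phi_td = x$phi_td,
    lambda_1 = Mod(x$eigenvalues[1]),
    lambda_2 = Mod(x$eigenvalues[2])
  )
}

#' @export
glance.gait_fixed_point <- function(x, ...) {
  tibble::tibble(
    gait = x$label,
    lambda_max = Mod(x$eigenvalues[1]),
    stable = Mod(x$eigenvalues[1]) < 1,
    residual = x$residual,
    iterations = x$iterations
  )
}
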