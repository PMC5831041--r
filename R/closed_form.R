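#' Closed-form fixed points of the wave gaits
#'
#' First-order (in `1/(d_star * K_star)`) expressions for the relative
#' phases of the two stable gaits.  Both gaits sit within `O(1/K*)` of their
#' anchors: `psi1 = psi2 = 2*(1-beta)*pi` for the direct wave and
#' `2*beta*pi` for the retrograde wave.
#'
#' Two coefficient sets are available for the propulsive (`s_star`) terms.
#' `"published"` uses, for the direct gait,
#' \deqn{\psi_1 = 2(1-\beta)\pi - \frac{2(1-\beta)}{d^*K^*}
#'   + \frac{2}{5}\frac{1-\beta}{\beta}\frac{s^*/a^*}{d^*K^*},\qquad
#'   \psi_2 = 2(1-\beta)\pi - \frac{9(1-\beta)}{10\,d^*K^*}
#'   + \frac{(11\beta-30)(1-\beta)}{25}\frac{s^*/a^*}{d^*K^*},}
#' and the retrograde gait follows by the fore-aft mirror symmetry.
#' `"rederived"` replaces the `s_star` coefficients with the ones this
#' package derives from the quasi-static equilibrium equations themselves
#' (see the methods vignette): `(1-\beta)(45\beta-28)/(10\beta)` for
#' `psi1` and `(1-\beta)(75\beta-86)/(100\beta)` for `psi2`.  The two sets
#' agree exactly at `s_star = 0`; only the rederived set matches the
#' event-driven simulator to second order when `s_star != 0`.
#'
#' @param gait `"direct"` or `"retrograde"`.
#' @param beta Duty factor, ideally in `(1/2, 2/3)`.
#' @param d_star,K_star,s_star,a_star Body geometry (dimensionless); see
#'   [body_geometry()].
#' @param variant Coefficient set for the `s_star` terms.
#' @return A one-row tibble with columns `gait`, `psi1`, `psi2` (rad).
#' @export
#' @examples
#' analytic_fixed_point("direct", beta = 0.55, K_star = 50)
analytic_fixed_point <- function(gait = c("direct", "retrograde"), beta,
                                 d_star = 1, K_star = 50, s_star = 0.3,
                                 a_star = 1,
                                 variant = c("published", "rederived")) {
  gait <- match.arg(gait)
  variant <- match.arg(variant)
  dk <- d_star * K_star
  if (2 * (1 - beta) / dk > 0.2) {
    warn("first-order corrections exceed 0.2 rad; the expansion in 1/(d*K*) is unreliable here")
  }
  psi <- analytic_fp_values(gait, beta, dk, s_star / a_star, variant)
  tibble::tibble(gait = gait, psi1 = psi[1], psi2 = psi[2])
}

# Coefficient table for the first-order fixed-point expansions.
# Non-propulsive terms (shared by both variants):
#   2*(1-beta)        leading deficit of the same-side neighbour phase lag
#   (9/10)*(1-beta)   leading deficit of the second relative phase
# Propulsive (s*/a*) terms:
#   published:  +(2/5)*(1-beta)/beta           on psi1 (direct)
#               +(1/25)*(11*beta-30)*(1-beta)  on psi2 (direct)
#   rederived:  -(1-beta)*(45*beta-28)/(10*beta)   on psi1 (direct)
#               -(1-beta)*(75*beta-86)/(100*beta)  on psi2 (direct)
# The retrograde gait is the fore-aft mirror: swap the two deficit pairs
# and flip the sign of the anchors' offset.
fp_s_coef <- function(beta, variant) {
  if (variant == "published") {
    c(c1 = (2 / 5) * (1 - beta) / beta,
      c2 = (1 / 25) * (11 * beta - 30) * (1 - beta))
  } else {
    c(c1 = (1 - beta) * (45 * beta - 28) / (10 * beta),
      c2 = (1 - beta) * (75 * beta - 86) / (100 * beta))
  }
}

analytic_fp_values <- function(gait, beta, dk, soa, variant = "published") {
  t1 <- 2 * (1 - beta) / dk
  t3 <- (9 / 10) * (1 - beta) / dk
  cs <- fp_s_coef(beta, variant)
  t2 <- cs[["c1"]] * soa / dk
  t4 <- cs[["c2"]] * soa / dk
  if (gait == "direct") {
    c(2 * (1 - beta) * pi - t1 + t2, 2 * (1 - beta) * pi - t3 + t4)
  } else {
    c(2 * beta * pi + t3 + t4, 2 * beta * pi + t1 + t2)
  }
}

# numeric helper used as Newton initialization
analytic_fp_point <- function(gait, geom, variant = "published") {
  wrap_phase(analytic_fp_values(gait, geom$beta, geom$d_star * geom$K_star,
                                geom$s_star / geom$a_star, variant))
}

#' Half-cycle perturbation multipliers of the wave gaits
#'
#' Perturbation gains over the symmetric half gait cycle; the full-cycle
#' eigenvalues of the Poincare map are their squares.  For the direct wave
#' gait `m1 = 5/6 - (4/45)*beta*s*/a*` and `m2 = 13/18 + (4/81)*beta*s*/a*`;
#' the retrograde gait flips the signs of the propulsive terms.  At
#' `s_star = 0` both gaits share `lambda_max = (5/6)^2 = 25/36`.
#'
#' @inheritParams analytic_fixed_point
#' @param s_star,a_star Dimensionless stance line length and half body
#'   length.
#' @return Named numeric vector `c(m1, m2)`.
#' @export
#' @examples
#' halfcycle_multipliers("direct", beta = 0.5, s_star = 0.3)^2
halfcycle_multipliers <- function(gait = c("direct", "retrograde"), beta,
                                  s_star = 0, a_star = 1) {
  gait <- match.arg(gait)
  soa <- s_star / a_star
  sg <- if (gait == "direct") -1 else 1
  c(m1 = 5 / 6 + sg * (4 / 45) * beta * soa,
    m2 = 13 / 18 - sg * (4 / 81) * beta * soa)
}

#' Full-cycle evolution matrix of relative-phase perturbations
#'
#' The half-cycle map of perturbations `(dpsi1, dpsi2)` is lower triangular,
#' `M = [[m1, 0], [m2*(1-m1), m2]]`, built from the unsquared half-cycle
#' multipliers; a full gait cycle applies it twice.  The eigenvalues of the
#' returned matrix `M %*% M` are `(m1^2, m2^2)`.
#'
#' @inheritParams halfcycle_multipliers
#' @return A 2 x 2 matrix.
#' @export
evolution_matrix <- function(gait = c("direct", "retrograde"), beta,
                             s_star = 0, a_star = 1) {
  m <- halfcycle_multipliers(gait, beta, s_star, a_star)
  M <- matrix(c(m[["m1"]], m[["m2"]] * (1 - m[["m1"]]), 0, m[["m2"]]), 2, 2)
  M %*% M
}

#' Analytic summary of one wave gait
#'
#' Bundles the closed-form fixed point, half-cycle multipliers, full-cycle
#' eigenvalues and evolution matrix of one gait at one parameter setting.
#'
#' @inheritParams analytic_fixed_point
#' @return An object of class `analytic_gait`.
#' @export
#' @examples
#' tidy(analytic_gait("direct", beta = 0.55))
analytic_gait <- function(gait = c("direct", "retrograde"), beta, d_star = 1,
                          K_star = 50, s_star = 0.3, a_star = 1,
                          variant = c("published", "rederived")) {
  gait <- match.arg(gait)
  variant <- match.arg(variant)
  psi <- analytic_fp_values(gait, beta, d_star * K_star, s_star / a_star,
                            variant)
  m <- halfcycle_multipliers(gait, beta, s_star, a_star)
  structure(
    list(gait = gait, beta = beta, d_star = d_star, K_star = K_star,
         s_star = s_star, a_star = a_star, variant = variant,
         psi1 = psi[1], psi2 = psi[2],
         m1 = m[["m1"]], m2 = m[["m2"]],
         lambda1 = m[["m1"]]^2, lambda2 = m[["m2"]]^2,
         evolution_matrix = evolution_matrix(gait, beta, s_star, a_star)),
    class = "analytic_gait"
  )
}

#' @export
print.analytic_gait <- function(x, ...) {
  cat(sprintf("<analytic_gait> %s wave gait, beta = %.3g (%s coefficients)\n",
              x$gait, x$beta, x$variant))
  cat(sprintf("  psi1 = %.6f, psi2 = %.6f\n", x$psi1, x$psi2))
  cat(sprintf("  m = (%.5f, %.5f); lambda = (%.5f, %.5f)\n",
              x$m1, x$m2, x$lambda1, x$lambda2))
  invisible(x)
}

#' @export
tidy.analytic_gait <- function(x, ...) {
  tibble::tibble(
    gait = x$gait, beta = x$beta,
    psi1 = x$psi1, psi2 = x$psi2,
    m1 = x$m1, m2 = x$m2,
    lambda1 = x$lambda1, lambda2 = x$lambda2
  )
}

#' @export
glance.analytic_gait <- function(x, ...) {
  tibble::tibble(gait = x$gait, lambda_max = max(x$lambda1, x$lambda2),
                 stable = max(x$lambda1, x$lambda2) < 1)
}

#' Compare closed-form predictions with the event-driven simulator
#'
#' Sweeps duty factors (and optionally stiffnesses), finds both gaits'
#' numerical fixed points and stability multipliers, and tabulates them
#' against the closed forms.
#'
#' @param beta Duty factors to sweep.
#' @param K_star Stiffness values to sweep.
#' @param s_star,a_star,b_star,d_star Body geometry (scalars).
#' @param variant Coefficient set for the closed-form `s_star` terms.
#' @param jacobian Also compute numerical eigenvalues (slower).
#' @return A tibble with one row per (`beta`, `K_star`, `gait`):
#'   closed-form and numerical `psi1`, `psi2`, their discrepancies, and
#'   (with `jacobian = TRUE`) `lambda_max_analytic`, `lambda_max_numeric`.
#' @export
compare_with_numeric <- function(beta, K_star = 50, s_star = 0.3, a_star = 1,
                                 b_star = 1, d_star = 1,
                                 variant = c("published", "rederived"),
                                 jacobian = TRUE) {
  variant <- match.arg(variant)
  grid <- tidyr::expand_grid(beta = beta, K_star = K_star,
                             gait = c("direct", "retrograde"))
  rows <- purrr::pmap(grid, function(beta, K_star, gait) {
    geom <- body_geometry(beta = beta, K_star = K_star, a_star = a_star,
                          b_star = b_star, d_star = d_star, s_star = s_star)
    fp <- suppressWarnings(find_fixed_point(gait, geom))
    ana <- analytic_fp_values(gait, beta, d_star * K_star, s_star / a_star,
                              variant)
    m <- halfcycle_multipliers(gait, beta, s_star, a_star)
    out <- tibble::tibble(
      beta = beta, K_star = K_star, gait = gait,
      psi1_analytic = wrap_phase(ana[1]), psi2_analytic = wrap_phase(ana[2]),
      psi1_numeric = fp$psi1, psi2_numeric = fp$psi2,
      dpsi1 = torus_diff(fp$psi1, ana[1]),
      dpsi2 = torus_diff(fp$psi2, ana[2])
    )
    if (jacobian) {
      out$lambda_max_analytic <- m[["m1"]]^2
      out$lambda_max_numeric <- Mod(fp$eigenvalues[1])
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Sweep plot of relative phases and stability against duty factor
#'
#' @param comparison Output of [compare_with_numeric()].
#' @return A ggplot object: analytic curves and numerical points for
#'   `psi1`, `psi2` and (if present) the maximum eigenvalue, faceted by
#'   quantity.
#' @export
plot_gait_sweep <- function(comparison) {
  long <- comparison |>
    tidyr::pivot_longer(
      dplyr::any_of(c("psi1_analytic", "psi2_analytic", "psi1_numeric",
                      "psi2_numeric", "lambda_max_analytic",
                      "lambda_max_numeric")),
      names_to = c("quantity", "source"),
      names_pattern = "(.*)_(analytic|numeric)",
      values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta, y = .data$value,
                                     colour = .data$gait,
                                     linetype = .data$source)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$source == "analytic")) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$source == "numeric")) +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y") +
    ggplot2::labs(x = expression(beta), y = NULL) +
    ggplot2::theme_minimal()
}
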