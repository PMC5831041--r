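# Independent brute-force oracle for the quasi-static equilibrium: assembles
# the force/moment residuals directly from the per-leg rows and solves them
# by dense least squares, without the package's structured 3x3 assembly.
oracle_equilibrium <- function(phi, stance_set, geom) {
  eff <- (c(phi, phi + pi)) %% (2 * pi)
  beta <- geom$beta
  bp2 <- 2 * beta * pi
  st <- eff < bp2
  u <- (eff - bp2) / (2 * (1 - beta))
  L <- ifelse(st, 1, 1 - geom$d_star * sin(u))
  dx <- ifelse(st, geom$s_star * (0.5 - eff / bp2),
               geom$s_star * (-0.5 + u / pi))
  xi <- c(1, 0, -1, 1, 0, -1) * geom$a_star
  yy <- c(-1, -1, -1, 1, 1, 1) * geom$b_star
  x <- xi + dx
  K <- geom$K_star
  S <- stance_set
  # unknown v = (pitch, roll, height); compression row: dl_i = pitch*x_i -
  # roll*y_i + L_i - height.  Residuals: sum(K dl) = 1; sum(K dl x) = pitch;
  # sum(K dl y) = -roll (moment arms with the small-angle rotation and unit
  # leg length).
  resid <- function(v) {
    dl <- v[1] * x[S] - v[2] * yy[S] + L[S] - v[3]
    c(K * sum(dl) - 1,
      K * sum(dl * x[S]) - v[1],
      K * sum(dl * yy[S]) + v[2])
  }
  sol <- pracma::fsolve(resid, c(0, 0, 1 - 1 / (2 * K)), tol = 1e-14)
  v <- as.numeric(sol$x)
  dl_all <- v[1] * x - v[2] * yy + L - v[3]
  list(pitch = v[1], roll = v[2], height = v[3], compressions = dl_all)
}

# random non-degenerate stance sets (>= 3 legs, non-collinear feet)
random_stance_set <- function() {
  repeat {
    n <- sample(3:6, 1)
    S <- sort(sample(1:6, n))
    # quick collinearity screen on the nominal foot positions
    xi <- c(1, 0, -1, 1, 0, -1)[S]
    yy <- c(-1, -1, -1, 1, 1, 1)[S]
    if (length(unique(yy)) > 1 || length(unique(xi)) > 1) {
      if (qr(cbind(xi - mean(xi), yy - mean(yy)))$rank == 2) return(S)
    }
  }
}

default_geom <- function(beta = 0.55, ...) {
  suppressWarnings(body_geometry(beta = beta, ...))
}

expect_torus_equal <- function(a, b, tol) {
  d <- abs(((a - b + pi) %% (2 * pi)) - pi)
  expect_lt(max(d), tol)
}
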