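test_that("converged direct gait touches down in the wave order 2,6,1,5,3,4", {
  for (beta in c(0.55, 0.6)) {
    g <- default_geom(beta = beta)
    fp <- find_fixed_point("direct", g)
    sim <- simulate_gait(fp$psi1, fp$psi2, g, n_cycles = 4)
    td <- sim$events$leg[sim$events$type == "touchdown"]
    ref <- c(2L, 6L, 1L, 5L, 3L, 4L)
    last12 <- tail(td, 12)
    r <- match(last12[1], ref)
    expected <- ref[((seq_len(12) - 1 + r - 1) %% 6) + 1]
    expect_equal(last12, expected)
  }
})

test_that("phase resetting maps the touchdown phase to pi + phi_td/2", {
  g <- default_geom(beta = 0.55)
  sim <- simulate_gait(2.8, 2.8, g, n_cycles = 2)
  td2 <- which(sim$events$leg == 2 & sim$events$type == "touchdown")
  phtd <- sim$events$phi_td[td2[1]]
  expect_equal(sim$events$reset[td2[1]], (2 * pi - phtd) / 2,
               tolerance = 1e-12)
})

test_that("the gait stays on the section when started at the analytic fixed point", {
  # stiff limit: the first-order fixed point is second-order accurate, so
  # Poincare samples stay put to well below 1e-6 rad over 10 cycles
  g <- default_geom(beta = 0.55, K_star = 5000, s_star = 0)
  ana <- analytic_fixed_point("direct", beta = 0.55, K_star = 5000, s_star = 0)
  sim <- simulate_gait(ana$psi1, ana$psi2, g, n_cycles = 10)
  expect_torus_equal(sim$poincare$psi1, ana$psi1, 1e-6)
  expect_torus_equal(sim$poincare$psi2, ana$psi2, 1e-6)
})

test_that("the half-cycle map composed twice equals the full-cycle map", {
  # the identity is exact on the gait branch, where the section state is
  # fully determined by the relative phases; far from the attractors the
  # contact configuration carries memory that (psi1, psi2) cannot encode
  g <- default_geom(beta = 0.55)
  fps <- list(find_fixed_point("direct", g), find_fixed_point("retrograde", g))
  starts <- list(c(fps[[1]]$psi1, fps[[1]]$psi2),
                 c(fps[[1]]$psi1 + 0.02, fps[[1]]$psi2 - 0.02),
                 c(fps[[2]]$psi1 - 0.02, fps[[2]]$psi2 + 0.02))
  for (start in starts) {
    h2 <- poincare_map(start[1], start[2], g, iterations = 2, half = TRUE)
    f1 <- poincare_map(start[1], start[2], g, iterations = 1)
    expect_torus_equal(h2$psi1[3], f1$psi1[2], 1e-10)
    expect_torus_equal(h2$psi2[3], f1$psi2[2], 1e-10)
  }
})

test_that("map displacement vanishes at the numerical fixed point", {
  g <- default_geom(beta = 0.55)
  fp <- find_fixed_point("direct", g)
  m <- poincare_map(fp$psi1, fp$psi2, g)
  expect_torus_equal(m$psi1[2], fp$psi1, 1e-8)
  expect_torus_equal(m$psi2[2], fp$psi2, 1e-8)
})

test_that("successive displacements contract at the rate of the top multiplier", {
  g <- default_geom(beta = 0.55, K_star = 500)
  fp <- find_fixed_point("direct", g)
  sim <- simulate_gait(fp$psi1 + 3e-4, fp$psi2 + 1.5e-4, g, n_cycles = 15)
  d <- sqrt(((sim$poincare$psi1 - fp$psi1)^2 +
             (sim$poincare$psi2 - fp$psi2)^2))
  ratios <- tail(d, -1) / head(d, -1)
  expect_equal(tail(ratios, 1), Mod(fp$eigenvalues[1]), tolerance = 0.05)
})

test_that("fore-aft symmetry maps the direct gait onto the retrograde gait", {
  g <- default_geom(beta = 0.55, s_star = 0.3)
  gm <- default_geom(beta = 0.55, s_star = -0.3)
  set.seed(2)
  for (rep in 1:3) {
    psi <- c(2 * (1 - 0.55) * pi, 2 * (1 - 0.55) * pi) + runif(2, -0.25, 0.25)
    q <- poincare_map(psi[1], psi[2], g)
    m <- poincare_map(2 * pi - psi[2], 2 * pi - psi[1], gm)
    expect_torus_equal(q$psi1[2], 2 * pi - m$psi2[2], 1e-10)
    expect_torus_equal(q$psi2[2], 2 * pi - m$psi1[2], 1e-10)
  }
})

test_that("unreachable relative phases raise a section error", {
  g <- default_geom(beta = 0.55)
  # all-in-phase oscillators leave no solvable leg-2 touchdown state
  expect_error(simulate_gait(0, 0, g, n_cycles = 1), class = "hexagait_section_error")
})
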