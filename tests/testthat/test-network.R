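test_that("contralateral coupling vanishes at antiphase and is antisymmetric", {
  phi <- c(0.3, 1.1, 2.7, 0.3 + pi, 1.1 + pi, 2.7 + pi)
  expect_equal(contralateral_coupling(phi, 10), rep(0, 6), tolerance = 1e-12)

  phi2 <- c(0, 0, 0, pi / 2, 0, 0)
  g <- contralateral_coupling(phi2, 10)
  expect_equal(g[1], -10 * sin(-3 * pi / 2), tolerance = 1e-12) # = -10
  expect_equal(g[1], -10)
  expect_equal(g[4], 10, tolerance = 1e-12)
  expect_equal(g[1], -g[4], tolerance = 1e-12)
})

test_that("phase resetting ignores stance contact and advances swing contact", {
  beta <- 0.5
  expect_equal(phase_reset_feedback(2 * pi - 0.1, beta), 0.1, tolerance = 1e-12)
  expect_equal(phase_reset_feedback(0.5 * beta * pi, beta), 0)
  # the branch boundary belongs to the swing branch
  expect_equal(phase_reset_feedback(2 * beta * pi, beta),
               2 * pi - 2 * beta * pi, tolerance = 1e-12)
})

test_that("free network rotates rigidly at omega", {
  p <- gait_params(beta = 0.55, T_sw = 10)
  omega <- derived_timing(p)$omega
  phi0 <- c(0.5, 1.5, 2.5, 0.5 + pi, 1.5 + pi, 2.5 + pi)
  st <- network_state(phi0)
  for (k in 1:100) st <- step_network(st, 1e-2, p)
  expect_equal(st$phi, wrap_phase(phi0 + omega * 1), tolerance = 1e-9)
  expect_equal(st$y, rep(0, 6))
})

test_that("antiphase deviation decays monotonically from random phases", {
  set.seed(42)
  p <- gait_params(beta = 0.55, T_sw = 10, k_c = 10)
  phi0 <- runif(6, 0, 2 * pi)
  # avoid the measure-zero unstable in-phase configuration
  st <- network_state(phi0)
  dev <- function(s) max(abs(((s$phi[4:6] - s$phi[1:3]) %% (2 * pi)) - pi))
  devs <- numeric(101)
  devs[1] <- dev(st)
  for (k in 1:100) {
    for (j in 1:100) st <- step_network(st, 1e-3, p)
    devs[k + 1] <- dev(st)
  }
  expect_lt(devs[101], 1e-3)             # < 1e-3 rad within 10 s
  expect_true(all(diff(devs) <= 1e-10))  # monotone decay
})

test_that("one reset impulse adds exactly its amount of phase through the lag", {
  # k_c = 0 isolates the impulse response of a single oscillator
  p <- gait_params(beta = 0.5, T_sw = 10, k_c = 0, tau = 0.5)
  omega <- derived_timing(p)$omega
  dt <- 1e-4
  A <- phase_reset_feedback(2 * pi - 0.35, p$beta)  # reset amount 0.35
  st <- network_state(rep(2 * pi - 0.35, 6))
  st <- step_network(st, dt, p, touchdown_legs = 1L)
  # instantaneous jump y <- y + A / tau
  expect_equal(st$y[1], A / p$tau, tolerance = 1e-3 * A / p$tau)
  y0 <- st$y[1]
  # exponential decay of the lag state
  for (k in 1:5000) st <- step_network(st, dt, p)
  expect_equal(st$y[1], y0 * exp(-0.5 / p$tau), tolerance = 1e-6)
  # integrate long enough that the residual tail is < 1e-7 * A
  n_more <- (8 - 0.5) / dt
  for (k in seq_len(n_more)) st <- step_network(st, dt, p)
  extra <- ((st$phi[1] - (2 * pi - 0.35) - omega * st$t) %% (2 * pi))
  expect_equal(extra, A, tolerance = 1e-6 * A)
})

test_that("tau = 0 applies the reset as a direct phase jump", {
  p <- gait_params(beta = 0.5, tau = 0, k_c = 0)
  st <- network_state(rep(2 * pi - 0.2, 6))
  st <- step_network(st, 1e-3, p, touchdown_legs = 2L)
  # phase reset to zero, then advanced by one step of flow
  expect_lt(abs(st$phi[2] - derived_timing(p)$omega * 1e-3), 1e-6)
  expect_equal(st$y, rep(0, 6))
})

test_that("simulate_network exports the trajectory table", {
  p <- gait_params(beta = 0.5, T_sw = 1)
  out <- simulate_network(p, phi0 = c(1:3, 1:3 + pi), duration = 0.05,
                          dt = 1e-3, record_every = 10,
                          touchdowns = data.frame(t = 0.02, leg = 2))
  expect_named(out, c("t", "leg", "phi", "y", "dx", "height", "contact"))
  expect_true(all(out$leg %in% 1:6))
  expect_true(any(out$contact[out$leg == 2]))
})
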