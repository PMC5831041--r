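test_that("classification anchors and the far-from-both case", {
  beta <- 0.6
  a_d <- 2 * (1 - beta) * pi
  a_r <- 2 * beta * pi
  expect_equal(classify_gait(a_d, a_d, beta), "direct")
  expect_equal(classify_gait(a_r, a_r, beta), "retrograde")
  expect_equal(classify_gait(pi / 4, 7 * pi / 4, beta, tol = 0.5), "other")
  # vectorized
  expect_equal(classify_gait(c(a_d, a_r), c(a_d, a_r), beta),
               c("direct", "retrograde"))
})

test_that("the tripod degeneracy at beta = 1/2 is resolved by touchdown order", {
  g <- suppressWarnings(default_geom(beta = 0.5))
  ana <- analytic_fixed_point("direct", beta = 0.5, variant = "rederived")
  sim <- suppressWarnings(simulate_gait(ana$psi1, ana$psi2, g, n_cycles = 25))
  n <- nrow(sim$poincare)
  lab <- classify_gait(sim$poincare$psi1[n], sim$poincare$psi2[n], beta = 0.5,
                       events = sim$events)
  expect_equal(lab, "direct")
  expect_warning(classify_gait(pi, pi, beta = 0.5), "coincide")
})

test_that("fixed points keep their labels under map iteration", {
  g <- default_geom(beta = 0.55)
  fps <- list(find_fixed_point("direct", g), find_fixed_point("retrograde", g))
  pts <- tibble::tibble(psi1 = c(fps[[1]]$psi1, fps[[2]]$psi1),
                        psi2 = c(fps[[1]]$psi2, fps[[2]]$psi2))
  b <- basin_scan(g, n_steps = 30, fixed_points = fps, points = pts)
  expect_equal(b$points$label, c("direct", "retrograde"))
  expect_true(all(b$points$converged))
  expect_true(all(b$points$n_steps_to_converge <= 3))
})

test_that("a coarse basin scan finds both attractors with larger direct share", {
  # run to convergence: the map creeps at O(1/K*) per cycle far from the
  # attractors, so short scans measure convergence speed, not basin size
  g <- default_geom(beta = 0.6)
  b <- basin_scan(g, n_grid = 8, n_steps = 800)
  gl <- glance(b)
  expect_equal(sort(b$counts$label), c("direct", "retrograde"))
  expect_gt(gl$n_direct, gl$n_retrograde)
  expect_equal(gl$n_invalid, 0)
})
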