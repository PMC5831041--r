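test_that("fixed points approach the gait anchors as stiffness grows", {
  for (beta in c(0.52, 0.6)) {
    fd <- analytic_fixed_point("direct", beta = beta, K_star = 1e9, s_star = 0.3)
    expect_equal(fd$psi1, 2 * (1 - beta) * pi, tolerance = 1e-6)
    expect_equal(fd$psi2, 2 * (1 - beta) * pi, tolerance = 1e-6)
    fr <- analytic_fixed_point("retrograde", beta = beta, K_star = 1e9,
                               s_star = 0.3)
    expect_equal(fr$psi1, 2 * beta * pi, tolerance = 1e-6)
    expect_equal(fr$psi2, 2 * beta * pi, tolerance = 1e-6)
  }
})

test_that("published first-order values match hand-computed cases", {
  # beta = 1/2, d*K* = 50, s* = 0: (pi - 0.02, pi - 0.009)
  a0 <- analytic_fixed_point("direct", beta = 0.5, K_star = 50, s_star = 0)
  expect_equal(a0$psi1, pi - 0.02, tolerance = 1e-12)
  expect_equal(a0$psi2, pi - 0.009, tolerance = 1e-12)
  # beta = 1/2, d*K* = 50, s*/a* = 0.3: psi1 = pi - 0.02 + 0.0024
  a1 <- analytic_fixed_point("direct", beta = 0.5, K_star = 50, s_star = 0.3)
  expect_equal(a1$psi1, pi - 0.02 + 0.0024, tolerance = 1e-12)
  expect_equal(round(a1$psi1, 4), 3.1240)
})

test_that("the published pair respects the fore-aft mirror symmetry", {
  for (variant in c("published", "rederived")) {
    d <- analytic_fixed_point("direct", beta = 0.57, K_star = 80,
                              s_star = -0.2, variant = variant)
    r <- analytic_fixed_point("retrograde", beta = 0.57, K_star = 80,
                              s_star = 0.2, variant = variant)
    expect_equal(r$psi1, 2 * pi - d$psi2, tolerance = 1e-12)
    expect_equal(r$psi2, 2 * pi - d$psi1, tolerance = 1e-12)
  }
})

test_that("half-cycle multipliers give the printed stability values", {
  m0 <- halfcycle_multipliers("direct", beta = 0.5, s_star = 0)
  expect_equal(m0[["m1"]], 5 / 6)
  expect_equal(m0[["m1"]]^2, 25 / 36)
  mr0 <- halfcycle_multipliers("retrograde", beta = 0.5, s_star = 0)
  expect_equal(mr0, m0)  # equal stability at s* = 0

  md <- halfcycle_multipliers("direct", beta = 0.5, s_star = 0.3)
  expect_equal(md[["m1"]]^2, 0.6724, tolerance = 1e-10)
  mr <- halfcycle_multipliers("retrograde", beta = 0.5, s_star = 0.3)
  expect_equal(mr[["m1"]]^2, 0.7168, tolerance = 1e-3)
  expect_gt(mr[["m1"]]^2, md[["m1"]]^2)  # direct wave more stable
})

test_that("the evolution matrix squares the half-cycle structure", {
  for (beta in c(0.5, 0.6)) for (s in c(0, 0.3)) {
    m <- halfcycle_multipliers("direct", beta, s_star = s)
    M2 <- evolution_matrix("direct", beta, s_star = s)
    ev <- sort(eigen(M2, only.values = TRUE)$values)
    expect_equal(ev, sort(c(m[["m1"]]^2, m[["m2"]]^2)), tolerance = 1e-12)
    expect_equal(det(M2), (m[["m1"]] * m[["m2"]])^2, tolerance = 1e-12)
    expect_equal(M2[1, 2], 0)
    # lower-left entry of the symbolic square
    expect_equal(M2[2, 1], m[["m2"]] * (1 - m[["m1"]]) * (m[["m1"]] + m[["m2"]]),
                 tolerance = 1e-12)
  }
  s0 <- evolution_matrix("direct", 0.55, s_star = 0)
  expect_equal(s0[1, 1], 25 / 36, tolerance = 1e-12)
  expect_equal(s0[2, 2], (13 / 18)^2, tolerance = 1e-12)
})

test_that("anchors change monotonically and the stability gap is linear in s*", {
  betas <- seq(0.51, 0.66, by = 0.01)
  dir_anchor <- 2 * (1 - betas) * pi
  ret_anchor <- 2 * betas * pi
  expect_true(all(diff(dir_anchor) < 0))
  expect_true(all(diff(ret_anchor) > 0))

  gap <- function(s) {
    halfcycle_multipliers("retrograde", 0.55, s)[["m1"]]^2 -
      halfcycle_multipliers("direct", 0.55, s)[["m1"]]^2
  }
  expect_equal(gap(0.3), 2 * gap(0.15), tolerance = 1e-12)
  expect_equal(gap(0), 0)
})

test_that("closed forms agree with the simulator at their stated order", {
  # at s* = 0 the published expansion is second-order accurate: at
  # d*K* = 200 the fixed-point discrepancy is far below 1e-3 rad
  cmp <- compare_with_numeric(beta = c(0.55, 0.6), K_star = 200, s_star = 0,
                              jacobian = TRUE)
  expect_lt(max(abs(c(cmp$dpsi1, cmp$dpsi2))), 1e-3)
  expect_lt(max(abs(cmp$lambda_max_numeric - cmp$lambda_max_analytic) /
                  cmp$lambda_max_analytic), 0.02)

  # with propulsion the package's rederived coefficients track the simulator
  # to the linear-in-s* truncation (the residual is the model's genuine
  # quadratic s* remainder, which scales as 1/K*)
  cmp_r <- compare_with_numeric(beta = 0.55, K_star = c(100, 200), s_star = 0.3,
                                variant = "rederived", jacobian = FALSE)
  cmp_p <- compare_with_numeric(beta = 0.55, K_star = 200, s_star = 0.3,
                                variant = "published", jacobian = FALSE)
  d100 <- max(abs(c(cmp_r$dpsi1[cmp_r$K_star == 100],
                    cmp_r$dpsi2[cmp_r$K_star == 100])))
  d200 <- max(abs(c(cmp_r$dpsi1[cmp_r$K_star == 200],
                    cmp_r$dpsi2[cmp_r$K_star == 200])))
  d200_pub <- max(abs(c(cmp_p$dpsi1, cmp_p$dpsi2)))
  expect_lt(d200, 2e-4)
  expect_equal(d100 / d200, 2, tolerance = 0.15)  # first-order remainder
  expect_lt(d200, d200_pub / 3)  # and well inside the published residual
})

test_that("the two s* coefficient variants differ only in the propulsive terms", {
  p0 <- analytic_fixed_point("direct", beta = 0.55, s_star = 0,
                             variant = "published")
  r0 <- analytic_fixed_point("direct", beta = 0.55, s_star = 0,
                             variant = "rederived")
  expect_equal(p0$psi1, r0$psi1)
  expect_equal(p0$psi2, r0$psi2)
  p1 <- analytic_fixed_point("direct", beta = 0.55, s_star = 0.3,
                             variant = "published")
  r1 <- analytic_fixed_point("direct", beta = 0.55, s_star = 0.3,
                             variant = "rederived")
  expect_false(isTRUE(all.equal(p1$psi1, r1$psi1)))
})
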