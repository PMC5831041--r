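test_that("symmetric six-leg and tripod stances match closed-form statics", {
  g <- default_geom(beta = 0.55, s_star = 0)
  K <- g$K_star

  eq6 <- solve_equilibrium(c(0, 0, 0), 1:6, g)
  expect_equal(eq6$pitch, 0, tolerance = 1e-12)
  expect_equal(eq6$roll, 0, tolerance = 1e-12)
  expect_equal(eq6$height, 1 - 1 / (6 * K), tolerance = 1e-12)
  expect_equal(eq6$compressions, rep(1 / (6 * K), 6), tolerance = 1e-12)

  # tripod {1,3,5}: outer legs carry half the load of the middle leg
  eq3 <- solve_equilibrium(c(0, 0, 0), c(1, 3, 5), g)
  expect_equal(eq3$compressions[1], eq3$compressions[3], tolerance = 1e-14)
  # load split 1:1:2 up to O(1/K*) corrections of the linearized moments
  expect_lt(abs(eq3$compressions[5] - 2 * eq3$compressions[1]), 2 / K^2)
  expect_lt(abs(eq3$compressions[1] - 1 / (4 * K)), 1 / K^2)
  expect_lt(abs(eq3$compressions[5] - 1 / (2 * K)), 2 / K^2)
})

test_that("every returned solution balances forces and moments", {
  set.seed(7)
  for (rep in 1:25) {
    g <- default_geom(beta = runif(1, 0.51, 0.66), s_star = runif(1, 0, 0.3),
                      K_star = runif(1, 30, 300))
    phi <- runif(3, 0, 2 * pi)
    S <- random_stance_set()
    eq <- tryCatch(solve_equilibrium(phi, S, g), error = function(e) NULL)
    if (is.null(eq)) next
    kin <- spring_kinematics(wrap_phase(c(phi, phi + pi)), g)
    x <- c(1, 0, -1, 1, 0, -1) * g$a_star + kin$dx_star
    y <- c(-1, -1, -1, 1, 1, 1) * g$b_star
    dl <- eq$compressions[S]
    K <- g$K_star
    expect_equal(K * sum(dl), 1, tolerance = 1e-12)               # force
    expect_lt(abs(K * sum(dl * x[S]) - eq$pitch), 1e-12)          # pitch
    expect_lt(abs(K * sum(dl * y[S]) + eq$roll), 1e-12)           # roll
  }
})

test_that("structured solve agrees with a dense least-squares oracle", {
  skip_if_not_installed("pracma")
  set.seed(11)
  n_ok <- 0
  for (rep in 1:200) {
    g <- default_geom(beta = runif(1, 0.45, 0.7), s_star = runif(1, -0.3, 0.3),
                      K_star = runif(1, 20, 500))
    phi <- runif(3, 0, 2 * pi)
    S <- random_stance_set()
    eq <- tryCatch(solve_equilibrium(phi, S, g), error = function(e) NULL)
    if (is.null(eq)) next
    orc <- oracle_equilibrium(phi, S, g)
    expect_lt(abs(eq$pitch - orc$pitch), 1e-10)
    expect_lt(abs(eq$roll - orc$roll), 1e-10)
    expect_lt(abs(eq$height - orc$height), 1e-10)
    expect_lt(max(abs(eq$compressions - orc$compressions)), 1e-9)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 150)
})

test_that("left-right mirror negates roll and preserves pitch and height", {
  set.seed(3)
  for (rep in 1:10) {
    g <- default_geom(beta = 0.55, s_star = 0.3)
    phi <- runif(3, 0, 2 * pi)
    S <- random_stance_set()
    eq <- tryCatch(solve_equilibrium(phi, S, g), error = function(e) NULL)
    if (is.null(eq)) next
    S_m <- sort(ifelse(S > 3, S - 3, S + 3))
    eq_m <- solve_equilibrium(wrap_phase(phi + pi), S_m, g)
    expect_equal(eq_m$roll, -eq$roll, tolerance = 1e-12)
    expect_equal(eq_m$pitch, eq$pitch, tolerance = 1e-12)
    expect_equal(eq_m$height, eq$height, tolerance = 1e-12)
  }
})

test_that("fore-aft mirror with s* -> -s* negates pitch", {
  set.seed(5)
  g <- default_geom(beta = 0.55, s_star = 0.3)
  gm <- default_geom(beta = 0.55, s_star = -0.3)
  for (rep in 1:10) {
    phi <- runif(3, 0, 2 * pi)
    S <- random_stance_set()
    eq <- tryCatch(solve_equilibrium(phi, S, g), error = function(e) NULL)
    if (is.null(eq)) next
    # swap legs 1<->3 and 4<->6: the reduced phases reverse order
    swap <- c(3L, 2L, 1L, 6L, 5L, 4L)
    eq_m <- solve_equilibrium(phi[c(3, 2, 1)], sort(swap[S]), gm)
    expect_equal(eq_m$pitch, -eq$pitch, tolerance = 1e-12)
    expect_equal(eq_m$roll, eq$roll, tolerance = 1e-12)
    expect_equal(eq_m$height, eq$height, tolerance = 1e-12)
  }
})

test_that("posture deviations scale as 1/K*", {
  g1 <- default_geom(beta = 0.55, s_star = 0.2, K_star = 80)
  g2 <- default_geom(beta = 0.55, s_star = 0.2, K_star = 160)
  # phases chosen so every stance leg is on the stance branch (L* = 1);
  # swing-branch neutral-length changes are O(1), not O(1/K*)
  phi <- c(0.3, 0.2, 1.0)
  S <- c(1, 3, 4, 5)
  e1 <- solve_equilibrium(phi, S, g1)
  e2 <- solve_equilibrium(phi, S, g2)
  expect_equal(e2$pitch / e1$pitch, 0.5, tolerance = 0.01)
  expect_equal(e2$roll / e1$roll, 0.5, tolerance = 0.01)
  expect_equal((1 - e2$height) / (1 - e1$height), 0.5, tolerance = 0.01)
})

test_that("singular stance configurations are rejected by name", {
  g <- default_geom(beta = 0.55)
  expect_error(solve_equilibrium(c(0, 0, 0), c(1, 2), g), "singular")
  # legs 4,5,6 share one body edge: collinear feet
  expect_error(solve_equilibrium(c(0, 0, 0), c(4, 5, 6), g),
               "singular.*4,5,6")
})

test_that("hypothetical compression is consistent with the stance solution", {
  g <- default_geom(beta = 0.55, s_star = 0.2)
  phi <- c(0.4, 1.2, 2.2)
  eq <- solve_equilibrium(phi, c(1, 2, 4, 5), g)
  for (leg in c(1, 2, 4, 5)) {
    expect_equal(hypothetical_compression(phi, leg, eq, g),
                 eq$compressions[leg], tolerance = 1e-12)
  }
  # flat symmetric stance, one leg mid-swing: gap = -d* + 1/(6K*)
  g0 <- default_geom(beta = 0.55, s_star = 0)
  eq6 <- solve_equilibrium(c(0, 0, 0), 1:6, g0)
  mid_swing <- (1 + g0$beta) * pi
  gap <- g0$a_star * 0 + 0 + (1 - g0$d_star) - eq6$height
  expect_equal(gap, -g0$d_star + 1 / (6 * g0$K_star), tolerance = 1e-12)
  expect_lt(gap, 0)
})

test_that("resolve_stance_set sheds legs the ground cannot hold", {
  g <- default_geom(beta = 0.55, s_star = 0)
  # flag a mid-swing leg as contact: its compression is strongly negative
  phi <- c(0, (1 + g$beta) * pi, 0)
  res <- resolve_stance_set(phi, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), g)
  expect_false(2 %in% res$stance_set)
  expect_true(all(res$solution$compressions[res$stance_set] >= -1e-12))
  # a consistent set is returned unchanged
  res2 <- resolve_stance_set(c(0, 0, 0), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                           FALSE), g)
  expect_equal(res2$stance_set, c(1, 3, 5))
})
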