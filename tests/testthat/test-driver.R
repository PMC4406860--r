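test_that("initial state matches the prescribed weak-attachment seed", {
  p <- best()
  np <- solver_coefficients(p)
  g <- tiny_grid()
  st <- initialize_state(np, g)
  expect_equal(st$xi_b[1], 0.01)
  expect_equal(st$xi_b[g$s >= 0.2], rep(0, sum(g$s >= 0.2)))
  inside <- g$s < 0.2
  expect_equal(st$xi_b[inside], 0.01 * (1 - 5 * g$s[inside]))
  expect_equal(st$Z0, 1 + np$lambda)
  expect_equal(internalization_metrics(st)$d_over_2a, 0)
  expect_equal(st$Ttens, rep(np$T0, g$n))
})

test_that("time step grows geometrically to the cap when bonds are frozen", {
  p <- best()
  np <- solver_coefficients(p)
  g <- tiny_grid()
  st <- initialize_state(np, g)
  # put every node at its local equilibrium: zero predicted change
  l <- npwrap:::state_gap(st)
  st$xi_b <- npwrap:::riccati_roots(1, np$xi_r, np$Kf,
                                    npwrap:::kd_hat(l, np))$minus
  dt <- 1e-6
  for (i in 1:25) dt <- choose_time_step(st, np, dt)
  expect_equal(dt, 0.05)
})

test_that("early time steps are small (order 1e-6 time units)", {
  p <- best()
  np <- solver_coefficients(p)
  g <- tiny_grid()
  st <- initialize_state(np, g)
  dt <- choose_time_step(st, np, dt_prev = 0.05)
  expect_lt(dt, 5e-5)
  expect_gt(dt, 1e-8)
})

test_that("frozen kinetics leave the weakly attached state near rest", {
  p <- best(a = 50e-9)
  np <- solver_coefficients(p)
  np$Kf <- 0; np$Kd0 <- 0 # kinetics switched off; seed bonds frozen
  g <- build_grid(NULL, s_max_factor = 10, ds0 = 0.1)
  st <- initialize_state(np, g)
  st2 <- step(st, np, g, dt = 0.01)
  expect_equal(st2$time, 0.01)
  expect_equal(st2$xi_b, st$xi_b)
  # the weak seed ring barely deforms anything
  expect_lt(max(abs(st2$theta)), 0.1)
  expect_lt(abs(st2$Z0 - st$Z0), 0.1)
})

test_that("operator splitting is first order in the step size", {
  p <- best(a = 50e-9)
  np <- solver_coefficients(p)
  g <- build_grid(NULL, s_max_factor = 10, ds0 = 0.1)
  st <- initialize_state(np, g)
  # advance into the dynamic regime first
  for (i in 1:5) st <- step(st, np, g)
  dt <- 4e-5
  d0 <- internalization_metrics(st)$d_over_2a
  full <- step(st, np, g, dt = dt)
  half <- step(step(st, np, g, dt = dt / 2), np, g, dt = dt / 2)
  d_full <- internalization_metrics(full)$d_over_2a
  d_half <- internalization_metrics(half)$d_over_2a
  # halving the step shifts the result by a fraction of the per-step
  # advance (first-order splitting), not by its own magnitude
  advance <- abs(d_half - d0)
  expect_gt(advance, 0)
  expect_lt(abs(d_full - d_half), 0.25 * advance)
})

test_that("run driver reports convergence and metrics coherently", {
  p <- best(a = 50e-9)
  # near-inert binding with fast dissociation: the seed ring dies away
  # and the particle detaches (depth drifts to zero or below)
  p <- best(a = 50e-9, K_f = 1e-22, Kd0_over_Kf = 5e21)
  g <- build_grid(NULL, s_max_factor = 10, ds0 = 0.1)
  r <- run_simulation(p, grid = g, t_max = 25)
  expect_true(r$converged)
  expect_lte(r$final$time, 25.1)
  expect_lt(r$max_depth, 0.1)
  expect_true(is.na(r$internalization_time))
  expect_false(r$reached_internalization)
  expect_true(all(diff(r$trajectory$time) > 0))
  expect_named(r$trajectory,
               c("time", "dt", "Z0", "d_over_2a", "wrap_angle",
                 "total_bonds", "max_xi_b"))
})

test_that("depth metric is tied to the wrapping geometry", {
  p <- best()
  np <- solver_coefficients(p)
  g <- tiny_grid()
  st <- initialize_state(np, g)
  # equatorial wrapping: Z0 = 0 gives d = a
  st$Z0 <- 0
  expect_equal(internalization_metrics(st)$d_over_2a, 0.5)
  # full engulfment: center one contact radius below the plane
  st$Z0 <- -(1 + np$lambda)
  expect_equal(internalization_metrics(st)$d_over_2a, 1)
})
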