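test_that("flat membrane is a machine-precision root under zero stress", {
  p <- best()
  np <- solver_coefficients(p)
  g <- tiny_grid()
  n <- g$n
  zero <- function(R, Z, theta) list(sigma_r = numeric(length(R)),
                                     sigma_v = numeric(length(R)))
  sol <- solve_shape(list(theta = numeric(n), Ttens = rep(np$T0, n)),
                     zero, g, p)
  expect_equal(sol$iterations, 0)
  expect_lt(sol$residual_norm, 1e-12)
  expect_equal(sol$theta, numeric(n))
  expect_equal(sol$Ttens, rep(np$T0, n))
})

test_that("small uniform load reproduces the plate-on-foundation limit", {
  p <- best()
  np <- solver_coefficients(p)
  g <- build_grid(NULL, s_max_factor = 10, ds0 = 0.05)
  n <- g$n
  load <- 1e-5 # linear regime
  press <- function(R, Z, theta)
    list(sigma_r = numeric(length(R)),
         sigma_v = -np$Efound * Z * cos(theta) - rep(load, length(R)))
  sol <- solve_shape(list(theta = numeric(n), Ttens = rep(np$T0, n)),
                     press, g, p)
  # away from the edge the foundation carries the load: Z = -load/K
  interior <- g$s < 5
  expect_equal(sol$Z[interior], rep(-load / np$Efound, sum(interior)),
               tolerance = 0.05)
  # the edge boundary layer decays over the bending-foundation length
  # (B/K)^(1/4)
  expect_lt((np$bend / np$Efound)^0.25, 1)
})

test_that("Newton converges quadratically on a smooth loaded state", {
  p <- best()
  np <- solver_coefficients(p)
  g <- tiny_grid(s_max = 8, ds0 = 0.06)
  n <- g$n
  press <- function(R, Z, theta)
    list(sigma_r = numeric(length(R)),
         sigma_v = -np$Efound * Z * cos(theta) - 0.02 * exp(-R^2))
  sys <- list(grid = g, np = np, joint = FALSE, stress_fn = press)
  x0 <- npwrap:::pack_state(numeric(n), numeric(n), numeric(n),
                            rep(np$T0, n), g$s, numeric(n))
  sol <- npwrap:::newton_solve(x0, sys, tol = 1e-11)
  h <- sol$history
  expect_lt(sol$residual_norm, 1e-11)
  # superlinear tail: successive residuals drop faster than a fixed
  # linear rate once in the Newton basin
  drops <- h[-1] / h[-length(h)]
  expect_lt(min(drops), 1e-3)
})

test_that("compiled and reference residuals agree to machine precision", {
  p <- best(a = 60e-9)
  np <- solver_coefficients(p)
  g <- tiny_grid(s_max = 6, ds0 = 0.08)
  n <- g$n
  set.seed(3)
  theta <- smooth_theta(g, amp = 0.5)
  pq <- npwrap:::derive_pq(theta, g)
  sh <- reconstruct_shape(theta, g)
  Z <- sh$Z - 0.2 * exp(-g$s^2 / 2)
  x <- npwrap:::pack_state(theta, pq$p, pq$q, rep(np$T0, n) +
                             0.01 * sin(g$s), sh$R, Z, 0.8)
  sys <- list(grid = g, np = np, joint = TRUE, stress_fn = NULL,
              xi_b = runif(n), Z_prev = Z + 0.005 * runif(n, -1, 1),
              dt = 0.003)
  rc <- npwrap:::coupled_residual(x, sys)
  sysr <- sys; sysr$force_r <- TRUE
  rr <- npwrap:::coupled_residual(x, sysr)
  expect_lt(max(abs(rc - rr)), 1e-11 * max(1, max(abs(rr))))
})

test_that("solving with the built-in stress model honors the particle balance", {
  p <- best(a = 50e-9)
  np <- solver_coefficients(p)
  g <- build_grid(NULL, s_max_factor = 10, ds0 = 0.08)
  state <- initialize_state(np, g)
  st1 <- step(state, np, g)
  # the joint solve leaves a negligible net force on the particle
  mem <- list(theta = st1$theta, R = st1$R, Z = st1$Z)
  f <- net_vertical_force(st1$Z0, mem, st1$xi_b, np, g)
  expect_lt(abs(f), 1e-8)
  # and the membrane static+viscous residual is converged
  expect_lt(max(abs(st1$theta[1])), 1e-12)
})
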