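test_that("shape reconstruction integrates the inclination field", {
  g <- tiny_grid()
  th0 <- numeric(g$n)
  sh <- reconstruct_shape(th0, g)
  expect_equal(sh$R, g$s)
  expect_equal(sh$Z, numeric(g$n))
  # straight cone on a uniform toy grid
  gu <- uniform_grid()
  phi <- 0.4
  thc <- rep(phi, gu$n)
  thc[1] <- 0 # axis value irrelevant except for the R(0) anchor
  shc <- reconstruct_shape(c(0, rep(phi, gu$n - 1)), gu)
  # away from the first cell the cone is exact for the trapezoid rule
  i <- 3:gu$n
  expect_equal(diff(shc$R[i]) / diff(gu$s[i]), rep(cos(phi), length(i) - 1),
               tolerance = 1e-12)
  expect_equal(diff(shc$Z[i]) / diff(gu$s[i]), rep(sin(phi), length(i) - 1),
               tolerance = 1e-12)
  expect_equal(shc$Z[gu$n], 0)
  expect_error(reconstruct_shape(rep(0.1, g$n), g), "axis")
})

test_that("reconstruction converges at second order to a fine-quadrature oracle", {
  th_fun <- function(s) 0.5 * sin(0.9 * s) * (1 - exp(-s^2))
  err <- sapply(c(0.1, 0.025), function(h) {
    g <- build_grid(NULL, s_max_factor = 6, ds0 = h)
    sh <- reconstruct_shape(th_fun(g$s), g)
    sfine <- seq(0, 6, length.out = 20001)
    Rf <- cumsum(c(0, diff(sfine) * (cos(th_fun(sfine))[-1] +
                                       cos(th_fun(sfine))[-20001]) / 2))
    max(abs(sh$R - approx(sfine, Rf, g$s)$y))
  })
  expect_lt(err[2], err[1] / 8)
})

test_that("internal resultants recover closed forms", {
  g <- tiny_grid()
  mom0 <- internal_resultants(numeric(g$n), g, nu = 0.5, bend = 1)
  expect_equal(mom0$Ms, numeric(g$n))
  expect_equal(mom0$Mtheta, numeric(g$n))
  expect_equal(mom0$V, numeric(g$n))
  # spherical cap theta = s/rho: at the apex Ms = Mtheta = -B/rho, V -> 0
  rho <- 2.5
  gu <- uniform_grid(n = 201, s_max = 2)
  mom <- internal_resultants(gu$s / rho, gu, nu = 0.5, bend = 1)
  expect_equal(mom$Ms[1], -(1 + 0.5) / rho, tolerance = 1e-6)
  expect_equal(mom$Mtheta[1], -(1 + 0.5) / rho, tolerance = 1e-6)
  expect_lt(abs(mom$V[1]), 1e-4)
  # moments scale linearly with the bending modulus
  mom2 <- internal_resultants(gu$s / rho, gu, nu = 0.5, bend = 3)
  expect_equal(mom2$Ms, 3 * mom$Ms, tolerance = 1e-12)
})

test_that("flat membrane under zero stress is an exact equilibrium", {
  g <- tiny_grid()
  n <- g$n
  res <- assemble_residuals(numeric(n), rep(0.035, n), numeric(n),
                            numeric(n), g, bend = 0.01, T0 = 0.035)
  expect_equal(max(abs(res)), 0)
  # a uniform vertical load appears verbatim in the vertical residuals
  cval <- 0.17
  res2 <- assemble_residuals(numeric(n), rep(0.035, n), numeric(n),
                             rep(cval, n), g, bend = 0.01, T0 = 0.035)
  idx <- 2:(n - 1)
  expect_equal(res2[2 * idx], rep(cval, length(idx)))
  expect_equal(res2[2 * idx - 1], rep(0, length(idx)))
})

test_that("expanded equilibrium residuals agree with the primitive-form oracle", {
  set.seed(7)
  g <- tiny_grid(s_max = 5, ds0 = 0.08)
  n <- g$n
  bend <- 0.0117
  for (rep in 1:5) {
    amp <- runif(1, 0.05, 0.6)
    k <- runif(1, 0.5, 2)
    theta <- amp * sin(k * g$s) * (1 - exp(-g$s^2))
    Ttens <- 0.035 + 0.01 * cos(0.7 * g$s)
    sigma_r <- 0.02 * sin(g$s)
    sigma_v <- -0.05 * exp(-g$s^2)
    res <- assemble_residuals(theta, Ttens, sigma_r, sigma_v, g,
                              bend = bend, T0 = 0.035)
    orc <- oracle_eq67(theta, Ttens, sigma_r, sigma_v, g, bend, nu = 0.5)
    idx <- 2:(n - 1)
    expect_lt(max(abs(res[2 * idx - 1] - orc$res_r)), 1e-10)
    expect_lt(max(abs(res[2 * idx] - orc$res_v)), 1e-10)
  }
})

test_that("degenerate interior geometry is flagged", {
  g <- tiny_grid()
  n <- g$n
  theta <- c(0, rep(pi, n - 1)) # folds R back through zero
  expect_error(assemble_residuals(theta, rep(0.035, n), numeric(n),
                                  numeric(n), g, bend = 0.01, T0 = 0.035),
               "degenerate")
})
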