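test_that("dissociation rate follows the Bell law in |l - lambda|", {
  p <- best()
  expect_equal(dissociation_rate(p$lambda, p), p$K_d0)
  delta <- p$k_B * p$Temp / (p$kappa * p$x_b)
  expect_equal(dissociation_rate(p$lambda + delta, p), p$K_d0 * exp(1),
               tolerance = 1e-12)
  # symmetric in compression and extension
  expect_equal(dissociation_rate(p$lambda - delta / 3, p),
               dissociation_rate(p$lambda + delta / 3, p))
  # 10 nm of elongation at the default stiffness: about 1.2e5-fold
  ratio <- dissociation_rate(p$lambda + 10e-9, p) / p$K_d0
  expect_equal(ratio, exp(p$kappa * 10e-9 * p$x_b / (p$k_B * p$Temp)))
  expect_gt(ratio, 1e5)
  expect_lt(ratio, 1.4e5)
  expect_warning(dissociation_rate(p$lambda + 1, p), "saturated")
})

test_that("closed-form bond update matches exact special cases", {
  # double-root case: d xi/dt = (1 - xi)^2 from 0 gives t/(1+t)
  for (tt in c(0.3, 1, 2, 10)) {
    expect_equal(npwrap:::riccati_advance(0, 1, 1, 1, 0, tt), tt / (1 + tt),
                 tolerance = 1e-12)
  }
  # equilibrium is a fixed point
  p <- best()
  xeq <- equilibrium_bond_density(p$lambda, p)
  expect_equal(advance_bond_density(xeq, p$lambda, 5, p), xeq,
               tolerance = 1e-9 * p$xi_l)
})

test_that("closed-form update matches a high-accuracy ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- best()
  np <- solver_coefficients(p)
  # nondimensional best-estimate coefficients at several gaps
  for (lhat in c(np$lambda, np$lambda + 0.05, np$lambda - 0.02)) {
    Kd <- npwrap:::kd_hat(lhat, np)
    got <- npwrap:::riccati_advance(0.01, 1, np$xi_r, np$Kf, Kd, 0.05)
    ref <- ode_bond_oracle(0.01, 1, np$xi_r, np$Kf, Kd, 0.05)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("bond update preserves bounds and approaches equilibrium monotonically", {
  p <- best(xi_r = 0.7e15)
  np <- solver_coefficients(p)
  set.seed(42)
  for (rep in 1:20) {
    xi0 <- runif(1, 0, min(1, np$xi_r))
    lhat <- runif(1, 0.1, 3)
    Kd <- npwrap:::kd_hat(lhat, np)
    dts <- sort(runif(6, 1e-6, 10))
    xis <- vapply(dts, function(dt)
      npwrap:::riccati_advance(xi0, 1, np$xi_r, np$Kf, Kd, dt), 0)
    expect_true(all(xis >= -1e-12))
    expect_true(all(xis <= min(1, np$xi_r) + 1e-12))
    # monotone in t towards the smaller root
    xeq <- npwrap:::riccati_roots(1, np$xi_r, np$Kf, Kd)$minus
    d0 <- abs(xi0 - xeq)
    expect_true(all(diff(abs(xis - xeq)) <= 1e-12))
    expect_true(all(abs(xis - xeq) <= d0 + 1e-12))
  }
})

test_that("equilibrium density has the right limits", {
  p <- best(xi_r = 0.6e15)
  # no dissociation: all of the scarcer species is bound
  p0 <- p; p0$K_d0 <- 0
  expect_equal(equilibrium_bond_density(p$lambda, p0), 0.6e15,
               tolerance = 1e-6)
  # best estimates at rest gap: about 992.9 / 1000 bound
  pb <- best()
  expect_equal(equilibrium_bond_density(pb$lambda, pb) / 1e12, 992.9539,
               tolerance = 1e-4)
  # strong dissociation: xi -> Kf xi_l xi_r / Kd
  lfar <- pb$lambda + 25e-9
  Kd <- dissociation_rate(lfar, pb)
  expect_equal(equilibrium_bond_density(lfar, pb),
               pb$K_f * pb$xi_l * pb$xi_r / Kd, tolerance = 1e-3)
})

test_that("short-time growth rate is K_f xi_l xi_r", {
  p <- best()
  dt <- 1e-6
  xi1 <- advance_bond_density(0, p$lambda, dt, p)
  expect_equal(xi1 / dt, p$K_f * p$xi_l * p$xi_r, tolerance = 1e-3)
})
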