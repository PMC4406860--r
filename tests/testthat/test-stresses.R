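test_that("bond geometry reproduces elementary configurations", {
  # apex node with the particle one rest length above the surface
  lam <- 0.2
  geo <- bond_geometry(R = 0, Z = 0, Z0 = 1 + lam, a = 1)
  expect_equal(geo$l, lam)
  expect_equal(geo$alpha, 0)
  # 45-degree node
  geo2 <- bond_geometry(R = 1 + lam, Z = 0, Z0 = 1 + lam, a = 1)
  expect_equal(geo2$l, (1 + lam) * sqrt(2) - 1, tolerance = 1e-12)
  expect_equal(geo2$alpha, pi / 4, tolerance = 1e-12)
  # a node above the particle center is admissible: alpha > pi/2
  geo3 <- bond_geometry(R = 0.5, Z = 1.5, Z0 = 1.0, a = 1)
  expect_gt(geo3$alpha, pi / 2)
  expect_error(bond_geometry(R = 0, Z = 1, Z0 = 1, a = 1), "collapsed")
})

test_that("repulsion law matches direct substitution and decays", {
  gam <- 2.5; tau <- 0.05
  expect_equal(repulsion_magnitude(tau, gam, tau),
               (gam / tau) * (2 / tau) * exp(-1), tolerance = 1e-12)
  ls <- seq(0.5, 10, by = 0.5) * tau
  vals <- repulsion_magnitude(ls, gam, tau)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[20] / vals[2], 1e-3)
  expect_equal(repulsion_magnitude(c(0.3, 2) * tau, 0, tau), c(0, 0))
  expect_warning(repulsion_magnitude(-1e-3, gam, tau), "clamped")
})

test_that("total stresses decompose along the bond direction", {
  p <- best(a = 50e-9)
  np <- solver_coefficients(p)
  g <- tiny_grid()
  n <- g$n
  # flat resting state far from the particle (l >> tau): negligible
  geo <- bond_geometry(g$s, numeric(n), Z0 = 3, a = 1)
  st <- total_stresses(geo, numeric(n), numeric(n), numeric(n), numeric(n),
                       dt = 0.01, p)
  expect_lt(max(abs(st$sigma_r)), 1e-6)
  expect_lt(max(abs(st$sigma_v)), 1e-6)
  # apex node with stretched bonds pulls the membrane up
  geo2 <- bond_geometry(0, 0, Z0 = 1 + np$lambda + 0.05, a = 1)
  st2 <- total_stresses(geo2, 0.5, 0, 0, 0, dt = 0.01, p)
  expect_equal(st2$sigma_r, 0)
  expect_equal(st2$bond_v, np$CK * 0.5 * 0.05, tolerance = 1e-10)
  expect_gt(st2$sigma_v, 0)
})

test_that("stress fields match a direct transcription of the stress model", {
  set.seed(11)
  p <- best(a = 80e-9)
  np <- solver_coefficients(p)
  g <- tiny_grid()
  n <- g$n
  theta <- smooth_theta(g)
  sh <- reconstruct_shape(theta, g)
  Z <- sh$Z - 0.3 * exp(-g$s^2)
  Zp <- Z + 0.01 * runif(n, -1, 1)
  xi <- runif(n, 0, 1)
  Z0 <- 0.9
  dt <- 0.037
  geo <- bond_geometry(sh$R, Z, Z0, a = 1)
  st <- total_stresses(geo, xi, Z, Zp, theta, dt, p)
  # independent elementwise transcription
  l <- sqrt(sh$R^2 + (Z0 - Z)^2) - 1
  al <- atan2(sh$R, Z0 - Z)
  fb <- np$CK * xi * (l - np$lambda)
  rep <- (np$gamma / l) * (1 / l + 1 / np$tau) * exp(-l / np$tau)
  sr <- -fb * sin(al) + rep * sin(al)
  sv <- (-np$Efound * Z - np$Efound * (Z - Zp) / dt) * cos(theta) +
    fb * cos(al) - rep * cos(al)
  expect_lt(max(abs(st$sigma_r - sr)), 1e-12)
  expect_lt(max(abs(st$sigma_v - sv)), 1e-12)
  # vector consistency: bond + repulsion = (net magnitude) x unit vector
  # towards the particle center
  ehat_r <- -sin(al); ehat_v <- cos(al)
  expect_lt(max(abs((st$bond_r + st$rep_r) - (fb - rep) * ehat_r)), 1e-12)
  expect_lt(max(abs((st$bond_v + st$rep_v) - (fb - rep) * ehat_v)), 1e-12)
  # pure elastic limit: cytoplasm stress opposes displacement
  st3 <- total_stresses(geo, xi, Z, Z, theta, dt, p)
  opp <- st3$cyto_v * Z
  expect_true(all(opp[abs(Z) > 1e-6] < 0))
})
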