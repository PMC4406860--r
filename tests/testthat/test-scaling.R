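test_that("maximum bond elongation follows the Bell-balance estimate", {
  p <- best() # kappa = 0.01 N/m
  dl <- max_bond_elongation(p)
  # about 8.5 nm; order 10 nm
  expect_equal(dl, (p$k_B * 310 / (0.01 * 0.5e-9)) * log(10 / 5e-4),
               tolerance = 1e-12)
  expect_equal(round(log10(dl * 1e9)), 1)
  # unit log when K_f xi_l = e * K_d0
  pe <- best()
  pe$K_d0 <- pe$K_f * pe$xi_l / exp(1)
  expect_equal(max_bond_elongation(pe),
               pe$k_B * pe$Temp / (pe$kappa * pe$x_b), tolerance = 1e-12)
  # inverse proportionality to the bond stiffness
  p2 <- best(kappa = 2 * p$kappa)
  expect_equal(max_bond_elongation(p2), dl / 2, tolerance = 1e-12)
  pbad <- best()
  pbad$K_d0 <- 1e9
  expect_error(max_bond_elongation(pbad), "no net bond formation")
})

test_that("firm-adhesion estimates match the energy balance", {
  p <- best(a = 50e-9)
  fa <- firm_adhesion_estimates(p)
  # about 5-6% of the ligand density
  expect_gt(fa$xi_b_firm_frac, 0.03)
  expect_lt(fa$xi_b_firm_frac, 0.08)
  # reached within about a millisecond (order consistency)
  expect_gt(fa$t_firm, 1e-4)
  expect_lt(fa$t_firm, 1e-2)
  # a^-2 scaling
  p4 <- best(a = 200e-9)
  fa4 <- firm_adhesion_estimates(p4)
  expect_equal(fa4$xi_b_firm / fa$xi_b_firm, 1 / 16, tolerance = 1e-10)
})

test_that("wrapping time scales as the particle-to-bond length ratio", {
  p <- best(a = 50e-9)
  wt <- wrapping_time(p)
  dl <- max_bond_elongation(p)
  expect_equal(wt$coefficient, (50e-9 + 20e-9) / dl, tolerance = 1e-12)
  # with the elongation rounded to 10 nm this is the classic factor 7
  expect_equal(wt$coefficient * dl / 10e-9, 7, tolerance = 1e-10)
  expect_equal(wt$t_wrapping, wt$coefficient * 0.1, tolerance = 1e-12)
  # halving the elongation (doubling kappa) doubles the coefficient
  p2 <- best(a = 50e-9, kappa = 2e-2)
  expect_equal(wrapping_time(p2)$coefficient, 2 * wt$coefficient,
               tolerance = 1e-12)
  # small-particle limit: coefficient -> lambda/(l_max - lambda)
  p0 <- best(a = 1e-12)
  expect_equal(wrapping_time(p0)$coefficient,
               p0$lambda / max_bond_elongation(p0), tolerance = 1e-3)
})

test_that("depth scalings have the stated parameter dependences", {
  p <- best(a = 100e-9)
  ds <- depth_scalings(p)
  # large particles: d/(2a) ~ 1/sqrt(E a): quadrupling a halves it
  p4 <- best(a = 400e-9)
  expect_equal(depth_scalings(p4)$large_particle, ds$large_particle / 2,
               tolerance = 1e-12)
  # small particles: the a/(B E) combination is invariant under
  # (a, B) -> (2a, 2B) at fixed E
  p2 <- best(a = 200e-9, B = 2e-19)
  expect_equal(depth_scalings(p2)$small_particle, ds$small_particle,
               tolerance = 1e-12)
  # deformation extent w = (B a / E)^(1/4)
  expect_equal(ds$w_small, (p$B * p$a / p$E)^0.25, tolerance = 1e-12)
})

test_that("scaling summary collects consistent entries", {
  p <- best(a = 50e-9)
  est <- scaling_estimates(p)
  expect_equal(est$t_b, 0.1, tolerance = 1e-12)
  expect_equal(est$bond_time_scale, 0.1, tolerance = 1e-12)
  expect_equal(est$wrapping_coefficient * est$l_max_minus_lambda,
               70e-9, tolerance = 1e-12)
  expect_true(all(unlist(est[c("l_max_minus_lambda", "xi_b_firm",
                               "t_firm", "t_wrapping")]) > 0))
})
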