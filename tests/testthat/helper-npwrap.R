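# Shared fixtures and oracles for the test suite.

best <- function(...) default_parameters(...)

# Small nondimensional grid for cheap solver tests.
tiny_grid <- function(s_max = 6, ds0 = 0.1) {
  build_grid(NULL, s_max_factor = s_max, ds0 = ds0)
}

# Uniform toy grid (closed-form geometry checks).
uniform_grid <- function(n = 51, s_max = 5) {
  s <- seq(0, s_max, length.out = n)
  g <- list(s = s, n = n, ds = diff(s), s_max = s_max,
            wq = npwrap:::trapz_weights(s), a = NA_real_,
            coarse = FALSE, ds0 = s_max / (n - 1),
            D1 = npwrap:::fd_operator(s, 1L, 5L),
            D2 = npwrap:::fd_operator(s, 2L, 5L),
            D3 = npwrap:::fd_operator(s, 3L, 5L),
            D1c = npwrap:::fd_operator(s, 1L, 3L))
  class(g) <- "npw_grid"
  g
}

# Independent evaluation of the projected equilibrium residuals: instead
# of the expanded radial/vertical forms, go through the primitive
# tangential/normal balances and the moment relations, with all chain
# rules written out analytically.  Shares only the discrete derivative
# operators with the implementation, so the algebra is checked
# independently.
oracle_eq67 <- function(theta, Ttens, sigma_r, sigma_v, grid, bend, nu) {
  n <- grid$n
  sh <- reconstruct_shape(theta, grid)
  r <- sh$R
  th1 <- as.numeric(grid$D1 %*% theta)
  th2 <- as.numeric(grid$D2 %*% theta)
  th3 <- as.numeric(grid$D3 %*% theta)
  T1 <- as.numeric(grid$D1c %*% Ttens)
  sn <- sin(theta); cs <- cos(theta)
  idx <- 2:(n - 1)
  r <- r[idx]; th <- theta[idx]; p <- th1[idx]; q <- th2[idx]
  c3 <- th3[idx]; Tt <- Ttens[idx]; dT <- T1[idx]
  sn <- sn[idx]; cs <- cs[idx]
  sr <- sigma_r[idx]; sv <- sigma_v[idx]
  # V is independent of nu: V = -B (theta'' + cos(theta) theta'/r
  #                                - sin(theta)cos(theta)/r^2)
  V <- -bend * (q + cs * p / r - sn * cs / r^2)
  # V' by the chain rule (r' = cos(theta))
  dVds <- -bend * (c3 +
                     (-sn * p^2 + cs * q) / r - cs^2 * p / r^2 -
                     ((cs^2 - sn^2) * p / r^2 - 2 * sn * cs^2 / r^3))
  sig_t <- sr * cs + sv * sn
  sig_n <- -sr * sn + sv * cs
  eq_tan <- dT - V * p + sig_t
  eq_nor <- Tt * p + dVds + Tt * sn / r + V * cs / r + sig_n
  list(res_r = cs * eq_tan - sn * eq_nor,
       res_v = sn * eq_tan + cs * eq_nor)
}

# High-accuracy reference solution of the bond kinetics by deSolve, used
# as the independent oracle for the closed-form update.
ode_bond_oracle <- function(xi0, xi_l, xi_r, Kf, Kd, tend) {
  f <- function(t, y, parms) {
    list(Kf * (xi_l - y) * (xi_r - y) - Kd * y)
  }
  out <- deSolve::ode(y = xi0, times = c(0, tend), func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-14)
  unname(out[2, 2])
}

# Random smooth fields vanishing appropriately at the axis.
smooth_theta <- function(grid, amp = 0.3, k = 1.3) {
  amp * sin(k * grid$s) * (1 - exp(-grid$s^2))
}
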