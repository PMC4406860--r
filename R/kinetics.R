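# Ligand-receptor bond kinetics with force-dependent dissociation.
#
# The local bond density obeys the second-order (Riccati) rate law
#   d xi/dt = K_f (xi_l - xi)(xi_r - xi) - K_d xi,
# with a dissociation rate that grows exponentially with the magnitude of
# the spring force on the bond (Bell kinetics).  With the geometry frozen
# over a time step the coefficients are constant and the equation has a
# closed-form solution, which is used instead of numerical integration.

# Largest admitted Bell exponent; beyond this the rate saturates (the bond
# population is annihilated within any practical time step anyway).
.bell_exponent_cap <- 700

#' Force-dependent bond dissociation rate
#'
#' Bell's law: \code{K_d = K_d0 * exp(kappa * |l - lambda| * x_b / (k_B Temp))}.
#' The rate depends on the magnitude of the bond deformation only: both
#' stretched and compressed bonds dissociate faster, since compression
#' distorts the binding interface much as tension does.
#'
#' @param l membrane-particle gap [m] (scalar or vector)
#' @param params an \code{npw_params} object
#' @return dissociation rate(s) [1/s]
#' @export
dissociation_rate <- function(l, params) {
  p <- params
  expo <- p$kappa * abs(l - p$lambda) * p$x_b / (p$k_B * p$Temp)
  if (any(expo > .bell_exponent_cap)) {
    warning("Bell exponent exceeds overflow guard; dissociation rate saturated")
    expo <- pmin(expo, .bell_exponent_cap)
  }
  p$K_d0 * exp(expo)
}

# Nondimensional variant used in the solver hot path (no warning; the cap
# is harmless there because the closed-form update is overflow-safe).
kd_hat <- function(l_hat, np) {
  np$Kd0 * exp(pmin(np$CK * abs(l_hat - np$lambda), .bell_exponent_cap))
}

# Roots xi_minus <= xi_plus of the Riccati quadratic
#   K_f xi^2 - (K_f (xi_l + xi_r) + K_d) xi + K_f xi_l xi_r = 0,
# computed in a cancellation- and overflow-safe form (K_d can be ~1e300
# after the Bell exponential).  Vectorized over K_d.
riccati_roots <- function(xi_l, xi_r, Kf, Kd) {
  b <- Kf * (xi_l + xi_r) + Kd
  # discriminant ratio (b^2 - 4ac)/b^2 via the exact identity
  # b^2 - 4ac = Kf^2 (xi_l - xi_r)^2 + Kd (2 Kf (xi_l + xi_r) + Kd),
  # evaluated factor-by-factor against b so that neither cancellation
  # (small Kd) nor overflow (huge Kd) occurs
  q <- (Kf * (xi_l - xi_r) / b)^2 +
    (Kd / b) * ((2 * Kf * (xi_l + xi_r) + Kd) / b)
  sq <- sqrt(pmin(pmax(q, 0), 1))
  xi_minus <- (2 * Kf * xi_l / (1 + sq)) * (xi_r / b)
  xi_plus <- b * (1 + sq) / (2 * Kf)
  list(minus = xi_minus, plus = xi_plus)
}

#' Equilibrium bond density at a given gap
#'
#' The attracting steady state of the kinetic law: the smaller root of the
#' Riccati quadratic.  It always lies in [0, min(xi_l, xi_r)]; for strong
#' dissociation it decays as K_f xi_l xi_r / K_d.
#'
#' @param l membrane-particle gap [m] (scalar or vector)
#' @param params an \code{npw_params} object
#' @return equilibrium bond density [m^-2]
#' @export
equilibrium_bond_density <- function(l, params) {
  p <- params
  Kd <- p$K_d0 * exp(pmin(p$kappa * abs(l - p$lambda) * p$x_b /
                            (p$k_B * p$Temp), .bell_exponent_cap))
  riccati_roots(p$xi_l, p$xi_r, p$K_f, Kd)$minus
}

# Closed-form advance of d xi/dt = Kf (xi_l - xi)(xi_r - xi) - Kd xi over
# a step dt with constant coefficients.  Vectorized over nodes.  Writing
# the rate as Kf (xi - xi-)(xi - xi+), the cross-ratio
#   u = (xi - xi-)/(xi - xi+)
# decays exactly as u(t) = u(0) exp(-Kf (xi+ - xi-) t), which converges
# monotonically to the smaller root xi- from any start below xi+.
# All quantities in a consistent unit system (the solver passes
# nondimensional ones).
riccati_advance <- function(xi0, xi_l, xi_r, Kf, Kd, dt) {
  if (Kf == 0) return(xi0 * exp(-Kd * dt)) # pure first-order decay
  rt <- riccati_roots(xi_l, xi_r, Kf, Kd)
  xm <- rt$minus
  xp <- rt$plus
  gap <- xp - xm
  out <- numeric(length(xm))
  # near-degenerate (double-root) branch: dy/dt = Kf y^2 with y = xi - xc
  dbl <- gap < 1e-12 * xp
  if (any(dbl)) {
    y0 <- xi0[dbl] - xm[dbl]
    out[dbl] <- xm[dbl] + y0 / (1 - Kf * y0 * dt)
  }
  reg <- !dbl
  if (any(reg)) {
    u0 <- (xi0[reg] - xm[reg]) / (xi0[reg] - xp[reg])
    u <- u0 * exp(-Kf * gap[reg] * dt)
    out[reg] <- (xm[reg] - xp[reg] * u) / (1 - u)
  }
  out
}

#' Advance the bond density field over one time step
#'
#' Exact constant-coefficient solution of the kinetic law at each node,
#' with the geometry (hence the dissociation rate) frozen at its
#' start-of-step value.  Maps the admissible interval
#' [0, min(xi_l, xi_r)] into itself for any dt and approaches the
#' equilibrium density monotonically.
#'
#' @param xi_b bond density field [m^-2]
#' @param l gap field [m], same length
#' @param dt time step [s], > 0
#' @param params an \code{npw_params} object
#' @return updated bond density field [m^-2]
#' @export
advance_bond_density <- function(xi_b, l, dt, params) {
  stopifnot(dt > 0, length(xi_b) == length(l))
  p <- params
  Kd <- p$K_d0 * exp(pmin(p$kappa * abs(l - p$lambda) * p$x_b /
                            (p$k_B * p$Temp), .bell_exponent_cap))
  riccati_advance(xi_b, p$xi_l, p$xi_r, p$K_f, Kd, dt)
}
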