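# Stresses exerted on the membrane: bond springs, short-range repulsion,
# and the Kelvin-Voigt cytoplasmic foundation.
#
# All functions here work in the nondimensional unit system of
# solver_coefficients(): lengths in particle radii, densities in xi_l,
# stresses in xi_l*k_B*Temp/x_b.  Module-surface wrappers accepting
# dimensional parameters convert at the boundary.

# Gap floor (in particle radii) guarding the 1/l factors of the repulsion
# law; the repulsion at the floor is many orders of magnitude larger than
# any bond stress, so interpenetration is stopped well before the floor is
# reached.
.l_floor <- 1e-4

#' Membrane-to-particle bond geometry
#'
#' For each membrane node at (R, Z) and a particle center on the axis at
#' elevation Z0, computes the gap l (distance from the node to the particle
#' surface along the line to the particle center) and the angle alpha
#' between that line and the vertical.  Nodes that have wrapped past the
#' particle equator (Z > Z0) have alpha > pi/2.
#'
#' @param R,Z membrane node coordinates (same length; in units of the
#'   particle radius if \code{a = 1}, else in the units of \code{a})
#' @param Z0 particle center elevation
#' @param a particle radius in the same units
#' @return list with fields \code{l} (gap, same units) and \code{alpha}
#'   (radians, in [0, pi))
#' @export
bond_geometry <- function(R, Z, Z0, a = 1) {
  stopifnot(length(R) == length(Z))
  dv <- Z0 - Z
  rr <- sqrt(R^2 + dv^2)
  if (any(rr < 1e-12 * a))
    stop("membrane node coincides with the particle center (geometry collapsed)",
         call. = FALSE)
  list(l = rr - a, alpha = atan2(R, dv))
}

#' Short-range membrane-particle repulsion
#'
#' Exponentially screened contact stress
#' \code{(gamma / l) (1/l + 1/tau) exp(-l/tau)}, acting along the line away
#' from the particle center.  Gaps at or below zero are clamped to a small
#' positive floor (1e-4 of the length unit) with a warning; the stress at
#' the floor is astronomically large, so the clamp only matters for
#' pathological trial states inside a Newton iteration.
#'
#' @param l gap (scalar or vector)
#' @param gamma repulsion constant
#' @param tau repulsion decay length
#' @return repulsion stress magnitude, in the unit system of the inputs
#' @export
repulsion_magnitude <- function(l, gamma, tau) {
  if (any(l <= 0)) {
    warning("nonpositive membrane-particle gap clamped to repulsion floor")
    l <- pmax(l, .l_floor * tau / 0.05)
  }
  (gamma / l) * (1 / l + 1 / tau) * exp(-l / tau)
}

# Hot-path repulsion and its d/dl.  Below the gap floor the law is
# extended linearly (continuing the slope at the floor): the 1/l^2
# singularity never enters the Newton iteration, yet trial iterates that
# interpenetrate still feel a strong, smoothly differentiable restoring
# stress.  Nondimensional.
rep_and_slope <- function(l, np) {
  lc <- pmax(l, .l_floor)
  e <- exp(-lc / np$tau)
  f <- (np$gamma / lc) * (1 / lc + 1 / np$tau) * e
  fp <- np$gamma * e * (-2 / lc^3 - 1 / (lc^2 * np$tau) -
                          (1 / lc^2 + 1 / (lc * np$tau)) / np$tau)
  below <- l < .l_floor
  if (any(below)) f[below] <- f[below] + fp[below] * (l[below] - .l_floor)
  list(f = f, fp = fp)
}

#' Total stresses on the membrane
#'
#' Sums the three stress contributions at each node:
#' \itemize{
#'   \item bond springs: magnitude \code{xi_b * kappa * (l - lambda)},
#'     directed towards the particle center (tension pulls the membrane up
#'     towards the particle);
#'   \item short-range repulsion, directed away from the particle center;
#'   \item Kelvin-Voigt cytoplasm: \code{(-K Z - M dZ/dt) cos(theta)} on the
#'     vertical component, with spring \code{K = E/a} and damper
#'     \code{M = mu/a}; the damper is discretized backward-Euler as
#'     \code{(Z - Z_prev)/dt}.
#' }
#'
#' This is the module surface used by tests and diagnostics; it takes
#' dimensional parameters and nondimensionalizes internally, returning
#' stresses in the stress unit of [nondimensionalize()].
#'
#' @param geom bond geometry from [bond_geometry()] (nondimensional: gaps
#'   in particle radii)
#' @param xi_b bond density field in units of xi_l
#' @param Z,Z_prev current and previous membrane elevation fields (radii)
#' @param theta membrane inclination field (radians)
#' @param dt time step in viscoelastic time units (mu/E)
#' @param params an \code{npw_params} object
#' @return list of class \code{npw_stress}: \code{sigma_r}, \code{sigma_v}
#'   (totals) and the per-component breakdown \code{bond_r}, \code{bond_v},
#'   \code{rep_r}, \code{rep_v}, \code{cyto_v}
#' @export
total_stresses <- function(geom, xi_b, Z, Z_prev, theta, dt, params) {
  stopifnot(dt > 0)
  np <- solver_coefficients(params)
  sina <- sin(geom$alpha)
  cosa <- cos(geom$alpha)
  fb <- np$CK * xi_b * (geom$l - np$lambda)
  rep <- rep_and_slope(geom$l, np)$f
  cyto_v <- -np$Efound * (Z + (Z - Z_prev) / dt) * cos(theta)
  out <- list(
    bond_r = -fb * sina, bond_v = fb * cosa,
    rep_r = rep * sina, rep_v = -rep * cosa,
    cyto_v = cyto_v)
  out$sigma_r <- out$bond_r + out$rep_r
  out$sigma_v <- out$bond_v + out$rep_v + out$cyto_v
  class(out) <- "npw_stress"
  out
}
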