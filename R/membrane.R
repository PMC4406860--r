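# Axisymmetric inextensible bending membrane: shape reconstruction,
# internal resultants, and the projected force-balance residuals.
#
# Everything here is nondimensional: lengths in particle radii, tensions in
# stress_unit * a, stresses in stress_unit (see nondimensionalize()).  The
# bending coefficient is bend = B x_b / (xi_l k_B Temp a^3).

#' Reconstruct the membrane shape from its inclination field
#'
#' Because s is material arc length of an inextensible membrane,
#' R' = cos(theta) and Z' = sin(theta).  R integrates outward from
#' R(0) = 0; Z is anchored at the outer edge, Z(s_max) = 0.  Trapezoidal
#' quadrature on the nonuniform grid.
#'
#' @param theta inclination angle per node (radians), theta[1] must be 0
#' @param grid an \code{npw_grid}
#' @return list with fields \code{R} and \code{Z}
#' @export
reconstruct_shape <- function(theta, grid) {
  stopifnot(length(theta) == grid$n)
  if (abs(theta[1]) > 1e-10)
    stop("theta must vanish on the symmetry axis", call. = FALSE)
  R <- cumtrapz(grid$s, cos(theta))
  Z <- cumtrapz(grid$s, sin(theta))
  list(R = R, Z = Z - Z[grid$n])
}

#' Bending moments and transverse shear of the membrane
#'
#' Thin-plate relations for the axisymmetric bending problem:
#' \code{Ms = -B (theta' + nu sin(theta)/r)},
#' \code{Mtheta = -B (sin(theta)/r + nu theta')}, and the moment
#' equilibrium \code{V = cos(theta)/r (Ms - Mtheta) + Ms'}.  On the axis
#' the indeterminate ratios are replaced by their limits
#' \code{sin(theta)/r -> theta'} and
#' \code{cos(theta)(Ms - Mtheta)/r -> (Ms - Mtheta)'}.
#'
#' @param theta inclination field (radians) with theta[1] = 0
#' @param grid an \code{npw_grid}
#' @param nu Poisson ratio
#' @param bend bending coefficient (nondimensional B); moments scale
#'   linearly with it
#' @return list with fields \code{Ms}, \code{Mtheta}, \code{V}
#' @export
internal_resultants <- function(theta, grid, nu = 0.5, bend = 1) {
  sh <- reconstruct_shape(theta, grid)
  th1 <- as.numeric(grid$D1 %*% theta)
  sin_over_r <- sin(theta) / sh$R
  sin_over_r[1] <- th1[1]
  Ms <- -bend * (th1 + nu * sin_over_r)
  Mt <- -bend * (sin_over_r + nu * th1)
  dM <- Ms - Mt
  V <- cos(theta) * dM / sh$R + as.numeric(grid$D1 %*% Ms)
  V[1] <- as.numeric(grid$D1 %*% dM)[1] + as.numeric(grid$D1 %*% Ms)[1]
  list(Ms = Ms, Mtheta = Mt, V = V)
}

# Projected radial/vertical force-balance residuals (the two equilibrium
# equations of the bent membrane) at the given nodes.  All inputs are
# per-node fields; idx selects the evaluation nodes (interior).  Returns
# list(res6, res7) of length(idx).
eq67_core <- function(theta, th1, th2, th3, Ttens, T1, r, sigma_r, sigma_v,
                      bend, idx) {
  th  <- theta[idx]; d1 <- th1[idx]; d2 <- th2[idx]; d3 <- th3[idx]
  Tt  <- Ttens[idx]; dT <- T1[idx]
  rr  <- pmax(r[idx], 1e-9)
  sr  <- sigma_r[idx]; sv <- sigma_v[idx]
  sn <- sin(th); cs <- cos(th)
  s2 <- sn * sn; c2 <- cs * cs
  res6 <- cs * dT - Tt * sn * d1 - Tt * s2 / rr +
    bend * (sn * d3 + 2 * sn * cs / rr * d2 + cs * d1 * d2 +
              (c2 - s2) / rr * d1^2 +
              sn * (s2 - 2 * c2) / rr^2 * d1 +
              s2 * c2 / rr^3) + sr
  res7 <- sn * dT + Tt * cs * d1 + Tt * sn * cs / rr +
    bend * (-cs * d3 - 2 * c2 / rr * d2 + sn * d1 * d2 +
              2 * sn * cs / rr * d1^2 +
              cs * (c2 - 2 * s2) / rr^2 * d1 -
              sn * c2 * cs / rr^3) + sv
  list(res6 = res6, res7 = res7)
}

#' Force-balance residuals for given stress fields
#'
#' Evaluates the projected radial and vertical equilibrium equations of the
#' bent membrane on the grid, for externally supplied stress fields.  The
#' membrane coordinates R, Z are reconstructed from theta.  Interior nodes
#' carry the radial (odd positions) and vertical (even positions)
#' residuals; the first node carries the axis conditions theta = 0 and
#' theta'' = 0, the last node the moment-free and imposed-tension edge
#' conditions Ms = 0 and T cos(theta) - V sin(theta) = T0.
#'
#' @param theta,Ttens inclination and tension fields
#' @param sigma_r,sigma_v imposed stress fields per node
#' @param grid an \code{npw_grid}
#' @param bend nondimensional bending coefficient
#' @param T0 nondimensional edge tension
#' @param nu Poisson ratio (enters the edge moment condition)
#' @return residual vector of length 2 * n, interleaved (radial, vertical)
#' @export
assemble_residuals <- function(theta, Ttens, sigma_r, sigma_v, grid,
                               bend, T0, nu = 0.5) {
  n <- grid$n
  stopifnot(length(theta) == n, length(Ttens) == n,
            length(sigma_r) == n, length(sigma_v) == n)
  sh <- reconstruct_shape(theta, grid)
  if (any(sh$R[2:n] <= 0))
    stop("degenerate geometry: interior node with nonpositive radius",
         call. = FALSE)
  th1 <- as.numeric(grid$D1 %*% theta)
  th2 <- as.numeric(grid$D2 %*% theta)
  th3 <- as.numeric(grid$D3 %*% theta)
  T1  <- as.numeric(grid$D1c %*% Ttens)
  idx <- 2:(n - 1)
  core <- eq67_core(theta, th1, th2, th3, Ttens, T1, sh$R,
                    sigma_r, sigma_v, bend, idx)
  res <- numeric(2 * n)
  res[1] <- theta[1]
  res[2] <- th2[1]
  res[2 * idx - 1] <- core$res6
  res[2 * idx] <- core$res7
  # edge: Ms = 0 and radial tension resultant = T0
  res[2 * n - 1] <- th1[n] + nu * sin(theta[n]) / sh$R[n]
  Vn <- -bend * (th2[n] + cos(theta[n]) * th1[n] / sh$R[n] -
                   sin(theta[n]) * cos(theta[n]) / sh$R[n]^2)
  res[2 * n] <- Ttens[n] * cos(theta[n]) - Vn * sin(theta[n]) - T0
  res
}
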