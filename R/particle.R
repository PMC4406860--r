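# Vertical force balance on the particle.
#
# The particle carries an optional external vertical force F_v and the
# reaction of every bond and contact stress it exerts on the membrane.
# The balance is implicit in the particle elevation Z0 because the gap l
# and bond angle alpha at every node depend on Z0.

#' Net vertical force on the particle at a trial elevation
#'
#' Evaluates (in the nondimensional force unit a^2 xi_l k_B Temp / x_b)
#' \deqn{F(Z_0) = F_v - \int_0^\infty [\xi_b \kappa (l-\lambda)\cos\alpha
#'   - f_{rep}(l) \cos\alpha]\, 2\pi r\, dr,}
#' with the area element mapped to arc length, r dr = R cos(theta) ds.
#' Membrane regions that have wrapped past the equator (cos(theta) < 0)
#' contribute with their signed measure.  Both the bond and the repulsion
#' vertical components carry cos(alpha): the repulsion acts along the same
#' bond direction, with opposite sign.
#'
#' @param Z0 trial particle elevation (particle radii)
#' @param membrane membrane state (fields \code{theta}, \code{R}, \code{Z})
#' @param xi_b bond density field (units of xi_l)
#' @param params an \code{npw_params} object (or solver coefficient list)
#' @param grid an \code{npw_grid}
#' @return net upward force (nondimensional); positive pushes the particle
#'   up, away from the cell
#' @export
net_vertical_force <- function(Z0, membrane, xi_b, params, grid) {
  np <- if (inherits(params, "npw_params")) solver_coefficients(params)
        else params
  R <- membrane$R; Z <- membrane$Z
  dv <- Z0 - Z
  rr <- pmax(sqrt(R^2 + dv^2), 1e-9)
  l <- rr - 1
  cosa <- dv / rr
  net <- (np$CK * xi_b * (l - np$lambda) - rep_and_slope(l, np)$f)
  np$Fv - sum(grid$wq * net * cosa * 2 * pi * R * cos(membrane$theta))
}

#' Solve the particle force balance for the elevation
#'
#' Brackets the root of [net_vertical_force()] around the previous
#' elevation and refines it with a safeguarded scalar root finder.
#'
#' @param prev_Z0 previous particle elevation (initial guess)
#' @param membrane membrane state (fields \code{theta}, \code{R}, \code{Z})
#' @param xi_b bond density field (units of xi_l)
#' @param params an \code{npw_params} object (or solver coefficient list)
#' @param grid an \code{npw_grid}
#' @param tol force tolerance (nondimensional force units)
#' @return list with \code{Z0} and \code{F_v} (the applied force)
#' @export
solve_particle_position <- function(prev_Z0, membrane, xi_b, params, grid,
                                    tol = 1e-10) {
  np <- if (inherits(params, "npw_params")) solver_coefficients(params)
        else params
  # degenerate: nothing couples the particle to the membrane
  dv0 <- prev_Z0 - membrane$Z
  lmin <- min(sqrt(membrane$R^2 + dv0^2)) - 1
  if (all(xi_b <= 0) && lmin > 20 * np$tau && np$gamma >= 0)
    stop("particle unconstrained: no bonds and repulsion out of range",
         call. = FALSE)
  f <- function(z) net_vertical_force(z, membrane, xi_b, np, grid)
  h <- 0.05
  lo <- prev_Z0 - h
  hi <- prev_Z0 + h
  flo <- f(lo); fhi <- f(hi)
  tries <- 0L
  # F decreases with Z0 (lowering the particle compresses the bonds),
  # so a root is bracketed by flo > 0 > fhi
  while (flo * fhi > 0 && tries < 12L) {
    h <- 2 * h
    lo <- prev_Z0 - h
    hi <- prev_Z0 + h
    flo <- f(lo); fhi <- f(hi)
    tries <- tries + 1L
  }
  if (flo * fhi > 0)
    stop(sprintf(
      "particle balance unresolved: F(%.4g) = %.4g, F(%.4g) = %.4g",
      lo, flo, hi, fhi), call. = FALSE)
  rt <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                       tol = 1e-14)
  z <- rt$root
  if (abs(f(z)) > tol) {
    # polish with a few secant steps
    z2 <- z + 1e-8
    for (k in 1:10) {
      f1 <- f(z); f2 <- f(z2)
      if (abs(f1) < tol || f2 == f1) break
      znew <- z - f1 * (z2 - z) / (f2 - f1)
      z2 <- z; z <- znew
    }
  }
  list(Z0 = z, F_v = np$Fv)
}
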