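# Closed-form scaling estimates for the stages of receptor-mediated
# wrapping: firm-adhesion onset, wrapping kinetics, and the dependence of
# the equilibrium depth on particle size and cell mechanics.  These are
# order-of-magnitude relations (undetermined O(1) prefactors); the
# simulator is the quantitative instrument and the estimates serve as
# cross-checks on it.

#' Maximum bond elongation sustaining net bond formation
#'
#' Bonds form faster than they break while K_d(l) < K_f xi_l.  With the
#' Bell law this bounds the elongation:
#' \deqn{l_{max} - \lambda = \frac{k_B T}{\kappa x_b}
#'   \ln\left(\frac{K_f \xi_l}{K_d(0)}\right).}
#' At the default parameters with kappa = 0.01 N/m this is about 10 nm.
#'
#' @param params an \code{npw_params} object
#' @return elongation (m)
#' @export
max_bond_elongation <- function(params) {
  p <- params
  if (p$K_f * p$xi_l <= p$K_d0)
    stop("no net bond formation: K_f * xi_l <= K_d0", call. = FALSE)
  (p$k_B * p$Temp / (p$kappa * p$x_b)) * log(p$K_f * p$xi_l / p$K_d0)
}

#' Firm-adhesion threshold density and time
#'
#' Wrapping can start once the elastic energy stored in the bond springs
#' matches the bending energy scale of the membrane:
#' \code{0.5 kappa (l_max - lambda)^2 xi_b,firm ~ 0.5 B / a^2}, giving
#' \code{xi_b,firm = B / (kappa (l_max - lambda)^2 a^2)}.  Early bond
#' formation proceeds at rate K_f xi_l xi_r, so the firm-adhesion stage
#' lasts \code{t_firm = xi_b,firm / (K_f xi_l xi_r)}.
#'
#' @param params an \code{npw_params} object
#' @return list with \code{xi_b_firm} (m^-2), \code{xi_b_firm_frac}
#'   (fraction of xi_l) and \code{t_firm} (s)
#' @export
firm_adhesion_estimates <- function(params) {
  p <- params
  dl <- max_bond_elongation(p)
  xi_firm <- p$B / (p$kappa * dl^2 * p$a^2)
  list(xi_b_firm = xi_firm,
       xi_b_firm_frac = xi_firm / p$xi_l,
       t_firm = xi_firm / (p$K_f * p$xi_l * p$xi_r))
}

#' Wrapping-stage time scale
#'
#' In the simplified wrapping picture the adhesion front advances by bond
#' formation inside an annulus of width p = (l_max - lambda)/tan(alpha),
#' each new ring taking a bond-formation time t_b = E/(mu K_f xi_l) (in
#' viscoelastic units).  Integrating d(alpha)/dt across the hemisphere
#' gives \code{t_wrapping ~ ((a + lambda)/(l_max - lambda)) t_b}: about
#' 7 t_b for a 50 nm particle.  The full simulation preserves the
#' proportionality to t_b but with a larger prefactor (about 25), since
#' the real front geometry is less favorable than the spherical-cap
#' sketch.
#'
#' @param params an \code{npw_params} object
#' @param t_b bond formation time (defaults to the value implied by
#'   params, in units of mu/E)
#' @return list with \code{coefficient} ((a + lambda)/(l_max - lambda)),
#'   \code{t_wrapping} (same units as t_b) and \code{alpha_rate}, the
#'   right-hand side of the simplified front equation
#'   d(alpha)/dt = (l_max - lambda)/((a + lambda) t_b tan(alpha))
#' @export
wrapping_time <- function(params, t_b = NULL) {
  p <- params
  dl <- max_bond_elongation(p)
  if (is.null(t_b)) t_b <- p$E / (p$mu * p$K_f * p$xi_l)
  coef <- (p$a + p$lambda) / dl
  list(coefficient = coef,
       t_wrapping = coef * t_b,
       alpha_rate = function(alpha) dl / ((p$a + p$lambda) * t_b * tan(alpha)))
}

#' Equilibrium-depth scaling with particle size and cell mechanics
#'
#' Two regimes control the maximum relative depth d/(2a):
#' \itemize{
#'   \item small particles: membrane bending dominates; balancing bending
#'     against the bond force over the deformed region of extent
#'     w ~ (B a / E)^(1/4) gives d/(2a) proportional to sqrt(a/(B E));
#'   \item large particles: cytoplasmic elasticity dominates (foundation
#'     stiffness K = E/a) and d/(2a) is proportional to 1/sqrt(E a).
#' }
#' Both values are reported up to their undetermined O(1) prefactors; they
#' are meant for collapse tests of simulated sweeps, not as absolute
#' predictions.
#'
#' @param params an \code{npw_params} object
#' @return list with \code{small_particle} (sqrt(a/(B E)), SI),
#'   \code{large_particle} (1/sqrt(E a), SI) and \code{w_small}
#'   ((B a / E)^(1/4), m, the bending-foundation decay length)
#' @export
depth_scalings <- function(params) {
  p <- params
  list(small_particle = sqrt(p$a / (p$B * p$E)),
       large_particle = 1 / sqrt(p$E * p$a),
       w_small = (p$B * p$a / p$E)^0.25)
}

#' All scaling estimates as one list
#'
#' Convenience wrapper collecting [max_bond_elongation()],
#' [firm_adhesion_estimates()], [wrapping_time()] and [depth_scalings()],
#' suitable for JSON output.
#'
#' @param params an \code{npw_params} object
#' @return named list of estimates (SI units; times in seconds where
#'   dimensional)
#' @export
scaling_estimates <- function(params) {
  fa <- firm_adhesion_estimates(params)
  wt <- wrapping_time(params)
  ds <- depth_scalings(params)
  nd <- nondimensionalize(params)
  list(l_max_minus_lambda = max_bond_elongation(params),
       xi_b_firm = fa$xi_b_firm,
       xi_b_firm_frac = fa$xi_b_firm_frac,
       t_firm = fa$t_firm,
       wrapping_coefficient = wt$coefficient,
       t_wrapping = wt$t_wrapping * nd$time_unit,
       t_b = nd$t_b,
       bond_time_scale = 1 / (params$K_f * params$xi_l),
       small_particle_scaling = ds$small_particle,
       large_particle_scaling = ds$large_particle,
       w_small = ds$w_small)
}
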