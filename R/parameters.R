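#' Physical model parameters
#'
#' Construct the set of dimensional physical parameters describing a
#' receptor-coated nanoparticle interacting with an endothelial cell
#' membrane.  All values are in SI units.  Defaults are the best-estimate
#' values for anti-ICAM-1-coated particles binding ICAM-1 receptors on an
#' inflamed endothelial cell.
#'
#' The zero-force dissociation rate is specified through the equilibrium
#' ratio \code{Kd0_over_Kf} (units m^-2), the quantity actually measured for
#' this receptor/antibody pair; the stored rate is
#' \code{K_d0 = Kd0_over_Kf * K_f} (units 1/s), which is what the kinetic
#' law consumes.
#'
#' @param a particle radius [m]
#' @param xi_l ligand density on the particle surface [m^-2]
#' @param xi_r receptor density on the cell membrane [m^-2]
#' @param kappa bond spring constant [N/m]
#' @param lambda bond rest length [m]
#' @param gamma short-range repulsion constant [N]
#' @param tau short-range repulsion decay length [m]
#' @param K_f bond formation rate coefficient [m^2/s]
#' @param Kd0_over_Kf zero-force dissociation-to-formation ratio [m^-2]
#' @param x_b Bell length (width of the bond energy barrier) [m]
#' @param T0 resting membrane tension [N/m]
#' @param E cytoplasm Young's modulus [Pa]
#' @param mu cytoplasm viscosity [Pa s]
#' @param B membrane bending modulus [J]
#' @param k_B Boltzmann constant [J/K]
#' @param Temp absolute temperature [K]
#' @param F_v external vertical force applied to the particle [N];
#'   negative values push the particle towards the cell
#' @param nu membrane Poisson ratio (only enters the bending moments and the
#'   outer moment-free boundary condition; 0.5 = incompressible)
#' @return an object of class \code{npw_params}
#' @export
model_parameters <- function(a = 1e-7,
                             xi_l = 1e15,
                             xi_r = 1e15,
                             kappa = 1e-2,
                             lambda = 20e-9,
                             gamma = 1e-15,
                             tau = 5e-9,
                             K_f = 1e-14,
                             Kd0_over_Kf = 5e10,
                             x_b = 0.5e-9,
                             T0 = 30e-6,
                             E = 1e3,
                             mu = 1e3,
                             B = 1e-19,
                             k_B = 1.380649e-23,
                             Temp = 310,
                             F_v = 0,
                             nu = 0.5) {
  p <- list(a = a, xi_l = xi_l, xi_r = xi_r, kappa = kappa, lambda = lambda,
            gamma = gamma, tau = tau, K_f = K_f,
            Kd0_over_Kf = Kd0_over_Kf, K_d0 = Kd0_over_Kf * K_f,
            x_b = x_b, T0 = T0, E = E, mu = mu, B = B,
            k_B = k_B, Temp = Temp, F_v = F_v, nu = nu)
  validate_parameters(p)
  class(p) <- "npw_params"
  p
}

#' Best-estimate parameter set
#'
#' The default parameter set in SI units: 100 nm particle radius,
#' ligand and receptor densities of 1000 molecules/um^2, bond spring
#' constant 0.01 N/m, bond rest length 20 nm, binding rate 0.01 um^2/s,
#' dissociation ratio 0.05 um^-2, Bell length 0.5 nm, membrane tension
#' 30 pN/um, cytoplasm modulus 1 kPa and viscosity 1 kPa s, membrane
#' bending modulus 1e-19 J, at body temperature.
#'
#' @param ... overrides passed on to [model_parameters()]
#' @return an \code{npw_params} object
#' @export
default_parameters <- function(...) model_parameters(...)

validate_parameters <- function(p) {
  pos <- c("a", "xi_l", "xi_r", "kappa", "lambda", "tau", "K_f",
           "Kd0_over_Kf", "x_b", "T0", "E", "mu", "B", "k_B", "Temp")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  if (!is.numeric(p$gamma) || length(p$gamma) != 1L || !is.finite(p$gamma) ||
      p$gamma < 0)
    stop("parameter 'gamma' must be a single nonnegative finite number",
         call. = FALSE)
  if (!is.numeric(p$F_v) || length(p$F_v) != 1L || !is.finite(p$F_v))
    stop("parameter 'F_v' must be a single finite number", call. = FALSE)
  if (!is.numeric(p$nu) || length(p$nu) != 1L || p$nu < 0 || p$nu >= 1)
    stop("parameter 'nu' must lie in [0, 1)", call. = FALSE)
  invisible(p)
}

#' @export
print.npw_params <- function(x, ...) {
  cat("Nanoparticle internalization parameters (SI units)\n")
  cat(sprintf("  particle radius a        %.4g m\n", x$a))
  cat(sprintf("  ligand density xi_l      %.4g m^-2\n", x$xi_l))
  cat(sprintf("  receptor density xi_r    %.4g m^-2\n", x$xi_r))
  cat(sprintf("  bond stiffness kappa     %.4g N/m, rest length %.4g m\n",
              x$kappa, x$lambda))
  cat(sprintf("  kinetics K_f %.4g m^2/s, K_d0 %.4g 1/s (ratio %.4g m^-2)\n",
              x$K_f, x$K_d0, x$Kd0_over_Kf))
  cat(sprintf("  Bell length x_b          %.4g m\n", x$x_b))
  cat(sprintf("  membrane T0 %.4g N/m, bending B %.4g J\n", x$T0, x$B))
  cat(sprintf("  cytoplasm E %.4g Pa, mu %.4g Pa s\n", x$E, x$mu))
  cat(sprintf("  repulsion gamma %.4g N, tau %.4g m\n", x$gamma, x$tau))
  cat(sprintf("  vertical force F_v       %.4g N\n", x$F_v))
  invisible(x)
}

#' Nondimensional groups and unit scales
#'
#' Computes the dimensionless coefficients characterizing the problem,
#' together with the unit scales used to nondimensionalize it: length a,
#' bond density xi_l, stress xi_l*k_B*Temp/x_b (the bond stress at the
#' characteristic thermal elongation k_B*Temp/(kappa*x_b)), and time mu/E
#' (the viscoelastic relaxation time of the cytoplasm).  The derived force
#' unit is a^2*xi_l*k_B*Temp/x_b.
#'
#' The \code{C_*} groups are reported in their conventional form (ratios of
#' the raw SI parameter values); the list also carries the internally
#' consistent solver coefficients derived from the unit scales (see
#' \code{solver_coefficients}).
#'
#' @param params an \code{npw_params} object
#' @return a list of class \code{npw_nondim} with the dimensionless groups
#'   (\code{xi_r_hat}, \code{K_r_hat}, \code{lambda_hat}, \code{tau_hat},
#'   \code{C_E}, \code{C_B}, \code{C_xi}, \code{C_rep}, \code{T0_hat},
#'   \code{C_K}, \code{t_b}) and unit scales (\code{length_unit},
#'   \code{density_unit}, \code{stress_unit}, \code{time_unit},
#'   \code{force_unit})
#' @export
nondimensionalize <- function(params) {
  p <- params
  kT <- p$k_B * p$Temp
  out <- list(
    xi_r_hat   = p$xi_r / p$xi_l,
    K_r_hat    = p$K_d0 / (p$K_f * p$xi_l),
    lambda_hat = p$lambda / p$a,
    tau_hat    = p$tau / p$a,
    C_E        = p$E * p$x_b / (p$xi_l * p$kappa * kT),
    C_B        = p$B * p$x_b / (p$xi_l * p$a^3 * p$kappa * kT),
    C_xi       = p$a * p$kappa * p$x_b / kT,
    C_rep      = p$gamma * p$x_b / (p$xi_l * p$a^2 * p$kappa * kT),
    T0_hat     = p$T0 * p$x_b / (p$xi_l * p$a * p$kappa * kT),
    C_K        = p$kappa * p$a * p$x_b / kT,
    t_b        = p$E / (p$mu * p$K_f * p$xi_l),
    length_unit  = p$a,
    density_unit = p$xi_l,
    stress_unit  = p$xi_l * kT / p$x_b,
    time_unit    = p$mu / p$E,
    force_unit   = p$a^2 * p$xi_l * kT / p$x_b
  )
  class(out) <- "npw_nondim"
  out
}

#' Dimensionless solver coefficients
#'
#' The coefficient set in which the force-balance, stress, kinetic and
#' particle equations are actually integrated.  Every quantity is expressed
#' in the unit system of [nondimensionalize()]: lengths in units of a,
#' densities in units of xi_l, stresses in units of xi_l*k_B*Temp/x_b,
#' times in units of mu/E.
#'
#' @param params an \code{npw_params} object
#' @return list with elements \code{lambda} (bond rest length), \code{tau}
#'   (repulsion length), \code{bend} (bending coefficient
#'   B*x_b/(xi_l*kT*a^3)), \code{Efound} (foundation stiffness
#'   E*x_b/(xi_l*kT); the damper has the same coefficient because time is
#'   measured in mu/E), \code{T0} (edge tension), \code{gamma} (repulsion
#'   amplitude), \code{CK} (Bell/bond-stress coefficient kappa*a*x_b/kT),
#'   \code{Kf}, \code{Kd0} (kinetic rates per time unit), \code{xi_r},
#'   \code{Fv}, \code{nu}
#' @keywords internal
#' @export
solver_coefficients <- function(params) {
  p <- params
  kT <- p$k_B * p$Temp
  sigma0 <- p$xi_l * kT / p$x_b
  list(
    lambda = p$lambda / p$a,
    tau    = p$tau / p$a,
    # every stress is measured against the bond stress scale
    # sigma0 = xi_l k_B T / x_b (the stress a fully bound patch exerts at
    # the thermal elongation k_B T/(kappa x_b)); these are the
    # dimensionally consistent reductions of the equilibrium equations
    bend   = p$B / (sigma0 * p$a^3),
    Efound = p$E / sigma0,
    T0     = p$T0 / (sigma0 * p$a),
    gamma  = p$gamma / (sigma0 * p$a^2),
    CK     = p$kappa * p$a * p$x_b / kT,
    Kf     = p$K_f * p$xi_l * p$mu / p$E,
    Kd0    = p$K_d0 * p$mu / p$E,
    xi_r   = p$xi_r / p$xi_l,
    Fv     = p$F_v / (p$a^2 * sigma0),
    nu     = p$nu
  )
}

#' Convert a dimensionless vertical force to Newtons
#'
#' The natural unit for a force applied to the particle is
#' a^2*xi_l*k_B*Temp/x_b, the total bond force a fully coated particle
#' face can sustain at the characteristic thermal elongation.  For a 50 nm
#' particle at the default densities this unit is about 20 pN.
#'
#' @param F_hat dimensionless vertical force (negative = pushing the
#'   particle onto the cell)
#' @param params an \code{npw_params} object
#' @return force in N
#' @export
dimensional_force <- function(F_hat, params) {
  F_hat * params$a^2 * params$xi_l * params$k_B * params$Temp / params$x_b
}

#' Read a parameter configuration from a JSON file
#'
#' Keys are the SI-unit parameter names of [model_parameters()]
#' (\code{a}, \code{xi_l}, \code{xi_r}, \code{kappa}, \code{lambda},
#' \code{gamma}, \code{tau}, \code{K_f}, \code{Kd0_over_Kf}, \code{x_b},
#' \code{T0}, \code{E}, \code{mu}, \code{B}, optionally \code{k_B},
#' \code{Temp}, \code{F_v}, \code{nu}).  Unknown keys are rejected.
#'
#' @param path path to a JSON file
#' @return an \code{npw_params} object
#' @export
read_parameters <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a JSON object", call. = FALSE)
  allowed <- setdiff(names(formals(model_parameters)), "...")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(model_parameters, cfg)
}

#' Write a parameter set to a JSON file
#' @param params an \code{npw_params} object
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_parameters <- function(params, path) {
  keep <- setdiff(names(formals(model_parameters)), "...")
  jsonlite::write_json(params[keep], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
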