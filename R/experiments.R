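# Scripted numerical experiments: single runs with snapshots and
# parameter sweeps over particle radius, bond properties, cell mechanics
# and applied vertical force.  Each experiment returns a plain data.frame
# (one row per run) that is written as CSV by the CLI.

run_one <- function(params, coarse = TRUE, grid = NULL,
                    stop_at_internalization = FALSE, t_max = 60, ...) {
  run_simulation(params, grid = grid, coarse = coarse, t_max = t_max,
                 stop_at_internalization = stop_at_internalization, ...)
}

row_from_run <- function(r, id_cols) {
  if (inherits(r, "error")) {
    return(cbind(id_cols, data.frame(
      internalization_time = NA_real_, max_depth = NA_real_,
      converged = NA, reached_internalization = NA, n_steps = NA_integer_,
      error = conditionMessage(r))))
  }
  cbind(id_cols, data.frame(
    internalization_time = r$internalization_time,
    max_depth = r$max_depth,
    converged = r$converged,
    reached_internalization = r$reached_internalization,
    n_steps = r$n_steps,
    error = NA_character_))
}

#' Sweep the particle radius
#'
#' Runs the full simulation for each radius with all other parameters
#' fixed, recording the internalization time (time to d/(2a) = 1, absent
#' when wrapping saturates below that) and the attained depth.  The
#' internalization time is U-shaped in the radius: bending rigidity
#' penalizes small particles (resistance ~ B/a^3), cytoplasmic elasticity
#' large ones.
#'
#' @param params base \code{npw_params} object
#' @param radii radii to simulate (m)
#' @param coarse use the desk-scale grid (default); set FALSE for the
#'   full production grid
#' @param stop_at_internalization stop runs once d/(2a) reaches 1 (the
#'   depth column is then a lower bound for internalized runs)
#' @param t_max maximum simulated time per run
#' @param verbose print one line per finished run
#' @return data.frame with columns a, internalization_time, max_depth,
#'   converged, reached_internalization, n_steps, error
#' @export
sweep_radius <- function(params, radii = seq(20e-9, 120e-9, by = 10e-9),
                         coarse = TRUE, stop_at_internalization = FALSE,
                         t_max = 60, verbose = FALSE, ...) {
  stopifnot(length(radii) >= 1)
  out <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    pa <- params
    pa$a <- radii[i]
    r <- tryCatch(run_one(pa, coarse = coarse, t_max = t_max,
                          stop_at_internalization = stop_at_internalization,
                          ...),
                  error = function(e) e)
    out[[i]] <- row_from_run(r, data.frame(a = radii[i]))
    if (verbose)
      message(sprintf("a = %g nm: time = %s, depth = %s", radii[i] * 1e9,
                      format(out[[i]]$internalization_time, digits = 4),
                      format(out[[i]]$max_depth, digits = 4)))
  }
  do.call(rbind, out)
}

# Recognized sweep variables and how they modify the parameter set.
apply_sweep_value <- function(params, variable, value) {
  switch(variable,
    kappa = { params$kappa <- value; params },
    Kd0_over_Kf = { params$Kd0_over_Kf <- value
                    params$K_d0 <- value * params$K_f; params },
    xi_l_and_xi_r = { params$xi_l <- value; params$xi_r <- value; params },
    B = { params$B <- value; params },
    T0 = { params$T0 <- value; params },
    E = { params$E <- value; params },
    K_f = { params$K_f <- value
            params$K_d0 <- params$Kd0_over_Kf * value; params },
    F_v = { params$F_v <- value; params },
    stop("unrecognized sweep variable: ", variable, call. = FALSE))
}

#' Sweep a scalar parameter (optionally crossed with radii)
#'
#' Supported variables: \code{kappa}, \code{Kd0_over_Kf},
#' \code{xi_l_and_xi_r} (ligand density with the receptor density tied to
#' it), \code{B}, \code{T0}, \code{E}, \code{K_f}, \code{F_v}.
#'
#' @param params base \code{npw_params} object
#' @param variable variable name (see above)
#' @param values values in SI units
#' @param radii optional radii vector to cross with the values; NULL
#'   keeps the base radius
#' @inheritParams sweep_radius
#' @return data.frame with columns variable, value, a, and the run metrics
#' @export
sweep_scalar <- function(params, variable, values, radii = NULL,
                         coarse = TRUE, stop_at_internalization = FALSE,
                         t_max = 60, verbose = FALSE, ...) {
  stopifnot(length(values) >= 1)
  if (is.null(radii)) radii <- params$a
  grid_rows <- expand.grid(value = values, a = radii)
  out <- vector("list", nrow(grid_rows))
  for (i in seq_len(nrow(grid_rows))) {
    pa <- apply_sweep_value(params, variable, grid_rows$value[i])
    pa$a <- grid_rows$a[i]
    r <- tryCatch(run_one(pa, coarse = coarse, t_max = t_max,
                          stop_at_internalization = stop_at_internalization,
                          ...),
                  error = function(e) e)
    out[[i]] <- row_from_run(r, data.frame(variable = variable,
                                           value = grid_rows$value[i],
                                           a = grid_rows$a[i]))
    if (verbose)
      message(sprintf("%s = %g, a = %g nm: depth = %s", variable,
                      grid_rows$value[i], grid_rows$a[i] * 1e9,
                      format(out[[i]]$max_depth, digits = 4)))
  }
  do.call(rbind, out)
}

#' Vertical-force study
#'
#' Internalization time versus applied nondimensional vertical force at a
#' fixed radius, and versus radius at a fixed force.  Forces are given in
#' the nondimensional unit a^2 xi_l k_B Temp / x_b of the respective run
#' (negative = compressive, pushing the particle onto the cell).
#'
#' @param params base \code{npw_params} object
#' @param F_hats nondimensional forces for the fixed-radius branch
#' @param a_fixed radius for the force branch (m)
#' @param radii radii for the fixed-force branch; NULL skips that branch
#' @param F_hat_fixed force for the radius branch
#' @inheritParams sweep_radius
#' @return data.frame with columns branch, F_hat, a, and run metrics
#' @export
force_study <- function(params, F_hats = c(0, -0.25, -0.5, -1),
                        a_fixed = 50e-9, radii = NULL, F_hat_fixed = -0.5,
                        coarse = TRUE, stop_at_internalization = TRUE,
                        t_max = 60, verbose = FALSE, ...) {
  rows <- list()
  for (fh in F_hats) {
    pa <- params
    pa$a <- a_fixed
    pa$F_v <- dimensional_force(fh, pa)
    r <- tryCatch(run_one(pa, coarse = coarse, t_max = t_max,
                          stop_at_internalization = stop_at_internalization,
                          ...),
                  error = function(e) e)
    rows[[length(rows) + 1L]] <-
      row_from_run(r, data.frame(branch = "force", F_hat = fh, a = a_fixed))
    if (verbose)
      message(sprintf("F_hat = %g: time = %s", fh,
                      format(rows[[length(rows)]]$internalization_time,
                             digits = 4)))
  }
  if (!is.null(radii)) {
    for (a in radii) {
      pa <- params
      pa$a <- a
      pa$F_v <- dimensional_force(F_hat_fixed, pa)
      r <- tryCatch(run_one(pa, coarse = coarse, t_max = t_max,
                            stop_at_internalization = stop_at_internalization,
                            ...),
                    error = function(e) e)
      rows[[length(rows) + 1L]] <-
        row_from_run(r, data.frame(branch = "radius", F_hat = F_hat_fixed,
                                   a = a))
    }
  }
  do.call(rbind, rows)
}

#' Single run with trajectory and snapshots
#'
#' Full simulation returning, besides the run metrics, membrane/bond
#' snapshots at requested times (each snapshot holds the state at the
#' first trajectory point at or after the requested time).
#'
#' @param params an \code{npw_params} object
#' @param snapshot_times times (viscoelastic units) at which to record
#'   snapshots
#' @inheritParams sweep_radius
#' @return an \code{npw_run} with an extra \code{snapshots} element: a
#'   named list of data.frames with columns s, R, Z, theta, Ttens, xi_b,
#'   l, alpha, bond_class
#' @export
run_single <- function(params, snapshot_times = c(5e-3, 1e-2, 2, 10),
                       coarse = TRUE, t_max = 60, verbose = FALSE) {
  grid <- if (coarse) build_grid(params, s_max_factor = 10, coarse = TRUE)
          else build_grid(params)
  snaps <- list()
  pending <- sort(snapshot_times)
  hook <- function(state) {
    while (length(pending) && state$time >= pending[1]) {
      snaps[[sprintf("t=%g", pending[1])]] <<- snapshot_frame(state, grid,
                                                              params)
      pending <<- pending[-1]
    }
  }
  r <- run_simulation(params, grid = grid, t_max = t_max, verbose = verbose,
                      step_hook = hook)
  r$snapshots <- snaps
  r
}

#' Classify bonds by their deformation state
#'
#' Buckets gaps into strongly compressed (l < 0.9 lambda), slightly
#' compressed (0.9 lambda <= l < lambda), slightly stretched
#' (lambda < l <= 1.1 lambda) and strongly stretched (l > 1.1 lambda);
#' bonds exactly at the rest length count as slightly compressed's upper
#' neighbor ("neutral" boundary is assigned to slightly_stretched).
#'
#' @param l gap values
#' @param lambda bond rest length (same units)
#' @return factor with levels strongly_compressed, slightly_compressed,
#'   slightly_stretched, strongly_stretched
#' @export
classify_bonds <- function(l, lambda) {
  cut(l / lambda, breaks = c(-Inf, 0.9, 1, 1.1, Inf),
      labels = c("strongly_compressed", "slightly_compressed",
                 "slightly_stretched", "strongly_stretched"))
}

# Per-node snapshot table of a state (nondimensional fields).
snapshot_frame <- function(state, grid, params) {
  np <- state$np
  dv <- state$Z0 - state$Z
  rr <- pmax(sqrt(state$R^2 + dv^2), 1e-12)
  l <- rr - 1
  data.frame(s = grid$s, R = state$R, Z = state$Z, theta = state$theta,
             Ttens = state$Ttens, xi_b = state$xi_b, l = l,
             alpha = atan2(state$R, dv),
             bond_class = classify_bonds(l, np$lambda),
             time = state$time)
}
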