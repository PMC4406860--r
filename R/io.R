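# Output writers: trajectory and snapshot CSVs, JSON run summaries.

#' Write the run trajectory to CSV
#'
#' Columns: time, dt, Z0, d_over_2a, wrap_angle, total_bonds, max_xi_b
#' (all nondimensional: times in mu/E units, lengths in particle radii,
#' densities in xi_l).
#'
#' @param run an \code{npw_run}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_trajectory <- function(run, path) {
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Write a membrane snapshot to CSV
#'
#' One row per grid node with columns s, R, Z, theta, Ttens, xi_b, l,
#' alpha, bond_class, time (nondimensional units).
#'
#' @param snapshot a snapshot data.frame (see [run_single()])
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_snapshot <- function(snapshot, path) {
  utils::write.csv(snapshot, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary of a run
#'
#' Records internalization_time (NA encoded as null), max_depth,
#' converged, and n_steps.
#'
#' @param run an \code{npw_run}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_run_summary <- function(run, path) {
  jsonlite::write_json(
    list(internalization_time = run$internalization_time,
         max_depth = run$max_depth,
         converged = run$converged,
         reached_internalization = run$reached_internalization,
         n_steps = run$n_steps),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
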