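#' Solve the membrane shape under a given stress model
#'
#' Newton solve of the projected force-balance equations with boundary
#' conditions, for a fixed stress model.  The stress model is either a
#' callable \code{stress_model(R, Z, theta) -> list(sigma_r, sigma_v)}
#' (nondimensional), or \code{NULL} to use the built-in
#' bond + repulsion + Kelvin-Voigt model, in which case \code{xi_b},
#' \code{Z_prev}, \code{dt} and \code{Z0} must be supplied.
#'
#' @param prev membrane state supplying the initial Newton iterate: a list
#'   with fields \code{theta}, \code{Ttens} (and optionally \code{R},
#'   \code{Z}, which are otherwise reconstructed)
#' @param stress_model callable or NULL
#' @param grid an \code{npw_grid}
#' @param params an \code{npw_params} object
#' @param xi_b,Z_prev,dt,Z0 built-in model inputs (nondimensional), used
#'   when \code{stress_model} is NULL
#' @param newton_opts list of options: \code{tol} (residual max-norm
#'   tolerance, default 1e-8), \code{max_iter}, \code{max_halvings}
#' @return membrane state: list with \code{theta}, \code{Ttens}, \code{R},
#'   \code{Z}, \code{Ms}, \code{Mtheta}, \code{V}, \code{iterations},
#'   \code{residual_norm}
#' @export
solve_shape <- function(prev, stress_model, grid, params,
                        xi_b = NULL, Z_prev = NULL, dt = NULL, Z0 = NULL,
                        newton_opts = list()) {
  np <- if (inherits(params, "npw_params")) solver_coefficients(params)
        else params
  n <- grid$n
  theta <- prev$theta
  Ttens <- prev$Ttens
  if (is.null(prev$R) || is.null(prev$Z)) {
    sh <- reconstruct_shape(theta, grid)
    prev$R <- sh$R; prev$Z <- sh$Z
  }
  sys <- list(grid = grid, np = np, joint = FALSE,
              stress_fn = stress_model,
              xi_b = xi_b, Z_prev = Z_prev, dt = dt, Z0_fixed = Z0)
  if (is.null(stress_model) &&
      (is.null(xi_b) || is.null(Z_prev) || is.null(dt) || is.null(Z0)))
    stop("built-in stress model needs xi_b, Z_prev, dt and Z0",
         call. = FALSE)
  opts <- utils::modifyList(list(tol = 1e-8, max_iter = 40L,
                                 max_halvings = 8L), newton_opts)
  if (is.null(prev$p) || is.null(prev$q)) {
    pq <- derive_pq(theta, grid)
    prev$p <- pq$p; prev$q <- pq$q
  }
  x0 <- pack_state(theta, prev$p, prev$q, Ttens, prev$R, prev$Z)
  sol <- newton_solve(x0, sys, tol = opts$tol, max_iter = opts$max_iter,
                      max_halvings = opts$max_halvings)
  st <- unpack_state(sol$x, n, FALSE)
  mom <- internal_resultants(st$theta, grid, np$nu, np$bend)
  c(st[c("theta", "p", "q", "Ttens", "R", "Z")], mom,
    list(iterations = sol$iterations, residual_norm = sol$residual_norm))
}
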