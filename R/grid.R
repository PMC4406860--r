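#' Build the nonuniform arc-length grid
#'
#' The membrane is discretized in material arc length s (in units of the
#' particle radius a).  The local spacing follows
#' \deqn{\Delta s = \Delta s_0 / g(s), \quad g(s) = 1 + 10 e^{-s^2/2},}
#' which concentrates nodes under the particle: the spacing is about ten
#' times finer at the center (\eqn{\Delta s(0) = \Delta s_0/11}) than at
#' the far edge (\eqn{\Delta s \to \Delta s_0}).  The default base spacing
#' is \eqn{\Delta s_0 = 0.04} and the default domain extends to s_max = 20
#' particle radii, beyond which further enlargement does not change the
#' results.
#'
#' @param params an \code{npw_params} object (only used to record a); may
#'   be NULL for a purely nondimensional grid
#' @param s_max_factor outer edge position in particle radii (>= 5)
#' @param coarse logical; if TRUE use the fast desk-scale grid (base
#'   spacing doubled to 0.08 and s_max halved to 10 radii)
#' @param ds0 base spacing override (in particle radii)
#' @return object of class \code{npw_grid}: list with \code{s} (nodes),
#'   \code{n} (node count), \code{ds} (interval widths), \code{s_max},
#'   \code{wq} (trapezoidal quadrature weights), and the sparse derivative
#'   operators \code{D1}, \code{D2}, \code{D3} (five-point) and \code{D1c}
#'   (three-point) used by the membrane solver
#' @export
build_grid <- function(params = NULL, s_max_factor = 20, coarse = FALSE,
                       ds0 = NULL) {
  if (!is.numeric(s_max_factor) || length(s_max_factor) != 1L ||
      s_max_factor < 5)
    stop("s_max_factor must be a single number >= 5", call. = FALSE)
  if (is.null(ds0)) ds0 <- if (coarse) 0.08 else 0.04
  if (coarse && missing(s_max_factor)) s_max_factor <- 10
  g <- function(s) 1 + 10 * exp(-s^2 / 2)
  s <- 0
  nodes <- numeric(4096)
  nodes[1] <- 0
  k <- 1L
  while (s < s_max_factor) {
    h <- ds0 / g(s)
    s <- s + h
    k <- k + 1L
    if (k > length(nodes)) nodes <- c(nodes, numeric(length(nodes)))
    nodes[k] <- s
  }
  nodes <- nodes[seq_len(k)]
  # land exactly on s_max: rescale the last interval onto the boundary
  nodes[k] <- s_max_factor
  if (k >= 2 && (nodes[k] - nodes[k - 1]) < 0.25 * ds0 / g(nodes[k])) {
    nodes <- nodes[-(k - 1L)]
    k <- k - 1L
  }
  grid <- list(s = nodes, n = k, ds = diff(nodes), s_max = s_max_factor,
               wq = trapz_weights(nodes),
               a = if (is.null(params)) NA_real_ else params$a,
               coarse = coarse, ds0 = ds0)
  grid$D1  <- fd_operator(nodes, 1L, 5L)
  grid$D2  <- fd_operator(nodes, 2L, 5L)
  grid$D3  <- fd_operator(nodes, 3L, 5L)
  grid$D1c <- fd_operator(nodes, 1L, 3L)
  class(grid) <- "npw_grid"
  grid
}

#' @export
print.npw_grid <- function(x, ...) {
  cat(sprintf("Arc-length grid: %d nodes on [0, %g] radii, ds %g..%g%s\n",
              x$n, x$s_max, min(x$ds), max(x$ds),
              if (isTRUE(x$coarse)) " (coarse)" else ""))
  invisible(x)
}
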