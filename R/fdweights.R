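# Finite-difference machinery for the nonuniform arc-length grid.

#' Finite-difference weights on arbitrary nodes (Fornberg recursion)
#'
#' Weights w such that sum(w * f(x)) approximates the m-th derivative of f
#' at x0, for any set of distinct nodes x.
#'
#' @param x0 evaluation point
#' @param x node positions (length >= m + 1)
#' @param m derivative order (0 = interpolation)
#' @return matrix (m + 1) x length(x); row k + 1 holds the weights for the
#'   k-th derivative
#' @keywords internal
fd_weights <- function(x0, x, m) {
  n <- length(x)
  stopifnot(n >= m + 1L)
  C <- matrix(0, nrow = m + 1L, ncol = n)
  c1 <- 1
  c4 <- x[1] - x0
  C[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1L, m)
    c2 <- 1
    c5 <- c4
    c4 <- x[i] - x0
    for (j in 1:(i - 1L)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1L) {
        if (mn >= 1) {
          for (k in mn:1) {
            C[k + 1L, i] <- c1 * (k * C[k, i - 1L] - c5 * C[k + 1L, i - 1L]) / c2
          }
        }
        C[1, i] <- -c1 * c5 * C[1, i - 1L] / c2
      }
      if (mn >= 1) {
        for (k in mn:1) {
          C[k + 1L, j] <- (c4 * C[k + 1L, j] - k * C[k, j]) / c3
        }
      }
      C[1, j] <- c4 * C[1, j] / c3
    }
    c1 <- c2
  }
  C
}

# Sparse derivative operator of order `ord` on nodes `s`, using a sliding
# stencil of `np` points (centered in the interior, one-sided at the ends).
# Returns a dgCMatrix D with (D %*% f)[i] ~ f^(ord)(s[i]).
fd_operator <- function(s, ord, np) {
  n <- length(s)
  stopifnot(np >= ord + 1L, n >= np)
  half <- (np - 1L) %/% 2L
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (i in seq_len(n)) {
    j0 <- min(max(i - half, 1L), n - np + 1L)
    idx <- j0:(j0 + np - 1L)
    w <- fd_weights(s[i], s[idx], ord)[ord + 1L, ]
    ii <- c(ii, rep.int(i, np)); jj <- c(jj, idx); vv <- c(vv, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

# Trapezoidal quadrature weights on nonuniform nodes.
trapz_weights <- function(s) {
  n <- length(s)
  ds <- diff(s)
  w <- numeric(n)
  w[1] <- ds[1] / 2
  w[n] <- ds[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (ds[-(n - 1)] + ds[-1]) / 2
  w
}

# Cumulative trapezoidal integral from s[1].
cumtrapz <- function(s, f) {
  c(0, cumsum(diff(s) * (f[-length(f)] + f[-1]) / 2))
}
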