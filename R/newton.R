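# Monolithic implicit solve of the membrane shape + particle position at
# one time instant, with the bond density field frozen.
#
# The equilibrium equations are integrated as a first-order (Keller box)
# system.  Solving the pair (radial, vertical) of projected force balances
# for the highest derivatives -- the combination
#   cos(theta)*Eq_r + sin(theta)*Eq_v  gives  T',
#   cos(theta)*Eq_v - sin(theta)*Eq_r  gives  B theta'''
# with determinant -B, always invertible -- yields the explicit system
#   theta' = p,  p' = q,  q' = f_q,  T' = f_T,  R' = cos(theta),
#   Z' = sin(theta),
# discretized at cell midpoints with compact two-point stencils (no
# spurious odd-even modes, second order on the graded mesh).
#
# Unknown vector, interleaved per node:
#   x = (theta, p, q, T, R, Z)_1, ..., (theta, p, q, T, R, Z)_n [, Z0]
# Rows: 3 axis conditions (theta = 0, theta'' = 0, R = 0), 6 equations per
# interval, 3 edge conditions (Z = 0, Ms = 0, T cos(theta) - V sin(theta)
# = T0) [, vertical force balance on the particle].  The shape rows are
# block bidiagonal; the particle row/column make the matrix an arrow
# matrix, which sparse LU handles with negligible fill-in.

.nvar <- 6L

# The compiled residual is used whenever the package is built with it;
# the R implementation below is the reference (and the only path for a
# user-supplied stress model).
.npw_has_compiled <- function() {
  exists("npw_residual_cpp", mode = "function")
}

idx_var <- function(n, v) .nvar * (seq_len(n) - 1L) + v
idx_th <- function(n) idx_var(n, 1L)
idx_p  <- function(n) idx_var(n, 2L)
idx_q  <- function(n) idx_var(n, 3L)
idx_T  <- function(n) idx_var(n, 4L)
idx_R  <- function(n) idx_var(n, 5L)
idx_Z  <- function(n) idx_var(n, 6L)

pack_state <- function(theta, p, q, Ttens, R, Z, Z0 = NULL) {
  x <- as.numeric(rbind(theta, p, q, Ttens, R, Z))
  if (!is.null(Z0)) x <- c(x, Z0)
  x
}

unpack_state <- function(x, n, joint) {
  list(theta = x[idx_th(n)], p = x[idx_p(n)], q = x[idx_q(n)],
       Ttens = x[idx_T(n)], R = x[idx_R(n)], Z = x[idx_Z(n)],
       Z0 = if (joint) x[.nvar * n + 1L] else NULL)
}

# Derivative slopes p = theta', q = theta'' consistent with the grid, used
# to seed the Newton iterate from a (theta, T) state.
derive_pq <- function(theta, grid) {
  list(p = as.numeric(grid$D1 %*% theta),
       q = as.numeric(grid$D2 %*% theta))
}

# Midpoint right-hand sides f_T, f_q of the first-order system, plus the
# kinematic slopes.  All arguments are midpoint values.
box_rhs <- function(th, p, q, Tt, R, Z, sigma_r, sigma_v, bend) {
  r <- pmax(R, 1e-9)
  sn <- sin(th); cs <- cos(th)
  s2 <- sn * sn; c2 <- cs * cs
  A0 <- -Tt * sn * p - Tt * s2 / r +
    bend * (2 * sn * cs / r * q + cs * p * q + (c2 - s2) / r * p^2 +
              sn * (s2 - 2 * c2) / r^2 * p + s2 * c2 / r^3) + sigma_r
  B0 <- Tt * cs * p + Tt * sn * cs / r +
    bend * (-2 * c2 / r * q + sn * p * q + 2 * sn * cs / r * p^2 +
              cs * (c2 - 2 * s2) / r^2 * p - sn * c2 * cs / r^3) + sigma_v
  list(fT = -(cs * A0 + sn * B0),
       fq = (cs * B0 - sn * A0) / bend)
}

# Bond + repulsion + Kelvin-Voigt stresses at given geometry points.
model_stresses <- function(R, Z, th, xi, Z_prev, dt, Z0, np) {
  dv <- Z0 - Z
  rr <- pmax(sqrt(R^2 + dv^2), 1e-9)
  l <- rr - 1
  sina <- R / rr
  cosa <- dv / rr
  net <- np$CK * xi * (l - np$lambda) - rep_and_slope(l, np)$f
  list(sigma_r = -net * sina,
       sigma_v = -np$Efound * (Z + (Z - Z_prev) / dt) * cos(th) + net * cosa,
       net = net, cosa = cosa, l = l)
}

# sys: list(grid, np, xi_b, Z_prev, dt, joint, Z0_fixed, stress_fn)
# stress_fn (optional) replaces the bond + repulsion + cytoplasm model:
# function(R, Z, theta) -> list(sigma_r, sigma_v), evaluated at midpoints.
coupled_residual <- function(x, sys) {
  grid <- sys$grid; np <- sys$np; n <- grid$n
  if (is.null(sys$stress_fn) && !isTRUE(sys$force_r) && .npw_has_compiled()) {
    return(npw_residual_cpp(x, n, grid$ds, grid$wq, sys$xi_b, sys$Z_prev,
                            sys$dt, np, sys$joint,
                            if (sys$joint) 0 else sys$Z0_fixed,
                            if (is.null(sys$ptc_eps)) 0 else sys$ptc_eps,
                            if (is.null(sys$theta_prev)) numeric(n)
                            else sys$theta_prev))
  }
  st <- unpack_state(x, n, sys$joint)
  theta <- st$theta; p <- st$p; q <- st$q
  Ttens <- st$Ttens; R <- st$R; Z <- st$Z
  Z0 <- if (sys$joint) st$Z0 else sys$Z0_fixed
  i <- seq_len(n - 1L)
  ds <- grid$ds
  mid <- function(f) (f[i] + f[i + 1L]) / 2
  dd <- function(f) (f[i + 1L] - f[i]) / ds
  thm <- mid(theta); pm <- mid(p); qm <- mid(q)
  Tm <- mid(Ttens); Rm <- mid(R); Zm <- mid(Z)
  if (is.null(sys$stress_fn)) {
    sf <- model_stresses(Rm, Zm, thm, mid(sys$xi_b), mid(sys$Z_prev),
                         sys$dt, Z0, np)
  } else {
    sf <- sys$stress_fn(Rm, Zm, thm)
  }
  rhs <- box_rhs(thm, pm, qm, Tm, Rm, Zm, sf$sigma_r, sf$sigma_v, np$bend)
  res <- numeric(if (sys$joint) .nvar * n + 1L else .nvar * n)
  # axis rows
  res[1L] <- theta[1L]
  res[2L] <- q[1L]
  res[3L] <- R[1L]
  # interval rows, 6 per interval, rows 6(i-1)+4 .. 6i+3
  base <- .nvar * (i - 1L) + 3L
  res[base + 1L] <- dd(theta) - pm
  res[base + 2L] <- dd(p) - qm
  res[base + 3L] <- dd(q) - rhs$fq
  if (!is.null(sys$ptc_eps) && sys$ptc_eps > 0) {
    # pseudo-transient rotational dashpot (solver continuation aid only)
    thpm <- (sys$theta_prev[i] + sys$theta_prev[i + 1L]) / 2
    res[base + 3L] <- res[base + 3L] +
      sys$ptc_eps * (thm - thpm) / sys$dt / np$bend
  }
  res[base + 4L] <- dd(Ttens) - rhs$fT
  res[base + 5L] <- dd(R) - cos(thm)
  res[base + 6L] <- dd(Z) - sin(thm)
  # edge rows
  rn <- max(R[n], 1e-9)
  snn <- sin(theta[n]); csn <- cos(theta[n])
  res[.nvar * n - 2L] <- Z[n]
  res[.nvar * n - 1L] <- p[n] + np$nu * snn / rn
  Vn <- -np$bend * (q[n] + csn * p[n] / rn - snn * csn / rn^2)
  res[.nvar * n] <- Ttens[n] * csn - Vn * snn - np$T0
  if (sys$joint) {
    sfn <- model_stresses(R, Z, theta, sys$xi_b, sys$Z_prev, sys$dt, Z0, np)
    h <- sfn$net * sfn$cosa * 2 * pi * R * cos(theta)
    res[.nvar * n + 1L] <- np$Fv - sum(grid$wq * h)
  }
  res
}

# Analytic gradient of the particle-balance row with respect to all
# unknowns (that row is dense and cannot be recovered from colored finite
# differences).
particle_row_grad <- function(x, sys) {
  grid <- sys$grid; np <- sys$np; n <- grid$n
  st <- unpack_state(x, n, TRUE)
  R <- st$R; Z <- st$Z; theta <- st$theta; Z0 <- st$Z0
  dv <- Z0 - Z
  rr <- pmax(sqrt(R^2 + dv^2), 1e-9)
  l <- rr - 1
  sina <- R / rr
  cosa <- dv / rr
  rp <- rep_and_slope(l, np)
  net <- np$CK * sys$xi_b * (l - np$lambda) - rp$f
  dnet_dl <- np$CK * sys$xi_b - rp$fp
  cth <- cos(theta); sth <- sin(theta)
  w <- grid$wq * 2 * pi
  dh_dth <- -w * net * cosa * R * sth
  dcosa_dR <- -dv * R / rr^3
  dh_dR <- w * cth * (dnet_dl * sina * cosa * R + net * dcosa_dR * R +
                        net * cosa)
  dcosa_dZ <- -R^2 / rr^3
  dh_dZ <- w * cth * R * (dnet_dl * (-cosa) * cosa + net * dcosa_dZ)
  g <- numeric(.nvar * n + 1L)
  g[idx_th(n)] <- -dh_dth
  g[idx_R(n)] <- -dh_dR
  g[idx_Z(n)] <- -dh_dZ
  g[.nvar * n + 1L] <- sum(dh_dZ) # Z0 enters as -Z does
  g
}

# Package-local cache of sparsity patterns and colorings, keyed by grid
# size (the pattern depends only on n).
.npw_cache <- new.env(parent = emptyenv())

coupled_pattern <- function(grid) {
  key <- sprintf("pat6_%d", grid$n)
  hit <- get0(key, envir = .npw_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  n <- grid$n
  nv <- .nvar
  # interval rows couple all 12 unknowns of nodes i, i+1
  i <- seq_len(n - 1L)
  row_int <- rep(nv * (i - 1L) + 3L, each = 6L * 2L * nv) +
    rep(rep(1:6, each = 2L * nv), times = n - 1L)
  col_int <- rep(nv * (i - 1L), each = 6L * 2L * nv) +
    rep(rep(seq_len(2L * nv), times = 6L), times = n - 1L)
  ii <- c(1L, 2L, 3L, row_int,
          rep(nv * n - 2L, 1L), rep(nv * n - 1L, nv), rep(nv * n, nv))
  jj <- c(1L, 3L, 5L, col_int,
          nv * n, nv * (n - 1L) + seq_len(nv), nv * (n - 1L) + seq_len(nv))
  rows_by_col <- split(ii, factor(jj, levels = seq_len(nv * n)))
  rows_by_col <- lapply(rows_by_col, unique)
  cols_by_row <- split(jj, factor(ii, levels = seq_len(nv * n)))
  cols_by_row <- lapply(cols_by_row, unique)
  color <- integer(nv * n)
  for (j in seq_len(nv * n)) {
    neigh <- unlist(cols_by_row[rows_by_col[[j]]], use.names = FALSE)
    used <- color[neigh]
    c0 <- 1L
    while (any(used == c0)) c0 <- c0 + 1L
    color[j] <- c0
  }
  ncolor <- max(color)
  groups <- vector("list", ncolor)
  for (cl in seq_len(ncolor)) {
    cols <- which(color == cl)
    rl <- rows_by_col[cols]
    len <- lengths(rl)
    groups[[cl]] <- list(
      cols = cols,
      rows_cat = unlist(rl, use.names = FALSE),
      cols_cat = rep.int(cols, len),
      colrep = rep.int(seq_along(cols), len))
  }
  pat <- list(groups = groups, ncolor = ncolor)
  assign(key, pat, envir = .npw_cache)
  pat
}

# Finite-difference Jacobian via the column coloring; particle row and Z0
# column (joint mode) filled analytically / by a dedicated perturbation.
coupled_jacobian <- function(x, res0, sys, pat) {
  n <- sys$grid$n
  m <- length(x)
  nsh <- .nvar * n
  epsb <- 1e-7
  nc <- pat$ncolor
  iiL <- vector("list", nc + 2L); jjL <- vector("list", nc + 2L)
  vvL <- vector("list", nc + 2L)
  for (cl in seq_len(nc)) {
    g <- pat$groups[[cl]]
    eps <- epsb * pmax(1, abs(x[g$cols]))
    x2 <- x
    x2[g$cols] <- x2[g$cols] + eps
    d <- coupled_residual(x2, sys) - res0
    iiL[[cl]] <- g$rows_cat
    jjL[[cl]] <- g$cols_cat
    vvL[[cl]] <- d[g$rows_cat] / eps[g$colrep]
  }
  if (sys$joint) {
    eps <- epsb * max(1, abs(x[m]))
    x2 <- x; x2[m] <- x2[m] + eps
    d <- (coupled_residual(x2, sys) - res0) / eps
    nz <- which(d != 0)
    nz <- nz[nz <= nsh]
    iiL[[nc + 1L]] <- nz
    jjL[[nc + 1L]] <- rep.int(m, length(nz))
    vvL[[nc + 1L]] <- d[nz]
    gr <- particle_row_grad(x, sys)
    nzr <- union(which(gr != 0), m)
    iiL[[nc + 2L]] <- rep.int(nsh + 1L, length(nzr))
    jjL[[nc + 2L]] <- nzr
    vvL[[nc + 2L]] <- gr[nzr]
  }
  Matrix::sparseMatrix(i = unlist(iiL, use.names = FALSE),
                       j = unlist(jjL, use.names = FALSE),
                       x = unlist(vvL, use.names = FALSE),
                       dims = c(m, m))
}

# Row-wise maximum absolute value of a sparse matrix.
apply_abs_rowmax <- function(J) {
  Tm <- methods::as(J, "TsparseMatrix")
  rmax <- numeric(nrow(J))
  ag <- tapply(abs(Tm@x), Tm@i, max)
  rmax[as.integer(names(ag)) + 1L] <- as.numeric(ag)
  rmax
}

# Damped (step-halving) Newton iteration with Jacobian reuse.  Returns the
# solution vector plus diagnostics; errors on non-convergence with the
# residual-norm history attached.
newton_solve <- function(x0, sys, tol = 1e-9, tol_particle = 1e-10,
                         tol_stagnation = 1e-6, max_iter = 40L,
                         max_halvings = 8L, cache = NULL,
                         careful = FALSE) {
  pat <- coupled_pattern(sys$grid)
  x <- x0
  res <- coupled_residual(x, sys)
  m <- length(x)
  normfun <- function(r) max(abs(r))
  hist <- normfun(res)
  luJ <- NULL
  rscale <- NULL
  J_fresh <- FALSE
  # warm start from the factorization of a nearby state (previous time
  # step); a stale Jacobian that fails to contract is refreshed below
  if (!is.null(cache) && !is.null(cache$luJ) &&
      identical(cache$m, m)) {
    luJ <- cache$luJ
    rscale <- cache$rscale
  }
  conv <- function(r) {
    ok <- normfun(r[seq_len(.nvar * sys$grid$n)]) < tol
    if (sys$joint) ok <- ok && abs(r[m]) < tol_particle
    ok
  }
  # stagnation acceptance: the implicit damper row scales as 1/dt, so the
  # attainable residual floor rises in stiff steps; a stalled iterate well
  # below the physical stress scale is a converged solution
  stag_ok <- function(r) {
    ok <- normfun(r[seq_len(.nvar * sys$grid$n)]) < tol_stagnation
    if (sys$joint) ok <- ok && abs(r[m]) < max(1e-8, 0.01 * tol_stagnation)
    ok
  }
  stag_count <- 0L
  for (it in seq_len(max_iter)) {
    if (conv(res)) {
      return(list(x = x, iterations = it - 1L, residual_norm = normfun(res),
                  history = hist))
    }
    if (is.null(luJ)) {
      J <- coupled_jacobian(x, res, sys, pat)
      # row equilibration keeps the LU pivoting well conditioned despite
      # the mixed row scales (1/ds kinematics vs O(1) stresses)
      rscale <- 1 / pmax(apply_abs_rowmax(J), 1e-300)
      luJ <- Matrix::lu(Matrix::Diagonal(x = rscale) %*% J)
      J_fresh <- TRUE
      if (!is.null(cache)) { cache$luJ <- luJ; cache$rscale <- rscale
                             cache$m <- m }
    }
    dx <- as.numeric(Matrix::solve(luJ, -res * rscale))
    stepped <- FALSE
    tstep <- 1
    r0 <- normfun(res)
    if (careful) {
      # exhaustive backtracking: evaluate the whole step ladder and keep
      # the best candidate (more robust near folds than first-improvement)
      best <- r0; bestx <- NULL; bestres <- NULL
      tt <- 1
      for (h in 0:max_halvings) {
        res_try <- coupled_residual(x + tt * dx, sys)
        nr <- normfun(res_try)
        if (all(is.finite(res_try)) && nr < best) {
          best <- nr; bestx <- x + tt * dx; bestres <- res_try; tstep <- tt
        }
        tt <- tt / 2
      }
      if (!is.null(bestx)) {
        x <- bestx; res <- bestres; stepped <- TRUE
      }
    } else {
      for (h in 0:max_halvings) {
        x_try <- x + tstep * dx
        res_try <- coupled_residual(x_try, sys)
        if (all(is.finite(res_try)) && (normfun(res_try) < r0 || conv(res_try))) {
          x <- x_try; res <- res_try; stepped <- TRUE
          break
        }
        tstep <- tstep / 2
      }
    }
    hist <- c(hist, normfun(res))
    if (stepped) {
      stag_count <- if (normfun(res) > 0.5 * r0) stag_count + 1L else 0L
      if (stag_count >= 2L && stag_ok(res)) {
        return(list(x = x, iterations = it, residual_norm = normfun(res),
                    history = hist, stagnated = TRUE))
      }
    }
    if (!stepped) {
      if (!J_fresh) { luJ <- NULL; next } # retry with a fresh Jacobian
      if (stag_ok(res)) {
        return(list(x = x, iterations = it, residual_norm = normfun(res),
                    history = hist, stagnated = TRUE))
      }
      err <- simpleError(sprintf(
        "Newton iteration failed to reduce the residual (norm %.3e after %d iterations)",
        r0, it))
      err$history <- hist
      stop(err)
    }
    # reuse the factorization while convergence is fast
    if (careful || tstep < 1 || normfun(res) > 0.2 * r0) luJ <- NULL
    J_fresh <- FALSE
  }
  if (conv(res) || stag_ok(res)) {
    return(list(x = x, iterations = max_iter, residual_norm = normfun(res),
                history = hist, stagnated = !conv(res)))
  }
  err <- simpleError(sprintf(
    "Newton did not converge in %d iterations (residual norm %.3e)",
    max_iter, normfun(res)))
  err$history <- hist
  stop(err)
}
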