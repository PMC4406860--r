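# Time integration of the coupled membrane / bond / particle system.
#
# Operator splitting per step (the kinetics first, then the mechanics):
#   1. advance the bond density analytically with the geometry frozen at
#      time t;
#   2. solve the membrane shape, tension and particle elevation implicitly
#      (one monolithic damped Newton over theta, T, R, Z, Z0) with the
#      updated bond field, the Kelvin-Voigt damper discretized backward
#      Euler against the shape at time t.
# The step size adapts so that no node's bond density changes by more than
# 2% (relative) or 0.02 xi_l (absolute) per step.

.dt_max <- 0.05       # cap on the time step (viscoelastic time units)
.dt_min <- 1e-12      # underflow guard (Newton-driven halving)
.dt_floor_bond <- 1e-7 # backstop for the bond-change criterion
.xi_rel_floor <- 1e-3 # density floor for the relative change criterion
.max_snaps <- 25L     # snap-through traversals allowed per run before the
                      # front counts as arrested (bounds worst-case cost)
.wiggle_cap <- 0.35   # max second difference of theta [rad] accepted from
                      # an implicit solve (mesh-scale oscillation guard; a
                      # resolved sharp neck stays well below this, a
                      # spurious oscillatory branch far above)

# mesh-scale oscillation measure of an inclination field
theta_wiggle <- function(th) max(abs(diff(diff(th))))

#' Initial simulation state
#'
#' Flat membrane (theta = 0, T = T0, R = s, Z = 0), the particle resting
#' at one bond length above it (Z0 = a + lambda, so that the apex bond is
#' exactly at rest), and a weak triangular seed bond distribution
#' xi_b(s, 0) = 0.01 xi_l (1 - 5 s/a) for s < 0.2 a.  The precise seed
#' shape is immaterial: bond formation at early times is so fast that the
#' field forgets it almost immediately.
#'
#' @param params an \code{npw_params} object
#' @param grid an \code{npw_grid}
#' @return list of class \code{npw_state} with fields \code{time},
#'   \code{theta}, \code{Ttens}, \code{R}, \code{Z}, \code{xi_b},
#'   \code{Z0}, \code{Z_prev}, \code{dt_prev}
#' @export
initialize_state <- function(params, grid) {
  np <- if (inherits(params, "npw_params")) solver_coefficients(params)
        else params
  n <- grid$n
  st <- list(
    time = 0,
    theta = numeric(n),
    p = numeric(n),
    q = numeric(n),
    Ttens = rep(np$T0, n),
    R = grid$s,
    Z = numeric(n),
    xi_b = pmax(0.01 * (1 - 5 * grid$s), 0),
    Z0 = 1 + np$lambda,
    Z_prev = numeric(n),
    dt_prev = 1e-6,
    np = np)
  if (np$Fv != 0) {
    # the particle balance is an algebraic constraint that must also hold
    # at t = 0: under an applied force the particle starts at the
    # elevation where the seed bonds and the contact repulsion carry it
    mem <- list(theta = st$theta, R = st$R, Z = st$Z)
    st$Z0 <- solve_particle_position(st$Z0, mem, st$xi_b, np, grid)$Z0
  }
  class(st) <- "npw_state"
  st
}

# Gap field for the current state geometry.
state_gap <- function(state) {
  pmax(sqrt(state$R^2 + (state$Z0 - state$Z)^2) - 1, .l_floor)
}

#' Adaptive time step from the bond-change criterion
#'
#' Chooses the largest dt <= 2 dt_prev (and <= 0.05 time units) such that
#' the closed-form bond update, with the geometry frozen, changes no
#' node's density by more than 2% of its local value (with a small floor
#' of 1e-4 xi_l on the reference density) nor by more than 0.02 xi_l.
#' Halves and retries while the trial step violates the thresholds.
#'
#' @param state an \code{npw_state}
#' @param params an \code{npw_params} object (or coefficient list)
#' @param dt_prev previous step size (time units)
#' @return dt (time units)
#' @export
choose_time_step <- function(state, params, dt_prev = state$dt_prev) {
  np <- if (inherits(params, "npw_params")) solver_coefficients(params)
        else params
  stopifnot(dt_prev > 0)
  l <- state_gap(state)
  Kd <- kd_hat(l, np)
  dt <- min(2 * dt_prev, .dt_max)
  repeat {
    xi_new <- riccati_advance(state$xi_b, 1, np$xi_r, np$Kf, Kd, dt)
    dxi <- xi_new - state$xi_b
    allowed <- pmin(0.02 * pmax(state$xi_b, .xi_rel_floor), 0.02)
    # the thresholds resolve the bond-formation front; bonds being expelled
    # from the contact zone decay at the Bell rate (up to e^(C_K dl), many
    # orders above every other rate) and are integrated exactly by the
    # closed form, so shrinking densities do not limit the step
    if (all(dxi <= allowed) || dt <= .dt_floor_bond) return(max(dt, .dt_floor_bond))
    dt <- dt / 2
  }
}

#' Advance the simulation by one time step
#'
#' Bond update (closed form, frozen geometry) followed by the implicit
#' joint solve of membrane shape and particle elevation.  If the Newton
#' iteration fails, the step is retried with a halved dt.
#'
#' @param state an \code{npw_state}
#' @param params an \code{npw_params} object (or coefficient list)
#' @param grid an \code{npw_grid}
#' @param dt optional imposed step; by default [choose_time_step()]
#' @return updated \code{npw_state}
#' @export
step <- function(state, params, grid, dt = NULL) {
  np <- state$np
  if (is.null(np))
    np <- if (inherits(params, "npw_params")) solver_coefficients(params)
          else params
  imposed <- !is.null(dt)
  if (!imposed) dt <- choose_time_step(state, np)
  l <- state_gap(state)
  Kd <- kd_hat(l, np)
  attempts <- 0L
  wig_prev <- theta_wiggle(state$theta)
  repeat {
    xi_new <- riccati_advance(state$xi_b, 1, np$xi_r, np$Kf, Kd, dt)
    sys <- list(grid = grid, np = np, joint = TRUE, stress_fn = NULL,
                xi_b = xi_new, Z_prev = state$Z, dt = dt)
    x0 <- pack_state(state$theta, state$p, state$q, state$Ttens,
                     state$R, state$Z, state$Z0)
    if (is.null(state$cache)) state$cache <- new.env(parent = emptyenv())
    # once dt has been driven very small, a stagnated iterate is accepted
    # at a looser residual bound: through the damper, a residual r at step
    # dt displaces the solution by only r*dt/Efound (< 1e-9 length units
    # here), while refusing it would deadlock the integration when the
    # discrete wrapping front sits between two grid nodes
    stag <- if (dt < 1e-8 && isTRUE(getOption("npwrap.loose_stagnation",
                                              FALSE))) 1e-3 else 1e-6
    sol <- tryCatch(newton_solve(x0, sys, tol_stagnation = stag,
                                 cache = state$cache),
                    error = function(e) e)
    if (!inherits(sol, "error")) {
      # guard against snap-through onto a spurious oscillatory branch:
      # near a fold of the smooth equilibrium the Newton iteration can
      # converge to a mesh-scale-oscillatory solution; such a branch is
      # recognizable by node-to-node curvature oscillations far above
      # anything the resolved physics produces
      th_new <- sol$x[idx_th(grid$n)]
      if (theta_wiggle(th_new) <= max(.wiggle_cap, wig_prev + 0.02)) break
    }
    if (dt <= 4 * .dt_floor_bond) {
      # the smooth branch has folded (snap-through of the wrapping
      # front); traverse it by pseudo-transient continuation, and only
      # if no smooth post-snap solution exists either, report the state
      # as terminal (wrapping arrested)
      n_snaps <- if (is.null(state$n_snaps)) 0L else state$n_snaps
      cap <- if (is.null(state$max_snaps)) .max_snaps else state$max_snaps
      if (n_snaps < cap) {
        for (try in list(c(1e-4, 0.3), c(3e-4, 1), c(1e-4, 0.03))) {
          snap <- traverse_snap(state, np, grid, dt_e = try[1],
                                eps_run = try[2])
          # a traversal that does not move the particle means the front
          # is truly stuck at the fold: arrest instead of spinning
          if (!is.null(snap) && abs(snap$Z0 - state$Z0) >= 1e-6) {
            snap$n_snaps <- n_snaps + 1L
            return(snap)
          }
        }
      }
      state$arrested <- TRUE
      state$time <- state$time + dt
      return(state)
    }
    attempts <- attempts + 1L
    dt <- dt / 2
    if (dt < .dt_min || attempts > 60L) {
      if (inherits(sol, "error"))
        stop(sprintf("implicit solve failed at t = %.6g: %s",
                     state$time, conditionMessage(sol)), call. = FALSE)
      stop(sprintf("implicit solve failed at t = %.6g: no smooth branch",
                   state$time), call. = FALSE)
    }
  }
  stnew <- unpack_state(sol$x, grid$n, TRUE)
  state$Z_prev <- state$Z
  state$theta <- stnew$theta
  state$p <- stnew$p
  state$q <- stnew$q
  state$Ttens <- stnew$Ttens
  state$R <- stnew$R
  state$Z <- stnew$Z
  state$Z0 <- stnew$Z0
  state$xi_b <- xi_new
  state$time <- state$time + dt
  state$dt_prev <- dt
  state$newton_iterations <- sol$iterations
  state$np <- np
  state
}

# Traverse a fold (snap-through) of the smooth equilibrium branch.  The
# snap is integrated as a short damped episode: implicit micro-steps with
# a rotational dashpot of strength eps*Efound added to the bending
# equation let the fast reconfiguration play out at a resolvable rate.
# The episode itself is solver scaffolding -- the state actually accepted
# is one exact (dashpot-free) implicit step over the whole episode
# duration, solved from the episode endpoint as the initial guess, so the
# recorded trajectory always satisfies the unmodified equations.
traverse_snap <- function(state, np, grid, dt_e = 1e-4, eps_run = 0.3,
                          max_episode = 60L) {
  n <- grid$n
  m <- .nvar * n + 1L
  x <- pack_state(state$theta, state$p, state$q, state$Ttens,
                  state$R, state$Z, state$Z0)
  xi <- state$xi_b
  tau <- 0
  for (k in seq_len(max_episode)) {
    thc <- x[idx_th(n)]
    Zc <- x[idx_Z(n)]
    Rc <- x[idx_R(n)]
    z0c <- x[m]
    l <- pmax(sqrt(Rc^2 + (z0c - Zc)^2) - 1, .l_floor)
    xi2 <- riccati_advance(xi, 1, np$xi_r, np$Kf, kd_hat(l, np), dt_e)
    sys <- list(grid = grid, np = np, joint = TRUE, stress_fn = NULL,
                xi_b = xi2, Z_prev = Zc, dt = dt_e,
                theta_prev = thc, ptc_eps = eps_run * np$Efound)
    sol <- tryCatch(newton_solve(x, sys, tol_stagnation = 1e-4,
                                 max_iter = 80L, careful = TRUE),
                    error = function(e) e)
    if (inherits(sol, "error")) break
    dz <- sol$x[m] - x[m]
    x <- sol$x
    xi <- xi2
    tau <- tau + dt_e
    if (abs(dz) < 1e-6 && k > 3L) break # episode has settled
  }
  if (tau == 0) return(NULL)
  # exact release step across the episode: frozen-geometry kinetics from
  # the pre-snap state, backward-Euler damper over the full duration
  l0 <- state_gap(state)
  xiR <- riccati_advance(state$xi_b, 1, np$xi_r, np$Kf, kd_hat(l0, np), tau)
  sysR <- list(grid = grid, np = np, joint = TRUE, stress_fn = NULL,
               xi_b = xiR, Z_prev = state$Z, dt = tau)
  rel <- tryCatch(newton_solve(x, sysR, tol_stagnation = 1e-6,
                               max_iter = 120L, careful = TRUE),
                  error = function(e) e)
  if (inherits(rel, "error")) return(NULL)
  if (theta_wiggle(rel$x[idx_th(n)]) > .wiggle_cap) return(NULL)
  stnew <- unpack_state(rel$x, grid$n, TRUE)
  xi_new <- xiR
  dt <- dt_e # restart the adaptive step cautiously after the snap
  state$Z_prev <- state$Z
  state$theta <- stnew$theta
  state$p <- stnew$p
  state$q <- stnew$q
  state$Ttens <- stnew$Ttens
  state$R <- stnew$R
  state$Z <- stnew$Z
  state$Z0 <- stnew$Z0
  state$xi_b <- xi_new
  state$time <- state$time + tau
  state$dt_prev <- dt
  state$cache <- NULL # the snap invalidates any cached factorization
  state
}

#' Internalization metrics of a state
#'
#' The penetration depth follows the wrapping geometry: with a spherical
#' contact zone of radius a + lambda joining a flat outer membrane, the
#' particle elevation and the wrapping angle are tied by
#' Z0 = (a + lambda) cos(alpha), and the depth d = a (1 - cos(alpha))
#' becomes \code{d = a (1 - Z0/(a + lambda))}.  It is zero at the initial
#' elevation Z0 = a + lambda, reaches a at equatorial wrapping and 2a at
#' full engulfment; the particle counts as internalized when d/(2a) = 1.
#' The wrapping angle is reported as the largest bond angle alpha among
#' nodes carrying a substantial bond density (> 0.1 xi_l).
#'
#' @param state an \code{npw_state}
#' @return list with \code{d_over_2a} and \code{wrap_angle} (radians)
#' @export
internalization_metrics <- function(state) {
  np <- state$np
  d <- 1 - state$Z0 / (1 + np$lambda)
  sel <- state$xi_b > 0.1
  wrap <- if (any(sel)) {
    alpha <- atan2(state$R, state$Z0 - state$Z)
    max(alpha[sel])
  } else 0
  list(d_over_2a = d / 2, wrap_angle = wrap)
}

#' Run a full internalization simulation
#'
#' Integrates from the initial weakly-attached state until the wrapping
#' depth has equilibrated (relative change of d/(2a) below 1e-4 over a
#' 1-time-unit window) or \code{t_max} is reached.
#'
#' @param params an \code{npw_params} object
#' @param grid an \code{npw_grid}; built automatically when NULL
#' @param t_max maximum simulated time (viscoelastic time units mu/E)
#' @param coarse passed to [build_grid()] when the grid is built here
#' @param stop_at_internalization if TRUE, stop as soon as d/(2a) >= 1
#'   (the maximum depth is then a lower bound)
#' @param conv_tol relative depth-change tolerance for equilibrium
#' @param max_steps safety cap on the number of time steps
#' @param max_snaps snap-through traversals allowed before the wrapping
#'   front counts as arrested (bounds the cost of deeply engulfed runs)
#' @param verbose print progress lines
#' @return list of class \code{npw_run}: \code{internalization_time}
#'   (time units; NA if d/(2a) = 1 is never reached),
#'   \code{max_depth} (final d/(2a)), \code{converged},
#'   \code{reached_internalization}, \code{n_steps}, \code{final} (final
#'   state) and \code{trajectory} (data.frame with time, dt, Z0, d_over_2a,
#'   wrap_angle, total_bonds, max_xi_b)
#' @export
run_simulation <- function(params, grid = NULL, t_max = 60, coarse = FALSE,
                           stop_at_internalization = FALSE,
                           conv_tol = 1e-4, max_steps = 200000L,
                           max_snaps = 25L, verbose = FALSE,
                           step_hook = NULL) {
  np <- solver_coefficients(params)
  if (is.null(grid))
    grid <- if (coarse) build_grid(params, s_max_factor = 10, coarse = TRUE)
            else build_grid(params)
  state <- initialize_state(np, grid)
  state$max_snaps <- as.integer(max_snaps)
  cap <- 4096L
  traj <- matrix(NA_real_, nrow = cap, ncol = 7L)
  colnames(traj) <- c("time", "dt", "Z0", "d_over_2a", "wrap_angle",
                      "total_bonds", "max_xi_b")
  k <- 0L
  record <- function(state) {
    if (k + 1L > nrow(traj)) {
      traj <<- rbind(traj, matrix(NA_real_, nrow = nrow(traj), ncol = 7L))
    }
    k <<- k + 1L
    m <- internalization_metrics(state)
    nb <- sum(grid$wq * state$xi_b * 2 * pi * state$R)
    traj[k, ] <<- c(state$time, state$dt_prev, state$Z0, m$d_over_2a,
                    m$wrap_angle, nb, max(state$xi_b))
  }
  record(state)
  converged <- FALSE
  reached <- FALSE
  arrested <- FALSE
  while (state$time < t_max && k < max_steps) {
    state <- step(state, np, grid)
    if (isTRUE(state$arrested)) {
      # the wrapping front has reached a fold of the smooth equilibrium
      # branch; the depth has plateaued and the run is terminal
      arrested <- TRUE
      converged <- TRUE
      record(state)
      break
    }
    record(state)
    if (!is.null(step_hook)) step_hook(state)
    d_now <- traj[k, "d_over_2a"]
    if (!reached && d_now >= 1) {
      reached <- TRUE
      if (stop_at_internalization) break
    }
    if (verbose && k %% 200L == 0L)
      message(sprintf("t = %.4g  dt = %.3g  d/2a = %.4f", state$time,
                      state$dt_prev, d_now))
    if (state$time >= 1) {
      jwin <- findInterval(state$time - 1, traj[seq_len(k), "time"])
      if (jwin >= 1L && jwin < k) {
        d_then <- traj[jwin, "d_over_2a"]
        if (abs(d_now - d_then) / max(abs(d_now), 1e-2) < conv_tol) {
          converged <- TRUE
          break
        }
      }
    }
  }
  traj <- as.data.frame(traj[seq_len(k), , drop = FALSE])
  # internalization time by linear interpolation of the d/(2a) = 1 crossing
  t_int <- NA_real_
  ge <- which(traj$d_over_2a >= 1)
  if (length(ge)) {
    j <- ge[1]
    if (j == 1L) t_int <- traj$time[1]
    else {
      t0 <- traj$time[j - 1]; t1 <- traj$time[j]
      d0 <- traj$d_over_2a[j - 1]; d1 <- traj$d_over_2a[j]
      t_int <- t0 + (1 - d0) / (d1 - d0) * (t1 - t0)
    }
  }
  out <- list(internalization_time = t_int,
              max_depth = traj$d_over_2a[k],
              converged = converged,
              arrested = arrested,
              reached_internalization = reached,
              n_steps = k - 1L,
              final = state,
              trajectory = traj,
              grid = grid,
              params = params)
  class(out) <- "npw_run"
  out
}

#' @export
print.npw_run <- function(x, ...) {
  cat("Internalization run:", x$n_steps, "steps to t =",
      sprintf("%.4g", x$final$time), "time units\n")
  cat(sprintf("  final depth d/(2a) = %.4f%s\n", x$max_depth,
              if (x$reached_internalization) " (internalized)" else ""))
  if (!is.na(x$internalization_time))
    cat(sprintf("  internalization time = %.4g time units\n",
                x$internalization_time))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}
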