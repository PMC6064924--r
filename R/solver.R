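# Unsteady incompressible laminar Newtonian flow in an idealized 2-D channel
# with ostium side outlets. Staggered (MAC) grid projection method:
# QUICK-style upwind advection (AB2 in time), Crank-Nicolson diffusion,
# incremental pressure projection with a sparse Cholesky Poisson solve.
# Boundary protocol: Dirichlet parabolic inlet scaled to the instantaneous
# waveform mean; strong split-scaled plug outflow at the main outlet and at
# every ostium opening, so the prescribed flow division holds exactly;
# no-slip on solid walls.

# 1-D Laplacian (units 1/d^2). end = "dirichlet": neighbor value known,
# moved to RHS; "reflect": ghost = -adjacent (tangential no-slip across the
# wall); "neumann": ghost = adjacent (zero normal gradient).
lap1d <- function(n, d, left, right) {
  enddiag <- function(end) switch(end, dirichlet = -2, reflect = -3, neumann = -1)
  di <- rep(-2, n)
  di[1L] <- enddiag(left)
  di[n] <- enddiag(right)
  Matrix::bandSparse(n, n, k = -1:1,
                     diagonals = list(rep(1, n - 1L), di, rep(1, n - 1L))) / d^2
}

solver_plan <- function(geometry, props, dt) {
  nx <- geometry$grid_nx; ny <- geometry$grid_ny
  dx <- geometry$dx; dy <- geometry$dy
  nu <- props$dynamic_viscosity_eta / props$density_rho
  cdiff <- nu * dt / 2

  Ix_u <- Matrix::Diagonal(nx - 1L); Iy <- Matrix::Diagonal(ny)
  Lu <- Matrix::kronecker(Iy, lap1d(nx - 1L, dx, "dirichlet", "dirichlet")) +
    Matrix::kronecker(lap1d(ny, dy, "reflect", "reflect"), Ix_u)
  Au <- Matrix::Diagonal((nx - 1L) * ny) - cdiff * Lu

  Ix_v <- Matrix::Diagonal(nx); Iy_v <- Matrix::Diagonal(ny - 1L)
  Lv <- Matrix::kronecker(Iy_v, lap1d(nx, dx, "reflect", "reflect")) +
    Matrix::kronecker(lap1d(ny - 1L, dy, "dirichlet", "dirichlet"), Ix_v)
  Av <- Matrix::Diagonal(nx * (ny - 1L)) - cdiff * Lv

  Lp <- Matrix::kronecker(Matrix::Diagonal(ny), lap1d(nx, dx, "neumann", "neumann")) +
    Matrix::kronecker(lap1d(ny, dy, "neumann", "neumann"), Matrix::Diagonal(nx))
  Ap <- -Lp
  Ap[1L, 1L] <- Ap[1L, 1L] + 1  # pin the constant null space (SPD regularization)

  s <- (seq_len(ny) - 0.5) / ny
  plan <- list(
    nx = nx, ny = ny, dx = dx, dy = dy, dt = dt, nu = nu, cdiff = cdiff,
    profile = 6 * s * (1 - s),  # parabolic, unit mean
    chol_u = Matrix::Cholesky(Matrix::forceSymmetric(Au)),
    chol_v = Matrix::Cholesky(Matrix::forceSymmetric(Av)),
    chol_p = Matrix::Cholesky(Matrix::forceSymmetric(Ap)))
  plan$key <- c(nx, ny, dx, dy, dt, nu)
  plan
}

# Split fractions resolved against the geometry's outlets.
resolve_splits <- function(geometry, splits) {
  stopifnot(inherits(splits, "outlet_split"))
  n_ost <- if (is.null(geometry$ostia)) 0L else nrow(geometry$ostia)
  need <- c("main", if (n_ost) geometry$ostia$ostium)
  if (!all(need %in% names(splits)))
    stop("`splits` must name 'main' and every geometry ostium", call. = FALSE)
  f <- unclass(splits)[need]
  f / sum(f)  # renormalize over the outlets this geometry actually has
}

#' Initialize a flow state at rest
#'
#' Zero velocity and pressure everywhere on the staggered grid, with the
#' solver operators (Crank-Nicolson Helmholtz and pressure Poisson
#' factorizations) precomputed for the given time step.
#'
#' @param geometry A [build_channel()] geometry.
#' @param props A [fluid_properties()].
#' @param dt Time step in seconds.
#' @return An object of class `flow_state` holding the staggered velocity
#'   components (`u`: `(nx+1) x ny`, `v`: `nx x (ny+1)`), kinematic pressure
#'   `P` (Pa m^3/kg; multiply by density for Pa), current `time` and
#'   `cycle`, and cached solver operators.
#' @export
flow_state <- function(geometry, props, dt) {
  stopifnot(inherits(geometry, "channel_geometry"), inherits(props, "fluid_properties"))
  check_positive(dt, "dt")
  nx <- geometry$grid_nx; ny <- geometry$grid_ny
  structure(list(u = matrix(0, nx + 1L, ny), v = matrix(0, nx, ny + 1L),
                 P = matrix(0, nx, ny), time = 0, cycle = 0L,
                 adv_u_prev = NULL, adv_v_prev = NULL,
                 plan = solver_plan(geometry, props, dt)),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> grid %d x %d, t = %g s, max|u| = %.4g m/s\n",
              nrow(x$u) - 1L, ncol(x$u), x$time, max(abs(x$u))))
  invisible(x)
}

# QUICK-style upwind face values between consecutive columns of phi
# (faces f = 1..ncol-1); conv is the convecting velocity at the faces.
# Falls back to central interpolation where the upwind node is unavailable.
quick_y <- function(phi, conv) {
  m <- ncol(phi)
  cen <- 0.5 * (phi[, 1:(m - 1L), drop = FALSE] + phi[, 2:m, drop = FALSE])
  pos <- cen; neg <- cen
  if (m >= 3L) {
    pos[, 2:(m - 1L)] <- (6 * phi[, 2:(m - 1L)] + 3 * phi[, 3:m] - phi[, 1:(m - 2L)]) / 8
    neg[, 1:(m - 2L)] <- (6 * phi[, 2:(m - 1L)] + 3 * phi[, 1:(m - 2L)] - phi[, 3:m]) / 8
  }
  ifelse(conv >= 0, pos, neg)
}

quick_x <- function(phi, conv) {
  m <- nrow(phi)
  cen <- 0.5 * (phi[1:(m - 1L), , drop = FALSE] + phi[2:m, , drop = FALSE])
  pos <- cen; neg <- cen
  if (m >= 3L) {
    pos[2:(m - 1L), ] <- (6 * phi[2:(m - 1L), ] + 3 * phi[3:m, ] - phi[1:(m - 2L), ]) / 8
    neg[1:(m - 2L), ] <- (6 * phi[2:(m - 1L), ] + 3 * phi[1:(m - 2L), ] - phi[3:m, ]) / 8
  }
  ifelse(conv >= 0, pos, neg)
}

# Advection of u, conservative form, at interior u faces (i = 2..nx).
advect_u <- function(u, v, dx, dy) {
  nx <- nrow(u) - 1L; ny <- ncol(u)
  uc <- 0.5 * (u[1:nx, ] + u[2:(nx + 1L), ])          # at cell centers
  Fx <- uc * quick_x(u, uc)                            # nx x ny
  ddx <- (Fx[2:nx, ] - Fx[1:(nx - 1L), ]) / dx         # (nx-1) x ny
  up <- cbind(-u[, 1L], u, -u[, ny])                   # y ghosts (no-slip)
  vc <- 0.5 * (v[1:(nx - 1L), ] + v[2:nx, ])           # (nx-1) x (ny+1), at interior u faces
  Gy <- vc * quick_y(up[2:nx, , drop = FALSE], vc)     # (nx-1) x (ny+1)
  ddy <- (Gy[, 2:(ny + 1L)] - Gy[, 1:ny]) / dy
  ddx + ddy
}

# Advection of v at interior v faces (j = 2..ny).
advect_v <- function(u, v, dx, dy) {
  nx <- nrow(v); ny <- ncol(v) - 1L
  vcen <- 0.5 * (v[, 1:ny] + v[, 2:(ny + 1L)])         # at cell centers
  Ky <- vcen * quick_y(v, vcen)                        # nx x ny
  ddy <- (Ky[, 2:ny] - Ky[, 1:(ny - 1L)]) / dy         # nx x (ny-1)
  vp <- rbind(-v[1L, ], v, -v[nx, ])                   # x ghosts
  uc <- 0.5 * (u[, 1:(ny - 1L)] + u[, 2:ny])           # (nx+1) x (ny-1), at v corners
  Hx <- uc * quick_x(vp[, 2:ny, drop = FALSE], uc)     # (nx+1) x (ny-1)
  ddx <- (Hx[2:(nx + 1L), ] - Hx[1:nx, ]) / dx
  ddx + ddy
}

lap_interior_u <- function(u, dx, dy) {
  nx <- nrow(u) - 1L; ny <- ncol(u)
  up <- cbind(-u[, 1L], u, -u[, ny])
  (u[1:(nx - 1L), ] - 2 * u[2:nx, ] + u[3:(nx + 1L), ]) / dx^2 +
    (up[2:nx, 1:ny] - 2 * up[2:nx, 2:(ny + 1L)] + up[2:nx, 3:(ny + 2L)]) / dy^2
}

lap_interior_v <- function(v, dx, dy) {
  nx <- nrow(v); ny <- ncol(v) - 1L
  vp <- rbind(-v[1L, ], v, -v[nx, ])
  (v[, 1:(ny - 1L)] - 2 * v[, 2:ny] + v[, 3:(ny + 1L)]) / dy^2 +
    (vp[1:nx, 2:ny] - 2 * vp[2:(nx + 1L), 2:ny] + vp[3:(nx + 2L), 2:ny]) / dx^2
}

# Boundary values at a given waveform time: inlet profile, main outlet plug,
# per-ostium plug velocities (sign = outflow through the wall).
boundary_values <- function(plan, geometry, inlet, frac, t) {
  ny <- plan$ny; nx <- plan$nx
  u_in <- plan$profile * evaluate_waveform(inlet, t)
  Q_in <- sum(u_in) * plan$dy
  u_out <- frac[["main"]] * Q_in / (ny * plan$dy)
  v_bot <- numeric(nx); v_top <- numeric(nx)
  if (!is.null(geometry$ostia)) {
    for (k in seq_len(nrow(geometry$ostia))) {
      cells <- geometry$ostia$cells[[k]]
      q <- frac[[geometry$ostia$ostium[k]]] * Q_in / (length(cells) * plan$dx)
      if (geometry$ostia$side[k] == "bottom") v_bot[cells] <- -q else v_top[cells] <- q
    }
  }
  list(u_in = u_in, u_out = u_out, v_bot = v_bot, v_top = v_top, Q_in = Q_in)
}

#' Advance the flow one projection-method step
#'
#' One fractional step: QUICK-upwind advection (second-order
#' Adams-Bashforth), Crank-Nicolson diffusion, Dirichlet inlet velocity
#' evaluated from the waveform at the new time, split-scaled plug outflow at
#' the main outlet and ostia, then a pressure Poisson solve and projection
#' onto the discretely divergence-free space. The step signals an error if
#' the advective CFL number exceeds 1.
#'
#' @param state A [flow_state()].
#' @param geometry A [build_channel()] geometry (must match the state grid).
#' @param props A [fluid_properties()].
#' @param inlet A `bezier_waveform` inlet velocity waveform (cycle mean in
#'   m/s as a function of time).
#' @param splits An [outlet_split()]; entries are renormalized over the
#'   outlets present in this geometry.
#' @param dt Time step in seconds (must match the state's cached operators;
#'   a differing `dt` triggers a re-factorization).
#' @return The advanced `flow_state`, with a `diagnostics` field holding the
#'   post-projection maximum discrete divergence (1/s), the inflow, and the
#'   relative mass-balance and per-ostium split errors.
#' @export
advance_step <- function(state, geometry, props, inlet, splits, dt) {
  stopifnot(inherits(state, "flow_state"))
  plan <- state$plan
  nu <- props$dynamic_viscosity_eta / props$density_rho
  if (is.null(plan) ||
      !isTRUE(all.equal(plan$key,
                        c(geometry$grid_nx, geometry$grid_ny, geometry$dx,
                          geometry$dy, dt, nu)))) {
    plan <- solver_plan(geometry, props, dt)
    state$plan <- plan
  }
  nx <- plan$nx; ny <- plan$ny; dx <- plan$dx; dy <- plan$dy
  frac <- resolve_splits(geometry, splits)
  bc <- boundary_values(plan, geometry, inlet, frac, state$time + dt)

  u <- state$u; v <- state$v
  # Stability signal: a direction is safe if its advective CFL stays below
  # 0.9 or if Crank-Nicolson diffusion damps it (dt <= 2 nu / vel^2, the
  # von Neumann bound for central-type advection with implicit diffusion).
  umax <- max(abs(u), abs(bc$u_in), abs(bc$u_out))
  vmax <- max(abs(v), abs(bc$v_bot), abs(bc$v_top))
  cfl <- umax * dt / dx + vmax * dt / dy
  bad_x <- umax * dt / dx > 0.9 && dt > 2 * plan$nu / umax^2
  bad_y <- vmax * dt / dy > 0.9 && dt > 2 * plan$nu / vmax^2
  if (bad_x || bad_y)
    stop(sprintf("unstable step: advective CFL (%.2f) beyond the stable range",
                 cfl), call. = FALSE)

  adv_u <- advect_u(u, v, dx, dy)
  adv_v <- advect_v(u, v, dx, dy)
  au <- if (is.null(state$adv_u_prev)) adv_u else 1.5 * adv_u - 0.5 * state$adv_u_prev
  av <- if (is.null(state$adv_v_prev)) adv_v else 1.5 * adv_v - 0.5 * state$adv_v_prev

  gpx <- (state$P[2:nx, , drop = FALSE] - state$P[1:(nx - 1L), , drop = FALSE]) / dx
  gpy <- (state$P[, 2:ny, drop = FALSE] - state$P[, 1:(ny - 1L), drop = FALSE]) / dy

  rhs_u <- u[2:nx, , drop = FALSE] +
    dt * (-au - gpx + 0.5 * plan$nu * lap_interior_u(u, dx, dy))
  rhs_u[1L, ] <- rhs_u[1L, ] + plan$cdiff * bc$u_in / dx^2
  rhs_u[nx - 1L, ] <- rhs_u[nx - 1L, ] + plan$cdiff * bc$u_out / dx^2
  ustar <- matrix(as.numeric(Matrix::solve(plan$chol_u, as.numeric(rhs_u))),
                  nx - 1L, ny)

  rhs_v <- v[, 2:ny, drop = FALSE] +
    dt * (-av - gpy + 0.5 * plan$nu * lap_interior_v(v, dx, dy))
  rhs_v[, 1L] <- rhs_v[, 1L] + plan$cdiff * bc$v_bot / dy^2
  rhs_v[, ny - 1L] <- rhs_v[, ny - 1L] + plan$cdiff * bc$v_top / dy^2
  vstar <- matrix(as.numeric(Matrix::solve(plan$chol_v, as.numeric(rhs_v))),
                  nx, ny - 1L)

  u[1L, ] <- bc$u_in; u[nx + 1L, ] <- bc$u_out; u[2:nx, ] <- ustar
  v[, 1L] <- bc$v_bot; v[, ny + 1L] <- bc$v_top; v[, 2:ny] <- vstar

  div <- (u[2:(nx + 1L), ] - u[1:nx, ]) / dx + (v[, 2:(ny + 1L)] - v[, 1:ny]) / dy
  phi <- matrix(as.numeric(Matrix::solve(plan$chol_p, as.numeric(-div / dt))), nx, ny)
  u[2:nx, ] <- u[2:nx, ] - dt * (phi[2:nx, ] - phi[1:(nx - 1L), ]) / dx
  v[, 2:ny] <- v[, 2:ny] - dt * (phi[, 2:ny] - phi[, 1:(ny - 1L)]) / dy

  div2 <- (u[2:(nx + 1L), ] - u[1:nx, ]) / dx + (v[, 2:(ny + 1L)] - v[, 1:ny]) / dy

  Q_out <- u[nx + 1L, 1L] * ny * dy + sum(-v[, 1L]) * dx + sum(v[, ny + 1L]) * dx
  Qscale <- max(abs(bc$Q_in), .Machine$double.eps)
  split_err <- 0
  if (!is.null(geometry$ostia) && abs(bc$Q_in) > 0) {
    for (k in seq_len(nrow(geometry$ostia))) {
      cells <- geometry$ostia$cells[[k]]
      flux <- if (geometry$ostia$side[k] == "bottom")
        sum(-v[cells, 1L]) * dx else sum(v[cells, ny + 1L]) * dx
      target <- frac[[geometry$ostia$ostium[k]]] * bc$Q_in
      split_err <- max(split_err, abs(flux - target) / abs(target))
    }
  }

  state$u <- u; state$v <- v; state$P <- state$P + phi
  state$time <- state$time + dt
  state$adv_u_prev <- adv_u; state$adv_v_prev <- adv_v
  state$diagnostics <- list(max_divergence = max(abs(div2)),
                            Q_in = bc$Q_in,
                            mass_error_rel = abs(Q_out - bc$Q_in) / Qscale,
                            split_error_rel = split_err,
                            cfl = cfl)
  state
}

# Wall shear (x-component) at wall-adjacent u faces by one-sided
# second-order differentiation of the tangential velocity: the derivative
# at the wall of the quadratic through the three nearest u values.
wall_shear_bottom <- function(u, dy, eta) {
  if (ncol(u) < 3L)
    stop("geometry error: degenerate wall cell (no interior neighbor)", call. = FALSE)
  eta * (-2 * u[, 1L] + 3 * u[, 2L] - u[, 3L]) / dy
}

wall_shear_top <- function(u, dy, eta) {
  ny <- ncol(u)
  if (ny < 3L)
    stop("geometry error: degenerate wall cell (no interior neighbor)", call. = FALSE)
  eta * (-2 * u[, ny] + 3 * u[, ny - 1L] - u[, ny - 2L]) / dy
}

# Wall points (interior u faces not touching an ostium opening), their
# positions, normals (pointing into the fluid) and quadrant region labels.
wall_points <- function(geometry, region_halfwidth = 1.5) {
  nx <- geometry$grid_nx
  faces <- 2:nx
  x <- (faces - 1L) * geometry$dx
  out <- list()
  for (side in c("bottom", "top")) {
    excl <- integer()
    region <- rep("non-ostial", length(faces))
    if (!is.null(geometry$ostia)) {
      on_side <- which(geometry$ostia$side == side)
      for (k in on_side) {
        cells <- geometry$ostia$cells[[k]]
        excl <- c(excl, intersect(faces, c(cells, cells + 1L)))
        w <- geometry$ostia$width_eff[k]
        d <- pmax(0, abs(x - geometry$ostia$position[k]) - w / 2)
        region[d <= region_halfwidth * w] <- geometry$ostia$quadrant[k]
      }
    }
    keep <- !(faces %in% excl)
    out[[side]] <- data.frame(
      face = faces[keep], x = x[keep],
      y = if (side == "bottom") 0 else geometry$height_h,
      side = side,
      nx = 0, ny = if (side == "bottom") 1 else -1,
      region = region[keep], stringsAsFactors = FALSE)
  }
  rbind(out$bottom, out$top)
}

#' Instantaneous wall shear stress vectors
#'
#' Extracts the wall shear stress at every wall point (top and bottom walls,
#' excluding ostium openings) from a flow state:
#' `tau = eta * d(u_tangential)/d(n)` by a one-sided second-order finite
#' difference at the wall, oriented along the local wall tangent (+x) and
#' paired with the wall normal pointing into the fluid.
#'
#' @param state A [flow_state()].
#' @param geometry The matching [build_channel()] geometry.
#' @param props A [fluid_properties()].
#' @return Data frame with columns `point_id`, `x`, `y`, `side`, `nx`, `ny`,
#'   `region`, `tau_x`, `tau_y` (Pa).
#' @export
extract_wall_shear <- function(state, geometry, props) {
  stopifnot(inherits(state, "flow_state"), inherits(geometry, "channel_geometry"))
  eta <- props$dynamic_viscosity_eta
  wp <- wall_points(geometry)
  tb <- wall_shear_bottom(state$u, geometry$dy, eta)
  tt <- wall_shear_top(state$u, geometry$dy, eta)
  tau <- ifelse(wp$side == "bottom", tb[wp$face], tt[wp$face])
  data.frame(point_id = paste0(substr(wp$side, 1L, 1L), wp$face),
             x = wp$x, y = wp$y, side = wp$side, nx = wp$nx, ny = wp$ny,
             region = wp$region, tau_x = tau, tau_y = 0,
             stringsAsFactors = FALSE)
}

#' Run the pulsatile cycle protocol and record final-cycle wall shear
#'
#' Runs `n_cycles` cardiac cycles from rest at `steps_per_cycle` time steps
#' per cycle (the protocol default is dt = T/1000 and three cycles, with the
#' first two as warm-up so the last cycle is periodic), recording the wall
#' shear vector at every wall point at every step of the final
#' `record_cycles` cycles.
#'
#' @inheritParams advance_step
#' @param n_cycles Number of cycles to simulate (>= 2; >= `record_cycles` + 1).
#' @param steps_per_cycle Time steps per cycle (dt = period / steps_per_cycle).
#' @param record_cycles How many trailing cycles to record (1 or 2; with 2,
#'   the penultimate-cycle tau matrix is attached as attribute
#'   `"penultimate_tau"` for periodicity checks).
#' @param region_halfwidth Ostium-region half-width in multiples of the
#'   ostium width: wall points within this distance of an ostium mouth get
#'   the ostium's quadrant label.
#' @param initial `"rest"` (zero flow, the cycle-protocol default) or
#'   `"developed"` (parabolic profile at the waveform's t = 0 mean
#'   everywhere), which avoids the impulsive start when validating against
#'   steady solutions.
#' @return A 2-D [wss_record_set()] for the final cycle (components
#'   `tau_x`, `tau_y`; normals point into the fluid), with attributes
#'   `"diagnostics"` (worst-case divergence, mass and split errors over all
#'   steps, peak inflow) and optionally `"penultimate_tau"`.
#' @export
run_cycles <- function(geometry, props, inlet, splits, n_cycles = 3L,
                       steps_per_cycle = 1000L, record_cycles = 1L,
                       region_halfwidth = 1.5, initial = c("rest", "developed")) {
  initial <- match.arg(initial)
  stopifnot(inherits(inlet, "bezier_waveform"))
  n_cycles <- as.integer(n_cycles)
  steps_per_cycle <- as.integer(steps_per_cycle)
  record_cycles <- as.integer(record_cycles)
  if (n_cycles < 2L)
    stop("`n_cycles` must be >= 2 (at least one warm-up cycle)", call. = FALSE)
  if (record_cycles < 1L || record_cycles > n_cycles - 1L)
    stop("`record_cycles` must be in [1, n_cycles - 1]", call. = FALSE)
  dt <- inlet$period / steps_per_cycle
  state <- flow_state(geometry, props, dt)
  if (initial == "developed") {
    v0 <- evaluate_waveform(inlet, 0)
    state$u <- outer(rep(1, geometry$grid_nx + 1L), state$plan$profile * v0)
  }
  eta <- props$dynamic_viscosity_eta
  wp <- wall_points(geometry, region_halfwidth)
  n_pts <- nrow(wp)
  bot <- wp$side == "bottom"

  rec <- vector("list", record_cycles)
  for (k in seq_len(record_cycles)) rec[[k]] <- matrix(0, n_pts, steps_per_cycle)
  diag_worst <- c(max_divergence = 0, mass_error_rel = 0, split_error_rel = 0,
                  Q_in_peak = 0)

  for (cyc in seq_len(n_cycles)) {
    ri <- cyc - (n_cycles - record_cycles)
    for (s in seq_len(steps_per_cycle)) {
      state <- advance_step(state, geometry, props, inlet, splits, dt)
      d <- state$diagnostics
      diag_worst["max_divergence"] <- max(diag_worst["max_divergence"], d$max_divergence)
      diag_worst["mass_error_rel"] <- max(diag_worst["mass_error_rel"], d$mass_error_rel)
      diag_worst["split_error_rel"] <- max(diag_worst["split_error_rel"], d$split_error_rel)
      diag_worst["Q_in_peak"] <- max(diag_worst["Q_in_peak"], abs(d$Q_in))
      if (ri >= 1L) {
        col <- (s %% steps_per_cycle) + 1L  # step at t = T wraps to t = 0
        tb <- wall_shear_bottom(state$u, geometry$dy, eta)
        tt <- wall_shear_top(state$u, geometry$dy, eta)
        rec[[ri]][, col] <- ifelse(bot, tb[wp$face], tt[wp$face])
      }
    }
    state$cycle <- cyc
  }

  times <- (seq_len(steps_per_cycle) - 1L) * dt
  res <- wss_record_set(times, inlet$period,
                        tau_x = rec[[record_cycles]],
                        tau_y = matrix(0, n_pts, steps_per_cycle),
                        normal = cbind(wp$nx, wp$ny),
                        position = cbind(wp$x, wp$y),
                        point_id = paste0(substr(wp$side, 1L, 1L), wp$face),
                        region = wp$region)
  attr(res, "diagnostics") <- as.list(diag_worst)
  attr(res, "final_state") <- state
  if (record_cycles >= 2L)
    attr(res, "penultimate_tau") <- rec[[record_cycles - 1L]]
  res
}
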