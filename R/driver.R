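# Simulation driver: state initialization, the fixed per-step operation
# order, full runs, presets, and the virtual creep-test rheometer.
#
# Step ordering (frozen; changing it is a breaking change):
#   1. Lagrangian forces: elements, wall springs/tethers, biofilm anchors,
#      freeze tethers while t < t_freeze
#   2. spread forces to the grid
#   3. add the uniform Poiseuille drive rho*g
#   4. fluid step (spectral projection)
#   5. interpolate velocities, move all Lagrangian nodes by U*dt
#   6. Maxwell rest-length update
#   7. for t >= t_freeze: growth step, then transport step with the uptake
#      reaction and the source clamp
#   8. record at the configured stride

#' Initialize simulation state
#'
#' Builds the Eulerian field, wall chain, biofilm mesh (unless
#' \code{config$has_biofilm} is FALSE), growth ledger and nutrient source,
#' and seeds the RNG.
#'
#' @param config a \code{sim_config}.
#' @return a state list (time, field, mesh, wall, ledger, source).
#' @export
init_simulation <- function(config) {
  set.seed(config$seed)
  field <- make_field(config$Nx, config$Ny, config$h)
  wall <- wall_chain(config$Lx, config$d_w, 0, config$A, config$B)
  mesh <- NULL
  ledger <- NULL
  if (isTRUE(config$has_biofilm)) {
    kind <- if (is.finite(config$eta)) "maxwell" else "stokes"
    mesh <- generate_semicircle_mesh(config$r_c, config$ds,
                                     config$biofilm_center_x, kind = kind,
                                     lambda_b = config$lambda_b,
                                     v0 = config$v0, n0 = config$n0,
                                     chi = config$chi)
    ledger <- new_ledger(mesh)
  }
  list(t = 0, step = 0L, field = field, wall = wall, mesh = mesh,
       ledger = ledger, source = build_source(config),
       g = poiseuille_g(config$u_max, config$Ly, config$mu, config$rho),
       nutrient_on = config$nutrient_config != "none")
}

#' Advance the simulation by one time step
#'
#' @param state state list from \code{\link{init_simulation}}.
#' @param config a \code{sim_config}.
#' @return the updated state.
#' @export
sim_step <- function(state, config) {
  dt <- config$dt
  mesh <- state$mesh
  has_mesh <- !is.null(mesh)
  # (1) Lagrangian forces
  fw <- wall_forces(state$wall)
  if (has_mesh) {
    fb <- element_forces_all(mesh, config$E) +
      anchor_forces(mesh, config$C) +
      freeze_forces(mesh, config$D, state$t, config$t_freeze)
    pts <- rbind(mesh$pos, state$wall$pos)
    frc <- rbind(fb, fw)
  } else {
    pts <- state$wall$pos
    frc <- fw
  }
  # (2) spread, (3) drive, (4) fluid step
  st <- ib_stencil(pts[, 1], pts[, 2], config$Nx, config$Ny, config$h)
  sp <- spread_forces(pts, frc, config$Nx, config$Ny, config$h, stencil = st)
  state$field <- ns_step(state$field, sp$fx, sp$fy, dt,
                         config$mu, config$rho, state$g)
  # (5) interpolate and move
  U <- interp_velocity(state$field$u, state$field$v, pts, config$h,
                       stencil = st)
  pts <- pts + U * dt
  if (has_mesh) {
    nq <- mesh$Q
    mesh$pos <- pts[seq_len(nq), , drop = FALSE]
    state$wall$pos <- pts[-seq_len(nq), , drop = FALSE]
  } else {
    state$wall$pos <- pts
  }
  # (6) Maxwell rest lengths
  if (has_mesh)
    mesh <- update_rest_lengths(mesh, config$E, config$eta, dt)
  # (7) growth + transport after release
  if (has_mesh && state$nutrient_on && state$t >= config$t_freeze) {
    if (!isTRUE(state$source_initialized)) {
      state$field$c[state$source$cells] <- state$source$c0
      state$source_initialized <- TRUE
    }
    gs <- growth_step(mesh, state$ledger, state$field$c, dt, config)
    mesh <- gs$mesh
    state$ledger <- gs$ledger
    # the uptake region tracks the slowly moving boundary polygon; refresh
    # after topology changes and periodically as the mesh deforms
    if (is.null(state$region) || gs$spawned > 0 ||
        state$step %% 20L == 0L) {
      region <- uptake_region(config$Nx, config$Ny, config$h,
                              biofilm_polygon(mesh))
      if (length(region) == 0) {
        com <- center_of_mass(mesh)
        i0 <- round(com[1] / config$h) %% config$Nx
        j0 <- round(com[2] / config$h) %% config$Ny
        region <- i0 + config$Nx * j0 + 1L
      }
      state$region <- region
    }
    region <- state$region
    r <- NULL
    if (gs$deltaM > 0) {
      if (sum(state$field$c[region]) > 0) {
        r <- reaction_field(state$field$c, region, gs$deltaM, dt, config$Y,
                            config$mu_max, config$K, config$h)
      } else {
        # demand arises from node concentrations sampled just outside the
        # uptake polygon while the region itself is still empty: log it
        state$ledger$unmet <- state$ledger$unmet + gs$deltaM / config$Y
      }
    }
    tr <- adr_step(state$field$c, state$field$u, state$field$v, dt,
                   config$D_c, config$h, r = r, region = region,
                   source = state$source)
    state$field$c <- tr$c
    state$ledger$cumulative_consumed <- state$ledger$cumulative_consumed +
      tr$consumed
    state$ledger$unmet <- state$ledger$unmet + tr$unmet
  }
  state$mesh <- mesh
  state$t <- state$t + dt
  state$step <- state$step + 1L
  state
}

# one trajectory record from the current state
.record_row <- function(state) {
  if (!is.null(state$mesh)) {
    com <- center_of_mass(state$mesh)
    c(t = state$t, com_x = com[1], com_y = com[2],
      M = state$ledger$M, Q = state$mesh$Q, S = state$mesh$S,
      N = state$mesh$N, consumed = state$ledger$cumulative_consumed)
  } else {
    c(t = state$t, com_x = NA_real_, com_y = NA_real_, M = NA_real_,
      Q = NA_real_, S = NA_real_, N = NA_real_, consumed = NA_real_)
  }
}

#' Run a full simulation
#'
#' Executes \code{t_end/dt} steps of \code{\link{sim_step}} and collects a
#' trajectory record every \code{record_stride} steps (plus the initial and
#' final states). Deterministic under the configured seed.
#'
#' @param config a \code{sim_config}.
#' @param progress print progress every 10\% of the run.
#' @return data.frame of trajectory records (t, com_x, com_y, M, Q, S, N,
#'   consumed) with the final state attached as attribute \code{"state"}.
#' @export
run_simulation <- function(config, progress = FALSE) {
  state <- init_simulation(config)
  nsteps <- as.integer(round(config$t_end / config$dt))
  stride <- max(1L, as.integer(config$record_stride))
  recs <- matrix(NA_real_, floor(nsteps / stride) + 2L, 8)
  colnames(recs) <- c("t", "com_x", "com_y", "M", "Q", "S", "N", "consumed")
  ri <- 1L
  recs[ri, ] <- .record_row(state)
  for (s in seq_len(nsteps)) {
    state <- sim_step(state, config)
    if (!all(is.finite(state$field$u[1, ])))
      stop("run_simulation: non-finite velocity at step ", s)
    if (s %% stride == 0 || s == nsteps) {
      ri <- ri + 1L
      recs[ri, ] <- .record_row(state)
      if (!is.null(state$mesh) && !isTRUE(state$warned_self_intersect) &&
          !polygon_is_simple(biofilm_polygon(state$mesh))) {
        warning("run_simulation: biofilm boundary self-intersects at t = ",
                signif(state$t, 4), " s (reported, not repaired)",
                call. = FALSE)
        state$warned_self_intersect <- TRUE
      }
      if (progress && (s %% max(1, nsteps %/% 10) == 0))
        message(sprintf("step %d/%d (t = %.1f s)", s, nsteps, state$t))
    }
  }
  out <- as.data.frame(recs[seq_len(ri), , drop = FALSE])
  attr(out, "state") <- state
  attr(out, "config") <- config
  out
}

# structured equilateral-lattice rectangular patch used by the creep test
.make_patch <- function(nxc, nyc, ds, x0, y0, kind) {
  rows <- lapply(seq_len(nyc) - 1L, function(j) {
    xs <- x0 + (seq_len(nxc) - 1) * ds + (j %% 2) * ds / 2
    cbind(xs, y0 + j * ds * sqrt(3) / 2)
  })
  p <- do.call(rbind, rows)
  tri <- delaunay_triangulate(p)
  cr <- (p[tri[, 2], 1] - p[tri[, 1], 1]) * (p[tri[, 3], 2] - p[tri[, 1], 2]) -
    (p[tri[, 2], 2] - p[tri[, 1], 2]) * (p[tri[, 3], 1] - p[tri[, 1], 1])
  flip <- cr < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  anch <- p[, 2] <= y0 + 1e-12
  mesh_from_triangulation(p, tri, kind = kind, anchored = anch)
}

#' Virtual creep test
#'
#' Shears a rectangular biofilm patch: the bottom node row is tethered in
#' place and a constant tangential traction is applied along the top row
#' (total force \code{stress * width * ds}, the out-of-plane thickness
#' convention under which the element spring constant \code{k = E ds}
#' represents the material modulus E). The recorded shear strain
#' \code{gamma(t) = dx_top / height} is fitted, after discarding the initial
#' transient, to the creep compliance \code{gamma = stress (1/G' + t/eta')};
#' the reported relaxation time is \code{tau = eta'/G'}. Element-level
#' moduli are recovered through the triangular-lattice homogenization
#' \code{G = (sqrt(3)/4) E}.
#'
#' @param applied_stress shear stress (Pa).
#' @param E elastic modulus (Pa).
#' @param eta dashpot viscosity (Pa s); \code{Inf} for a Stokes patch.
#' @param t_end simulated duration (s).
#' @param dt time step (s).
#' @param fit_start fit window start (s); defaults to \code{t_end/3}.
#' @param nxc,nyc patch lattice columns and rows.
#' @param ds lattice spacing (m).
#' @param Nx,Ny,h fluid grid.
#' @param mu,rho fluid properties.
#' @param C_anchor bottom tether stiffness (N/m).
#' @param record_stride steps between strain records.
#' @return list: \code{strain} data.frame (t, gamma), fitted \code{G}
#'   (shear modulus, Pa), \code{eta_shear} (Pa s), recovered element-level
#'   \code{E} and \code{eta_axial}, and \code{tau} (s).
#' @export
creep_test <- function(applied_stress = 1, E = 50, eta = 5.349e4,
                       t_end = 450, dt = 0.05, fit_start = NULL,
                       nxc = 25, nyc = 7, ds = 2.5e-5,
                       Nx = 24, Ny = 24, h = 1e-4,
                       mu = 9.31e-4, rho = 1000, C_anchor = 1e-2,
                       record_stride = 20L) {
  if (is.null(fit_start)) fit_start <- t_end / 3
  kind <- if (is.finite(eta)) "maxwell" else "stokes"
  W <- (nxc - 1) * ds
  Hgt <- (nyc - 1) * ds * sqrt(3) / 2
  x0 <- (Nx * h - W) / 2
  y0 <- (Ny * h - Hgt) / 2
  mesh <- .make_patch(nxc, nyc, ds, x0, y0, kind)
  top <- which(mesh$pos[, 2] >= y0 + Hgt - 1e-12)
  x_top0 <- mean(mesh$pos[top, 1])
  f_app <- applied_stress * W * ds / length(top)
  field <- make_field(Nx, Ny, h)
  nsteps <- as.integer(round(t_end / dt))
  ts <- numeric(0); gam <- numeric(0)
  for (s in seq_len(nsteps)) {
    fb <- element_forces_all(mesh, E) + anchor_forces(mesh, C_anchor)
    fb[top, 1] <- fb[top, 1] + f_app
    st <- ib_stencil(mesh$pos[, 1], mesh$pos[, 2], Nx, Ny, h)
    sp <- spread_forces(mesh$pos, fb, Nx, Ny, h, stencil = st)
    field <- ns_step(field, sp$fx, sp$fy, dt, mu, rho)
    U <- interp_velocity(field$u, field$v, mesh$pos, h, stencil = st)
    mesh$pos <- mesh$pos + U * dt
    mesh <- update_rest_lengths(mesh, E, eta, dt)
    if (s %% record_stride == 0) {
      ts <- c(ts, s * dt)
      gam <- c(gam, (mean(mesh$pos[top, 1]) - x_top0) / Hgt)
    }
  }
  sel <- ts >= fit_start
  if (sum(sel) < 5) stop("creep_test: too few records in the fit window")
  fit <- stats::lm(gam[sel] ~ ts[sel])
  icpt <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (icpt <= 0) stop("creep_test: non-physical fitted compliance")
  G <- applied_stress / icpt
  eta_shear <- if (slope > 0) applied_stress / slope else Inf
  lat <- 4 / sqrt(3)
  list(strain = data.frame(t = ts, gamma = gam),
       G = G, eta_shear = eta_shear,
       E = G * lat, eta_axial = eta_shear * lat,
       tau = eta_shear / G,
       fit = c(intercept = icpt, slope = slope))
}

#' Largest stable time step for the explicit structure-fluid coupling
#'
#' The explicit immersed-boundary update of a spring of stiffness k against
#' the kernel-local fluid inertia rho h^2 is stable for
#' \code{k dt^2 / (rho h^2) < 1}; this returns \code{dt = safety * h *
#' sqrt(rho / k_max)} with \code{k_max} the stiffest spring in the problem
#' (elements \code{E ds} and the tether stiffnesses).
#'
#' @param E elastic modulus (Pa).
#' @param ds element spacing (m).
#' @param h grid spacing (m).
#' @param rho fluid density (kg/m^3).
#' @param tethers stiffest tether constant (N/m).
#' @param safety stability safety factor.
#' @return time step (s).
#' @export
stable_dt <- function(E, ds, h, rho = 1000, tethers = 0, safety = 0.25) {
  kmax <- max(E * ds, tethers)
  safety * h * sqrt(rho / kmax)
}

#' Scaled-down qualitative preset
#'
#' A half-length channel on a coarsened grid (three times the default
#' spacing) with softened tether stiffnesses and a time step set by the
#' explicit-coupling stability rule for the requested modulus, for
#' qualitative sign/ordering experiments at interactive cost. The source
#' strip margin is reduced so that the ratio of biofilm migration over a
#' run to the source offset matches the full-scale geometry.
#'
#' @param E elastic modulus (Pa); also sets the stable time step.
#' @param ... overrides passed to \code{\link{default_config}} (an explicit
#'   \code{dt} wins over the stability rule).
#' @return a \code{sim_config}.
#' @export
preset_ci <- function(E = 50, ...) {
  h <- 1.5e-3 / 12
  ds <- h / 5
  teth <- 6e-4
  base <- list(Lx = 5e-3, Ly = 1.5e-3, h = h, ds = ds,
               dt = stable_dt(E, ds, h, tethers = teth, safety = 0.4),
               E = E, d_w = h / 2, r_c = 3.6e-4,
               A = teth, B = teth, C = teth, D = teth,
               margin = 4e-4, t_freeze = 20, t_end = 420,
               record_stride = 20L)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  do.call(default_config, base)
}

#' Empty-channel flow-validation preset
#'
#' Full-scale grid, no biofilm: used to check that the driven channel flow
#' reaches the analytic Poiseuille maximum within tolerance.
#'
#' @param u_max target maximum speed (m/s).
#' @param ... further overrides.
#' @return a \code{sim_config}.
#' @export
preset_empty_channel <- function(u_max = 5e-6, ...) {
  # one marker per cell keeps the wall sealed (the kernel spans 4 cells)
  # at half the Lagrangian bookkeeping cost of the default h/2 spacing
  default_config(u_max = u_max, has_biofilm = FALSE, nutrient_config = "none",
                 d_w = 4.17e-5, t_end = 20, record_stride = 1000L, ...)
}
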