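# Nutrient transport: advection-diffusion-reaction on the periodic grid.
#
# Advection is first-order upwind in conservative (flux) form with face
# velocities averaged from the node-centered field, so total concentration
# mass is conserved to roundoff in the absence of sources and reaction.
# Diffusion is the explicit centered 5-point stencil; the reaction (biofilm
# uptake) is explicit; source cells are re-clamped to c0 after each step.
#
# Mass convention: a grid cell's nutrient mass is c * h^2 per unit slab
# thickness, mirroring the discrete uptake term r_ij = -(1/h^2)(1/Y)
# (dM/dt) gamma_ij / sum(gamma), which carries only the 1/h^2 geometric
# factor. The micron-scale slab thickness enters the biomass bookkeeping
# (m0) but not the concentration update.

#' Build the nutrient source strip
#'
#' The source is one Eulerian grid width thick, sitting in the first grid row
#' above the wall (j = j_wall + 1). Configurations: \code{"none"} (no
#' source), \code{"full"} (entire bottom row), \code{"down"} (cells with
#' \code{x > biofilm_center_x + margin}), \code{"up"} (cells with
#' \code{x < biofilm_center_x - margin}).
#'
#' @param config a \code{sim_config} (uses \code{nutrient_config},
#'   \code{c0}, \code{margin}, grid geometry).
#' @param biofilm_center_x abscissa of the biofilm center (m); defaults to
#'   the configured value.
#' @return list of class \code{source_strip} with \code{cells} (linear
#'   indices into the Nx x Ny concentration matrix), \code{c0} and
#'   \code{active_from} (s).
#' @export
build_source <- function(config, biofilm_center_x = config$biofilm_center_x) {
  Nx <- config$Nx
  h <- config$h
  xg <- (seq_len(Nx) - 1) * h
  jrow <- 2L  # one grid width above the wall row at y = 0
  sel <- switch(config$nutrient_config,
                none = rep(FALSE, Nx),
                full = rep(TRUE, Nx),
                down = xg > biofilm_center_x + config$margin,
                up   = xg < biofilm_center_x - config$margin,
                stop("build_source: unknown nutrient_config '",
                     config$nutrient_config, "'"))
  out <- list(cells = which(sel) + (jrow - 1L) * Nx,
              c0 = config$c0, active_from = config$t_freeze)
  class(out) <- "source_strip"
  out
}

#' Nutrient concentration at Lagrangian nodes
#'
#' Averages the four corners of the Eulerian grid square containing each
#' node: the cell is \code{[max(x_i < X), max(x_i < X) + h]} in each
#' coordinate, so a node sitting exactly on a grid line belongs to the cell
#' on its lower-index side.
#'
#' @param cmat concentration matrix (Nx x Ny).
#' @param points Lagrangian positions (np x 2, m).
#' @param h grid spacing (m).
#' @return numeric vector of per-node concentrations (kg/m^3).
#' @export
concentration_at_nodes <- function(cmat, points, h) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  Nx <- nrow(cmat); Ny <- ncol(cmat)
  gi <- points[, 1] / h
  gj <- points[, 2] / h
  i0 <- ceiling(gi) - 1   # index of max{x_i < X}, 0-based
  j0 <- ceiling(gj) - 1
  i1 <- (i0 + 1) %% Nx; i0 <- i0 %% Nx
  j1 <- (j0 + 1) %% Ny; j0 <- j0 %% Ny
  (cmat[cbind(i0 + 1, j0 + 1)] + cmat[cbind(i1 + 1, j0 + 1)] +
     cmat[cbind(i0 + 1, j1 + 1)] + cmat[cbind(i1 + 1, j1 + 1)]) / 4
}

#' Eulerian grid points inside the biofilm polygon
#'
#' Point-in-polygon with on-edge points counted inside; grid indices wrap
#' periodically, so the polygon may extend past the domain edges. For a
#' polygon smaller than one cell the set may be empty; the caller (the
#' uptake step) then falls back to the grid point nearest the polygon
#' centroid.
#'
#' @param Nx,Ny grid counts.
#' @param h grid spacing (m).
#' @param polygon two-column matrix of boundary vertices (open ring).
#' @return integer vector of linear indices into the Nx x Ny matrix.
#' @export
uptake_region <- function(Nx, Ny, h, polygon) {
  if (nrow(polygon) < 3) stop("uptake_region: degenerate polygon")
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  is <- floor(xr[1] / h):ceiling(xr[2] / h)
  js <- floor(yr[1] / h):ceiling(yr[2] / h)
  gg <- expand.grid(i = is, j = js)
  inside <- points_in_polygon(gg$i * h, gg$j * h, polygon,
                              edge_tol = 1e-9 * h)
  ii <- gg$i[inside] %% Nx
  jj <- gg$j[inside] %% Ny
  sort(unique(ii + Nx * jj + 1L))
}

#' Discrete biofilm uptake (reaction) field
#'
#' Monod-weighted distribution of the nutrient demand over the uptake
#' region: \code{r_ij = -(1/h^2) (1/Y) (deltaM/dt) gamma_ij / sum(gamma)}
#' inside the region and zero outside, with
#' \code{gamma_ij = mu_max c_ij / (K + c_ij)}.
#'
#' @param cmat concentration matrix (Nx x Ny, kg/m^3).
#' @param region integer linear indices of the uptake region.
#' @param deltaM biomass increment this step (kg).
#' @param dt time step (s).
#' @param Y yield coefficient.
#' @param mu_max maximum specific growth rate (1/s).
#' @param K half-saturation constant (kg/m^3).
#' @param h grid spacing (m).
#' @return matrix (Nx x Ny) of reaction rates (kg/m^3/s).
#' @export
reaction_field <- function(cmat, region, deltaM, dt, Y, mu_max, K, h) {
  r <- matrix(0, nrow(cmat), ncol(cmat))
  if (deltaM == 0) return(r)
  if (length(region) == 0)
    stop("reaction_field: empty uptake region with nonzero deltaM")
  gam <- mu_max * cmat[region] / (K + cmat[region])
  sg <- sum(gam)
  if (sg <= 0)
    stop("reaction_field: zero Monod weight over region with nonzero deltaM")
  r[region] <- -(1 / h^2) * (1 / Y) * (deltaM / dt) * gam / sg
  r
}

#' One advection-diffusion-reaction step
#'
#' Explicit update: conservative first-order upwind advection, centered
#' 5-point diffusion, explicit reaction, non-negativity floor, then source
#' re-clamp. Stability requires \code{max|u| dt / h <= 1} and
#' \code{D_c dt / h^2 <= 0.25}; a violation aborts with the offending
#' numbers rather than stepping.
#'
#' Flooring: cells driven negative by the uptake demand are capped at zero
#' and the unmet demand is redistributed over the remaining region cells in
#' one extra pass (Monod-weighted); any residual is reported as unmet.
#'
#' @param cmat concentration matrix (kg/m^3).
#' @param u,v velocity matrices (m/s).
#' @param dt time step (s).
#' @param D_c diffusivity (m^2/s).
#' @param h grid spacing (m).
#' @param r reaction-rate matrix from \code{\link{reaction_field}}, or NULL.
#' @param region uptake-region indices (needed for the redistribution pass).
#' @param source a \code{source_strip} or NULL; clamped cells are reset to
#'   \code{c0} after the update.
#' @return list: \code{c} updated matrix, \code{consumed} nutrient mass
#'   actually removed this step (kg, unit-thickness convention),
#'   \code{unmet} demand that could not be met (kg).
#' @export
adr_step <- function(cmat, u, v, dt, D_c, h, r = NULL, region = NULL,
                     source = NULL) {
  Nx <- nrow(cmat); Ny <- ncol(cmat)
  amax <- max(abs(u), abs(v))
  if (amax * dt / h > 1)
    stop("adr_step: advective CFL violated, max|u|*dt/h = ",
         format(amax * dt / h))
  if (D_c * dt / h^2 > 0.25)
    stop("adr_step: diffusive stability violated, D*dt/h^2 = ",
         format(D_c * dt / h^2))
  ip <- c(2:Nx, 1); im <- c(Nx, 1:(Nx - 1))
  jp <- c(2:Ny, 1); jm <- c(Ny, 1:(Ny - 1))
  # east/north face fluxes (upwind on face-averaged velocity)
  ue <- (u + u[ip, , drop = FALSE]) / 2
  vn <- (v + v[, jp, drop = FALSE]) / 2
  pe <- ue > 0; pn <- vn > 0
  Fe <- ue * (pe * cmat + (!pe) * cmat[ip, , drop = FALSE])
  Gn <- vn * (pn * cmat + (!pn) * cmat[, jp, drop = FALSE])
  adv <- (Fe - Fe[im, , drop = FALSE] + Gn - Gn[, jm, drop = FALSE]) / h
  lap <- (cmat[ip, , drop = FALSE] + cmat[im, , drop = FALSE] +
            cmat[, jp, drop = FALSE] + cmat[, jm, drop = FALSE] -
            4 * cmat) / h^2
  cn <- cmat + dt * (-adv + D_c * lap)
  consumed <- 0
  unmet <- 0
  if (!is.null(r)) {
    demand <- -sum(r) * h^2 * dt          # kg, unit-thickness convention
    cn2 <- cn + dt * r
    neg <- cn2 < 0
    if (any(neg)) {
      shortfall <- -sum(cn2[neg]) * h^2    # kg that was not available
      cn2[neg] <- 0
      # one redistribution pass over remaining region cells
      if (!is.null(region)) {
        rem <- region[cn2[region] > 0]
        if (length(rem) > 0 && shortfall > 0) {
          gam <- cn2[rem] / (max(cn2[rem]) + .Machine$double.xmin)
          w <- gam / sum(gam)
          take <- pmin(shortfall * w / h^2, cn2[rem])
          cn2[rem] <- cn2[rem] - take
          short2 <- shortfall - sum(take) * h^2
          unmet <- max(short2, 0)
        } else unmet <- shortfall
      } else unmet <- shortfall
      consumed <- demand - unmet
    } else {
      consumed <- demand
    }
    cn <- cn2
  }
  cn[cn < 0] <- 0
  if (!is.null(source) && length(source$cells) > 0)
    cn[source$cells] <- source$c0
  list(c = cn, consumed = consumed, unmet = unmet)
}
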