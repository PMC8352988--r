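# Lagrangian biofilm mesh: DistMesh-style generation of the initial
# semicircular patch, plus the topology queries used by growth and analysis.
#
# The mesh is a plain list of class "biofilm_mesh":
#   pos       Q x 2 node coordinates (m)
#   pos0      Q x 2 creation coordinates (anchor/tether reference)
#   edges     S x 2 node index pairs (viscoelastic elements)
#   d0, d     creation and current rest lengths (m)
#   kind      per-element "stokes" or "maxwell"
#   tri       N x 3 triangle node indices (CCW)
#   anchored  logical Q, nodes tethered to the wall (initially on y = 0)
#   Q, S, N   counts; delta_N fractional-triangle accumulator
#   a0, m0    average initial triangle area (m^2) and biomass per triangle (kg)

# ---------------------------------------------------------------------------
# Delaunay triangulation (incremental Bowyer-Watson).
# Used by the mesh generator; input points carry a deterministic sub-spacing
# jitter, so degenerate cocircular configurations do not arise in practice.
delaunay_triangulate <- function(p) {
  n <- nrow(p)
  if (n < 3) stop("delaunay_triangulate: need at least 3 points")
  xmin <- min(p[, 1]); xmax <- max(p[, 1])
  ymin <- min(p[, 2]); ymax <- max(p[, 2])
  dmax <- max(xmax - xmin, ymax - ymin, .Machine$double.eps)
  cx <- (xmin + xmax) / 2; cy <- (ymin + ymax) / 2
  # super-triangle well outside the point cloud
  sup <- rbind(c(cx - 20 * dmax, cy - 10 * dmax),
               c(cx + 20 * dmax, cy - 10 * dmax),
               c(cx, cy + 20 * dmax))
  pts <- rbind(sup, p)
  cap <- 8 * n + 16
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- numeric(cap); ccy <- numeric(cap); cr2 <- numeric(cap)
  alive <- logical(cap)
  circ <- function(idx) {
    a <- pts[idx[1], ]; b <- pts[idx[2], ]; cc <- pts[idx[3], ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                cc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-300) return(c(0, 0, Inf))
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(cc^2)
    ux <- (a2 * (b[2] - cc[2]) + b2 * (cc[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (cc[1] - b[1]) + b2 * (a[1] - cc[1]) + c2 * (b[1] - a[1])) / d
    c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
  }
  tri[1, ] <- 1:3
  cc0 <- circ(1:3)
  ccx[1] <- cc0[1]; ccy[1] <- cc0[2]; cr2[1] <- cc0[3]
  alive[1] <- TRUE
  m <- 1L
  for (ip in seq_len(n)) {
    pi_ <- ip + 3L
    px <- pts[pi_, 1]; py <- pts[pi_, 2]
    act <- which(alive[seq_len(m)])
    bad <- act[(px - ccx[act])^2 + (py - ccy[act])^2 <=
                 cr2[act] * (1 + 1e-12)]
    if (length(bad) == 0) stop("delaunay_triangulate: point outside hull")
    bt <- tri[bad, , drop = FALSE]
    e1 <- cbind(bt[, 1], bt[, 2])
    e2 <- cbind(bt[, 2], bt[, 3])
    e3 <- cbind(bt[, 3], bt[, 1])
    ed <- rbind(e1, e2, e3)
    key <- pmin(ed[, 1], ed[, 2]) * (n + 4) + pmax(ed[, 1], ed[, 2])
    cnt <- table(key)
    once <- as.numeric(names(cnt)[cnt == 1])
    keep <- key %in% once
    bed <- ed[keep, , drop = FALSE]
    alive[bad] <- FALSE
    nnew <- nrow(bed)
    if (m + nnew > cap) {
      cap2 <- 2 * (m + nnew)
      tri <- rbind(tri, matrix(NA_integer_, cap2 - cap, 3))
      ccx <- c(ccx, numeric(cap2 - cap)); ccy <- c(ccy, numeric(cap2 - cap))
      cr2 <- c(cr2, numeric(cap2 - cap)); alive <- c(alive, logical(cap2 - cap))
      cap <- cap2
    }
    for (k in seq_len(nnew)) {
      m <- m + 1L
      tri[m, ] <- c(bed[k, 1], bed[k, 2], pi_)
      cc <- circ(tri[m, ])
      ccx[m] <- cc[1]; ccy[m] <- cc[2]; cr2[m] <- cc[3]
      alive[m] <- TRUE
    }
  }
  out <- tri[which(alive[seq_len(m)]), , drop = FALSE]
  out <- out[rowSums(out <= 3) == 0, , drop = FALSE] - 3L
  out
}

# deterministic pseudo-jitter in (-0.5, 0.5), no RNG stream use
.hash_frac <- function(i) {
  x <- sin(i * 12.9898 + 78.233) * 43758.5453
  (x - floor(x)) - 0.5
}

# signed distance to the upper half-disk (intersection of disk and y >= 0)
.fd_halfdisk <- function(p, rc, cx) {
  pmax(sqrt((p[, 1] - cx)^2 + p[, 2]^2) - rc, -p[, 2])
}

#' Generate the initial semicircular biofilm mesh
#'
#' Builds a quasi-uniform triangulation of the upper half-disk of radius
#' \code{r_c} centered at \code{(center_x, 0)} by DistMesh-style force-based
#' smoothing: points start on a hexagonal lattice, are retriangulated by
#' Delaunay whenever they have moved appreciably, pushed along repulsive
#' edge-spring forces with target length about \code{ds}, and projected back
#' onto the boundary when they escape. Nodes on the flat side \code{y = 0}
#' are pinned at exact spacing and marked anchored (wall contact). The average
#' initial triangle area is \code{a0 = (pi r_c^2 / 2) / N} and the biomass per
#' triangle \code{m0 = lambda_b * v0 * n0 * chi * a0}.
#'
#' @param r_c radius of the semicircle (m); must exceed \code{2 ds}.
#' @param ds target node spacing (m).
#' @param center_x abscissa of the semicircle center (m).
#' @param kind element kind for the initial connections, \code{"stokes"} or
#'   \code{"maxwell"}.
#' @param lambda_b bacterial mass density (kg/m^3).
#' @param v0 bacterium volume (m^3).
#' @param n0 bacterial number density (1/m^3).
#' @param chi slab thickness (m).
#' @param dptol,maxiter smoothing convergence tolerance (relative node
#'   displacement per iteration) and iteration cap.
#' @return a \code{biofilm_mesh} list; see the package overview.
#' @export
generate_semicircle_mesh <- function(r_c, ds, center_x,
                                     kind = "maxwell",
                                     lambda_b = 1120, v0 = 1.75e-18,
                                     n0 = 2.1e17, chi = 1e-6,
                                     dptol = 2e-3, maxiter = 400) {
  if (r_c <= 2 * ds) stop("generate_semicircle_mesh: need r_c > 2*ds")
  h0 <- ds
  geps <- 1e-3 * h0
  # pinned wall row at exact spacing
  nb <- max(4L, round(2 * r_c / h0))
  fixed <- cbind(seq(center_x - r_c, center_x + r_c, length.out = nb + 1), 0)
  # hexagonal interior lattice
  xg <- seq(center_x - r_c, center_x + r_c, by = h0)
  yg <- seq(h0 * sqrt(3) / 2, r_c, by = h0 * sqrt(3) / 2)
  pp <- expand.grid(x = xg, y = yg)
  odd <- (round(pp$y / (h0 * sqrt(3) / 2)) %% 2) == 1
  pp$x[odd] <- pp$x[odd] + h0 / 2
  p <- as.matrix(pp)
  keep <- .fd_halfdisk(p, r_c, center_x) < -0.3 * h0
  p <- p[keep, , drop = FALSE]
  if (nrow(p) > 0) {
    idx <- seq_len(nrow(p))
    p[, 1] <- p[, 1] + 2e-3 * h0 * .hash_frac(idx)
    p[, 2] <- p[, 2] + 2e-3 * h0 * .hash_frac(idx + 7919)
  }
  nfix <- nrow(fixed)
  p <- rbind(fixed, p)
  np <- nrow(p)
  deltat <- 0.2; Fscale <- 1.2; ttol <- 0.1
  pold <- p + 100 * h0
  tri <- NULL; bars <- NULL
  converged <- FALSE
  for (it in seq_len(maxiter)) {
    if (max(sqrt(rowSums((p - pold)^2))) > ttol * h0) {
      pold <- p
      tri <- delaunay_triangulate(p)
      cent <- (p[tri[, 1], , drop = FALSE] + p[tri[, 2], , drop = FALSE] +
                 p[tri[, 3], , drop = FALSE]) / 3
      tri <- tri[.fd_halfdisk(cent, r_c, center_x) < -geps, , drop = FALSE]
      ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
      key <- pmin(ed[, 1], ed[, 2]) * (np + 1) + pmax(ed[, 1], ed[, 2])
      bars <- ed[!duplicated(key), , drop = FALSE]
      bars <- cbind(pmin(bars[, 1], bars[, 2]), pmax(bars[, 1], bars[, 2]))
    }
    vec <- p[bars[, 1], , drop = FALSE] - p[bars[, 2], , drop = FALSE]
    L <- sqrt(rowSums(vec^2))
    L0 <- Fscale * sqrt(sum(L^2) / length(L))
    Fb <- pmax(L0 - L, 0)
    Fv <- vec * (Fb / L)
    Ft <- rowsum(rbind(Fv, -Fv), group = c(bars[, 1], bars[, 2]))
    Ftot <- matrix(0, np, 2)
    Ftot[as.integer(rownames(Ft)), ] <- Ft
    Ftot[seq_len(nfix), ] <- 0
    p <- p + deltat * Ftot
    # project escaped points back to the boundary
    d <- .fd_halfdisk(p, r_c, center_x)
    out <- d > 0
    if (any(out)) {
      he <- sqrt(.Machine$double.eps) * h0
      dx <- (.fd_halfdisk(cbind(p[out, 1] + he, p[out, 2]), r_c, center_x) -
               d[out]) / he
      dy <- (.fd_halfdisk(cbind(p[out, 1], p[out, 2] + he), r_c, center_x) -
               d[out]) / he
      g2 <- pmax(dx^2 + dy^2, .Machine$double.eps)
      p[out, 1] <- p[out, 1] - d[out] * dx / g2
      p[out, 2] <- p[out, 2] - d[out] * dy / g2
    }
    p[abs(p[, 2]) < 1e-9 * r_c, 2] <- 0
    interior <- .fd_halfdisk(p, r_c, center_x) < -geps
    disp <- deltat * sqrt(rowSums(Ftot^2))
    if (max(c(disp[interior], 0)) / h0 < dptol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("generate_semicircle_mesh: smoothing did not converge in ",
         maxiter, " iterations")
  # final triangulation on the settled points
  tri <- delaunay_triangulate(p)
  cent <- (p[tri[, 1], , drop = FALSE] + p[tri[, 2], , drop = FALSE] +
             p[tri[, 3], , drop = FALSE]) / 3
  tri <- tri[.fd_halfdisk(cent, r_c, center_x) < -geps, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(np); remap[used] <- seq_along(used)
  p <- p[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  # orient all triangles CCW
  cr <- (p[tri[, 2], 1] - p[tri[, 1], 1]) * (p[tri[, 3], 2] - p[tri[, 1], 2]) -
    (p[tri[, 2], 2] - p[tri[, 1], 2]) * (p[tri[, 3], 1] - p[tri[, 1], 1])
  flip <- cr < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  mesh_from_triangulation(p, tri, kind = kind, r_c = r_c,
                          lambda_b = lambda_b, v0 = v0, n0 = n0, chi = chi)
}

#' Assemble a biofilm mesh from points and triangles
#'
#' Derives the element (edge) list, rest lengths, anchored set and mass
#' bookkeeping from a triangulation. Exposed mainly for tests and for building
#' small hand-made meshes; simulations normally call
#' \code{\link{generate_semicircle_mesh}}.
#'
#' @param pos node coordinate matrix (Q x 2).
#' @param tri triangle index matrix (N x 3), CCW.
#' @param kind element kind, "stokes" or "maxwell".
#' @param r_c if non-NULL, \code{a0} is set to \code{(pi r_c^2/2)/N};
#'   otherwise to the mean triangle area.
#' @param lambda_b,v0,n0,chi biomass bookkeeping parameters (see
#'   \code{\link{generate_semicircle_mesh}}).
#' @param anchored optional logical vector; default marks nodes with
#'   \code{y == 0}.
#' @return a \code{biofilm_mesh} list.
#' @export
mesh_from_triangulation <- function(pos, tri, kind = "maxwell", r_c = NULL,
                                    lambda_b = 1120, v0 = 1.75e-18,
                                    n0 = 2.1e17, chi = 1e-6,
                                    anchored = NULL) {
  kind <- match.arg(kind, c("stokes", "maxwell"))
  pos <- unname(as.matrix(pos))
  Q <- nrow(pos)
  tri <- matrix(as.integer(tri), ncol = 3)
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  key <- ed[, 1] * (Q + 1) + ed[, 2]
  edges <- ed[!duplicated(key), , drop = FALSE]
  L <- sqrt(rowSums((pos[edges[, 2], , drop = FALSE] -
                       pos[edges[, 1], , drop = FALSE])^2))
  if (is.null(anchored)) anchored <- pos[, 2] == 0
  N <- nrow(tri)
  a0 <- if (!is.null(r_c)) (pi * r_c^2 / 2) / N else mean(triangle_areas(pos, tri))
  mesh <- list(pos = pos, pos0 = pos, edges = edges, d0 = L, d = L,
               kind = rep(kind, nrow(edges)), tri = tri,
               anchored = anchored, Q = Q, S = nrow(edges), N = N,
               delta_N = 0, a0 = a0,
               m0 = lambda_b * v0 * n0 * chi * a0)
  class(mesh) <- "biofilm_mesh"
  mesh
}

#' @export
print.biofilm_mesh <- function(x, ...) {
  cat("biofilm_mesh: Q =", x$Q, "nodes, S =", x$S, "elements, N =", x$N,
      "triangles (Q - S + N =", x$Q - x$S + x$N, ")\n")
  cat("  a0 =", format(x$a0, digits = 4), "m^2, m0 =",
      format(x$m0, digits = 4), "kg, delta_N =",
      format(x$delta_N, digits = 4), "\n")
  invisible(x)
}

#' Boundary cycle and fluid-contact set of the mesh
#'
#' Boundary edges are those belonging to exactly one triangle. The cycle is
#' returned counterclockwise, rotated to start at the downstream-most (max x)
#' anchored node. The fluid-contact set excludes anchored (wall-contact)
#' nodes but keeps them in the cycle for geometry.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @return list with \code{cycle} (ordered node indices) and \code{fluid}
#'   (the subset in contact with the fluid, in cycle order).
#' @export
boundary_nodes <- function(mesh) {
  tri <- mesh$tri
  Q <- mesh$Q
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- pmin(ed[, 1], ed[, 2]) * (Q + 1) + pmax(ed[, 1], ed[, 2])
  tab <- tabulate(match(key, unique(key)))
  ukey <- unique(key)
  bkey <- ukey[tab == 1]
  if (length(bkey) == 0) stop("boundary_nodes: mesh has no boundary edge")
  bed <- ed[match(bkey, key), , drop = FALSE]
  # adjacency walk
  nodes <- unique(as.vector(bed))
  nb <- vector("list", Q)
  for (k in seq_len(nrow(bed))) {
    a <- bed[k, 1]; b <- bed[k, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  deg <- lengths(nb[nodes])
  if (any(deg != 2))
    stop("boundary_nodes: boundary is not a single simple cycle")
  start <- nodes[1]
  cyc <- integer(length(nodes))
  cyc[1] <- start
  prev <- 0L
  cur <- start
  for (k in 2:length(nodes)) {
    nxt <- nb[[cur]]
    nxt <- nxt[nxt != prev][1]
    cyc[k] <- nxt
    prev <- cur
    cur <- nxt
  }
  if (polygon_signed_area(mesh$pos[cyc, , drop = FALSE]) < 0)
    cyc <- rev(cyc)
  anc <- which(mesh$anchored[cyc])
  if (length(anc) > 0) {
    s <- anc[which.max(mesh$pos[cyc[anc], 1])]
    cyc <- c(cyc[s:length(cyc)], cyc[seq_len(s - 1)])
  }
  list(cycle = cyc, fluid = cyc[!mesh$anchored[cyc]])
}

#' Biofilm boundary as a closed polygon
#'
#' @param mesh a \code{biofilm_mesh}.
#' @return two-column matrix of boundary vertices in CCW order (open ring).
#' @export
biofilm_polygon <- function(mesh) {
  bnd <- boundary_nodes(mesh)
  mesh$pos[bnd$cycle, , drop = FALSE]
}

#' Area-weighted center of mass of the biofilm
#'
#' Centroid under uniform mass density per unit area:
#' \code{sum(area_k centroid_k) / sum(area_k)} over triangles.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @return numeric length-2 (x, y) in meters.
#' @export
center_of_mass <- function(mesh) {
  ar <- triangle_areas(mesh$pos, mesh$tri)
  if (sum(ar) <= 0) stop("center_of_mass: degenerate mesh")
  cent <- (mesh$pos[mesh$tri[, 1], , drop = FALSE] +
             mesh$pos[mesh$tri[, 2], , drop = FALSE] +
             mesh$pos[mesh$tri[, 3], , drop = FALSE]) / 3
  unname(colSums(cent * ar) / sum(ar))
}

#' Triangle quality of the mesh
#'
#' Radius ratio 2 r_in / r_circ, 1 for equilateral triangles.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @return numeric vector of per-triangle qualities.
#' @export
mesh_quality <- function(mesh) {
  p <- mesh$pos; tri <- mesh$tri
  a <- sqrt(rowSums((p[tri[, 2], , drop = FALSE] - p[tri[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((p[tri[, 1], , drop = FALSE] - p[tri[, 3], , drop = FALSE])^2))
  cc <- sqrt(rowSums((p[tri[, 1], , drop = FALSE] - p[tri[, 2], , drop = FALSE])^2))
  (b + cc - a) * (cc + a - b) * (a + b - cc) / (a * b * cc)
}
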