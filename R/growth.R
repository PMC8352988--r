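# Stochastic boundary growth: nutrient uptake -> biomass -> new triangles.
#
# Each step the mean Monod rate over ALL mesh nodes sets the biomass
# increment dM = mean(Gamma) * N * m0 * dt; the fractional triangle
# accumulator Delta_N carries the residue, and floor(Delta_N + dM/m0) new
# triangles of area a0 are spawned on the fluid-contact boundary with
# probability proportional to the local Monod rate. A candidate triangle is
# isosceles on the base joining the chosen site and its clockwise neighbor;
# it merges with a nearby boundary node (ear fill), is rejected if it
# overlaps the biofilm or the wall, or else adds one new node.

#' Monod specific growth rate
#'
#' \code{Gamma = mu_max C / (K + C)}: monotone in C, bounded by mu_max.
#'
#' @param C local nutrient concentration (kg/m^3), vector ok.
#' @param mu_max maximum specific growth rate (1/s).
#' @param K half-saturation constant (kg/m^3).
#' @return specific growth rate (1/s).
#' @export
monod_rate <- function(C, mu_max, K) {
  mu_max * C / (K + C)
}

#' Biomass increment over one step
#'
#' Forward-Euler increment \code{dM = mean(Gamma) N m0 dt}, where the mean
#' runs over all Q mesh nodes (interior included) and \code{N m0} is the
#' biomass at the start of the step.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param node_rates per-node Monod rates (1/s, length Q).
#' @param dt time step (s).
#' @return biomass increment (kg).
#' @export
biomass_increment <- function(mesh, node_rates, dt) {
  if (mesh$Q < 1) stop("biomass_increment: empty mesh")
  mean(node_rates) * mesh$N * mesh$m0 * dt
}

#' Spawn-site probabilities on the fluid-contact boundary
#'
#' \code{p_m = Gamma_m / sum(Gamma)} over the fluid-contact set, zero
#' elsewhere. If every boundary rate is zero the distribution falls back to
#' uniform (flagged in the result) so that accumulated growth is not lost.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param node_rates per-node Monod rates (length Q).
#' @param bnd optional precomputed \code{\link{boundary_nodes}} result.
#' @return list: \code{p} probabilities in boundary (cycle) order over the
#'   fluid-contact set, \code{nodes} their node indices, \code{uniform_fallback}.
#' @export
spawn_probabilities <- function(mesh, node_rates, bnd = NULL) {
  if (is.null(bnd)) bnd <- boundary_nodes(mesh)
  if (length(bnd$fluid) == 0) stop("spawn_probabilities: empty boundary set")
  g <- node_rates[bnd$fluid]
  fallback <- FALSE
  if (sum(g) <= 0) {
    g <- rep(1, length(g))
    fallback <- TRUE
  }
  list(p = g / sum(g), nodes = bnd$fluid, uniform_fallback = fallback)
}

#' Sample a spawn site by inverse-CDF
#'
#' Draws xi uniform on (0,1) and returns the first index m with cumulative
#' probability at least xi (cumulative sums taken in boundary order).
#'
#' @param p probability vector (sums to 1).
#' @param xi optional uniform variate; drawn from the session RNG if absent.
#' @return integer index into \code{p}.
#' @export
sample_spawn_site <- function(p, xi = stats::runif(1)) {
  cs <- cumsum(p)
  idx <- findInterval(xi, cs, left.open = FALSE) + 1L
  min(idx, length(p))
}

#' Construct a candidate growth triangle
#'
#' The base joins the chosen site m' and its clockwise-adjacent boundary
#' neighbor m'' (the cycle predecessor under the canonical counterclockwise
#' ordering; if that neighbor is a wall-contact node, the counterclockwise
#' neighbor is used instead). The apex sits on the outward perpendicular
#' bisector of the base at height \code{2 a0 / b}, making the triangle area
#' exactly \code{a0}.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param m_prime boundary node index of the chosen site.
#' @param a0 target triangle area (m^2).
#' @param bnd optional precomputed boundary.
#' @return list: \code{apex} (x, y), \code{base} node index pair
#'   (m', m''), \code{height}, \code{base_length}.
#' @export
construct_candidate <- function(mesh, m_prime, a0 = mesh$a0, bnd = NULL) {
  if (is.null(bnd)) bnd <- boundary_nodes(mesh)
  cyc <- bnd$cycle
  k <- match(m_prime, cyc)
  if (is.na(k)) stop("construct_candidate: site not on boundary")
  n <- length(cyc)
  pred <- cyc[if (k == 1) n else k - 1]
  succ <- cyc[if (k == n) 1 else k + 1]
  m2 <- if (!mesh$anchored[pred]) pred else succ
  a <- mesh$pos[m_prime, ]
  b <- mesh$pos[m2, ]
  base <- sqrt(sum((b - a)^2))
  if (base == 0) stop("construct_candidate: zero-length base")
  mid <- (a + b) / 2
  # outward normal: boundary is CCW, interior on the left of the walk
  # direction, so the right-hand normal of the edge (m'' -> m') points out
  dirv <- (a - b) / base
  nrm <- if (!mesh$anchored[pred]) c(dirv[2], -dirv[1]) else c(-dirv[2], dirv[1])
  hgt <- 2 * a0 / base
  list(apex = mid + hgt * nrm, base = c(m_prime, m2),
       height = hgt, base_length = base)
}

# does the mesh already contain edge (a, b)?
.has_edge <- function(mesh, a, b) {
  any(mesh$edges[, 1] == min(a, b) & mesh$edges[, 2] == max(a, b))
}

# number of triangles incident on edge (a, b): 1 = boundary, 2 = interior
.edge_tri_count <- function(mesh, a, b) {
  tri <- mesh$tri
  sum((tri[, 1] == a | tri[, 2] == a | tri[, 3] == a) &
        (tri[, 1] == b | tri[, 2] == b | tri[, 3] == b))
}

#' Attempt to realize a candidate triangle
#'
#' Outcomes: \code{"merged"} if the apex lies within \code{epsilon_merge} of
#' an existing boundary node that forms an ear with the base (exactly one
#' missing edge, so the Euler characteristic is preserved);
#' \code{"rejected"} if the candidate would overlap the biofilm interior,
#' cross the boundary, or dip below the wall; \code{"apex_spawned"}
#' otherwise, appending one node, two elements and one triangle.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param candidate result of \code{\link{construct_candidate}}.
#' @param epsilon_merge merge distance (m).
#' @param wall_y wall height (m); candidates reaching \code{y <= wall_y}
#'   are rejected.
#' @param kind element kind for new connections.
#' @param bnd optional precomputed boundary.
#' @return list: \code{mesh} (possibly updated), \code{outcome}.
#' @export
try_spawn <- function(mesh, candidate, epsilon_merge, wall_y = 0,
                      kind = "maxwell", bnd = NULL) {
  if (is.null(bnd)) bnd <- boundary_nodes(mesh)
  apex <- candidate$apex
  m1 <- candidate$base[1]; m2 <- candidate$base[2]
  cyc <- bnd$cycle
  poly <- mesh$pos[cyc, , drop = FALSE]
  tol <- 1e-9 * candidate$base_length
  # merge: nearest boundary node within epsilon that forms an ear
  others <- setdiff(cyc, c(m1, m2))
  if (length(others) > 0) {
    d2 <- (mesh$pos[others, 1] - apex[1])^2 + (mesh$pos[others, 2] - apex[2])^2
    j <- which.min(d2)
    if (d2[j] <= epsilon_merge^2) {
      m3 <- others[j]
      # the shared edge must be a boundary edge (one incident triangle) and
      # the third edge absent, so the fill is an ear and Euler is preserved
      e13 <- .has_edge(mesh, m1, m3) && .edge_tri_count(mesh, m1, m3) == 1
      e23 <- .has_edge(mesh, m2, m3) && .edge_tri_count(mesh, m2, m3) == 1
      if (xor(e13, e23) &&
          !(.has_edge(mesh, m1, m3) && .has_edge(mesh, m2, m3))) {
        newe <- if (e13) c(min(m2, m3), max(m2, m3)) else
          c(min(m1, m3), max(m1, m3))
        # reject degenerate ears
        ar <- abs((mesh$pos[m2, 1] - mesh$pos[m1, 1]) *
                    (mesh$pos[m3, 2] - mesh$pos[m1, 2]) -
                    (mesh$pos[m2, 2] - mesh$pos[m1, 2]) *
                    (mesh$pos[m3, 1] - mesh$pos[m1, 1])) / 2
        if (ar > tol * candidate$base_length) {
          L <- sqrt(sum((mesh$pos[newe[2], ] - mesh$pos[newe[1], ])^2))
          mesh$edges <- rbind(mesh$edges, newe)
          mesh$d0 <- c(mesh$d0, L)
          mesh$d <- c(mesh$d, L)
          mesh$kind <- c(mesh$kind, kind)
          mesh$tri <- rbind(mesh$tri, c(m1, m2, m3))
          mesh$S <- mesh$S + 1L
          mesh$N <- mesh$N + 1L
          return(list(mesh = mesh, outcome = "merged"))
        }
      }
      return(list(mesh = mesh, outcome = "rejected"))
    }
  }
  # wall overlap
  if (apex[2] <= wall_y) return(list(mesh = mesh, outcome = "rejected"))
  # biofilm overlap: apex inside the polygon, or a new edge crossing it
  if (points_in_polygon(apex[1], apex[2], poly, edge_tol = tol))
    return(list(mesh = mesh, outcome = "rejected"))
  if (segment_crosses_boundary(mesh$pos[m1, ], apex, poly, tol) ||
      segment_crosses_boundary(mesh$pos[m2, ], apex, poly, tol))
    return(list(mesh = mesh, outcome = "rejected"))
  # spawn a new node
  qn <- mesh$Q + 1L
  mesh$pos <- rbind(mesh$pos, apex)
  mesh$pos0 <- rbind(mesh$pos0, apex)
  mesh$anchored <- c(mesh$anchored, FALSE)
  L1 <- sqrt(sum((apex - mesh$pos[m1, ])^2))
  L2 <- sqrt(sum((apex - mesh$pos[m2, ])^2))
  mesh$edges <- rbind(mesh$edges,
                      c(min(m1, qn), max(m1, qn)),
                      c(min(m2, qn), max(m2, qn)))
  mesh$d0 <- c(mesh$d0, L1, L2)
  mesh$d <- c(mesh$d, L1, L2)
  mesh$kind <- c(mesh$kind, kind, kind)
  mesh$tri <- rbind(mesh$tri, c(m1, m2, qn))
  mesh$Q <- qn
  mesh$S <- mesh$S + 2L
  mesh$N <- mesh$N + 1L
  list(mesh = mesh, outcome = "apex_spawned")
}

#' One growth step
#'
#' Computes per-node concentrations and Monod rates, the biomass increment
#' dM, then performs \code{floor(Delta_N + dM/m0)} spawn attempts (with a
#' retry budget of \code{10 |B|} resamples per spawn; untaken growth is
#' deferred through Delta_N rather than lost). Returns the updated mesh,
#' ledger, and dM for the transport reaction.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param ledger growth ledger list (\code{M}, \code{cumulative_consumed},
#'   \code{unmet}); see \code{\link{new_ledger}}.
#' @param cmat concentration matrix (kg/m^3).
#' @param dt time step (s).
#' @param config a \code{sim_config} (uses mu_max, K, epsilon_merge,
#'   element kind, wall_y = 0, grid spacing).
#' @return list: \code{mesh}, \code{ledger}, \code{deltaM},
#'   \code{spawned}, \code{deferred}.
#' @export
growth_step <- function(mesh, ledger, cmat, dt, config) {
  Cm <- concentration_at_nodes(cmat, mesh$pos, config$h)
  rates <- monod_rate(Cm, config$mu_max, config$K)
  deltaM <- biomass_increment(mesh, rates, dt)
  dN <- deltaM / mesh$m0
  navail <- floor(mesh$delta_N + dN)
  spawned <- 0L
  if (navail >= 1) {
    kind <- if (is.finite(config$eta)) "maxwell" else "stokes"
    for (ns in seq_len(navail)) {
      bnd <- boundary_nodes(mesh)
      sp <- spawn_probabilities(mesh, rates, bnd = bnd)
      budget <- 10L * length(sp$nodes)
      ok <- FALSE
      for (try_i in seq_len(budget)) {
        site <- sp$nodes[sample_spawn_site(sp$p)]
        cand <- construct_candidate(mesh, site, mesh$a0, bnd = bnd)
        res <- try_spawn(mesh, cand, config$epsilon_merge, wall_y = 0,
                         kind = kind, bnd = bnd)
        if (res$outcome != "rejected") {
          mesh <- res$mesh
          ok <- TRUE
          break
        }
      }
      if (!ok) break  # defer the remainder via delta_N
      spawned <- spawned + 1L
      # rates for nodes added this step: evaluate at their position
      if (mesh$Q > length(rates)) {
        newidx <- (length(rates) + 1):mesh$Q
        Cnew <- concentration_at_nodes(cmat,
                                       mesh$pos[newidx, , drop = FALSE],
                                       config$h)
        rates <- c(rates, monod_rate(Cnew, config$mu_max, config$K))
      }
    }
  }
  mesh$delta_N <- mesh$delta_N + dN - spawned
  ledger$M <- (mesh$N + mesh$delta_N) * mesh$m0
  list(mesh = mesh, ledger = ledger, deltaM = deltaM,
       spawned = spawned, deferred = navail - spawned)
}

#' Create a growth ledger
#'
#' @param mesh the initial \code{biofilm_mesh}.
#' @return list with biomass \code{M}, \code{cumulative_consumed} and
#'   \code{unmet} nutrient masses (kg).
#' @export
new_ledger <- function(mesh) {
  list(M = (mesh$N + mesh$delta_N) * mesh$m0,
       cumulative_consumed = 0, unmet = 0)
}
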