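# Lagrangian force laws: biofilm Stokes/Maxwell elements, wall chains,
# anchors, temporary freeze tethers, and the Maxwell rest-length evolution.
#
# An element connecting nodes m and m' carries the force
#   F = d0^2 * E * (||X_m' - X_m|| / d(t) - 1) * unit(X_m' - X_m)
# on node m (equal and opposite on m'), with d(t) the evolving rest length.
# The prefactor d0^2 E makes the spring constant k = E d0 for small strain,
# so the element modulus is the material elastic modulus E directly.

#' Force of a single viscoelastic element
#'
#' @param Xm,Xm2 endpoint coordinates (length-2 vectors, m).
#' @param d0 creation rest length (m).
#' @param d current rest length (m).
#' @param E elastic modulus (Pa).
#' @return force on node m (N); the force on m' is its negative.
#' @export
element_force <- function(Xm, Xm2, d0, d, E) {
  v <- Xm2 - Xm
  L <- sqrt(sum(v^2))
  if (L == 0) stop("element_force: coincident endpoints")
  d0^2 * E * (L / d - 1) * v / L
}

#' Accumulate all element forces per node
#'
#' Vectorized sum of the viscoelastic element forces acting on every node.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param E elastic modulus (Pa).
#' @return matrix (Q x 2) of per-node forces (N).
#' @export
element_forces_all <- function(mesh, E) {
  e1 <- mesh$edges[, 1]; e2 <- mesh$edges[, 2]
  v <- mesh$pos[e2, , drop = FALSE] - mesh$pos[e1, , drop = FALSE]
  L <- sqrt(rowSums(v^2))
  mag <- mesh$d0^2 * E * (L / mesh$d - 1) / L
  fv <- v * mag
  acc <- rowsum(rbind(fv, -fv), group = c(e1, e2))
  out <- matrix(0, mesh$Q, 2)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' Forward-Euler update of a Maxwell element's rest length
#'
#' The dashpot stretches at a rate proportional to the spring force:
#' \code{d <- d + dt * (E d0 / eta) * (L/d - 1)}. The fixed point is
#' \code{L == d}; in the limit \code{eta -> Inf} the rest length is constant
#' and the element is a purely elastic (Stokes) spring.
#'
#' @param d current rest length (m).
#' @param current_length instantaneous element length (m).
#' @param d0 creation rest length (m).
#' @param E elastic modulus (Pa).
#' @param eta dashpot viscosity (Pa s); \code{Inf} bypasses the update.
#' @param dt time step (s).
#' @return updated rest length (m).
#' @export
update_rest_length <- function(d, current_length, d0, E, eta, dt) {
  if (!is.finite(eta)) return(d)
  d + dt * (E * d0 / eta) * (current_length / d - 1)
}

#' Rest-length update over all Maxwell elements of a mesh
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param E elastic modulus (Pa).
#' @param eta dashpot viscosity (Pa s); \code{Inf} is a no-op.
#' @param dt time step (s).
#' @return the mesh with updated rest lengths.
#' @export
update_rest_lengths <- function(mesh, E, eta, dt) {
  if (!is.finite(eta)) return(mesh)
  mx <- mesh$kind == "maxwell"
  if (!any(mx)) return(mesh)
  e <- mesh$edges[mx, , drop = FALSE]
  L <- sqrt(rowSums((mesh$pos[e[, 2], , drop = FALSE] -
                       mesh$pos[e[, 1], , drop = FALSE])^2))
  mesh$d[mx] <- mesh$d[mx] +
    dt * (E * mesh$d0[mx] / eta) * (L / mesh$d[mx] - 1)
  mesh
}

#' Create a wall chain
#'
#' A straight chain of Lagrangian nodes at height \code{y}, spaced \code{d_w}
#' across the periodic channel length \code{Lx}. Neighboring nodes are joined
#' by stiff springs (stiffness \code{A}) and every node is tethered to its
#' initial position (stiffness \code{B}); together these impose the no-slip
#' condition at the wall.
#'
#' @param Lx channel length (m).
#' @param d_w node spacing (m); \code{Lx/d_w} is rounded to an integer count.
#' @param y wall height (m).
#' @param A neighbor-spring stiffness (N/m).
#' @param B tether stiffness (N/m).
#' @return list of class \code{wall_chain}.
#' @export
wall_chain <- function(Lx, d_w, y = 0, A, B) {
  nw <- max(4L, round(Lx / d_w))
  xs <- (seq_len(nw) - 1) * (Lx / nw)
  pos <- cbind(xs, rep(y, nw))
  dimnames(pos) <- NULL
  w <- list(pos = pos, pos0 = pos, d_w = Lx / nw, Lx = Lx, A = A, B = B)
  class(w) <- "wall_chain"
  w
}

#' Wall chain forces
#'
#' Sum of neighbor-spring forces (both neighbors; the chain wraps
#' periodically in x) and tether forces to the initial positions.
#'
#' @param wall a \code{wall_chain}.
#' @return matrix (n x 2) of per-node forces (N).
#' @export
wall_forces <- function(wall) {
  p <- wall$pos
  n <- nrow(p)
  if (n < 2) stop("wall_forces: chain needs at least 2 nodes")
  nxt <- c(2:n, 1)
  v <- p[nxt, , drop = FALSE] - p
  # minimal-image wrap across the periodic seam
  v[, 1] <- v[, 1] - wall$Lx * round(v[, 1] / wall$Lx)
  L <- sqrt(rowSums(v^2))
  fmag <- wall$A * (L - wall$d_w) / L
  fspring <- v * fmag            # force on node i from its next neighbor
  f <- fspring - fspring[c(n, 1:(n - 1)), , drop = FALSE]
  f + wall$B * (wall$pos0 - p)
}

#' Anchor tether forces on wall-contact biofilm nodes
#'
#' \code{F = C (X_0m - X_m)} on anchored nodes, zero elsewhere.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param C tether stiffness (N/m).
#' @return matrix (Q x 2) of forces (N).
#' @export
anchor_forces <- function(mesh, C) {
  f <- matrix(0, mesh$Q, 2)
  a <- mesh$anchored
  if (any(a))
    f[a, ] <- C * (mesh$pos0[a, , drop = FALSE] - mesh$pos[a, , drop = FALSE])
  f
}

#' Temporary freeze tethers during flow development
#'
#' For \code{t < t_freeze} every biofilm node is tethered to its initial
#' position with stiffness \code{D}; the release at \code{t_freeze} uses the
#' half-open convention, so the force is identically zero for
#' \code{t >= t_freeze}.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param D tether stiffness (N/m).
#' @param t current time (s).
#' @param t_freeze hold duration (s).
#' @return matrix (Q x 2) of forces (N).
#' @export
freeze_forces <- function(mesh, D, t, t_freeze) {
  if (t >= t_freeze) return(matrix(0, mesh$Q, 2))
  D * (mesh$pos0 - mesh$pos)
}

#' Dashpot viscosity for a target relaxation time
#'
#' The creep relaxation time is \code{tau = eta_axial / E} with the effective
#' axial viscosity \code{eta_axial = eta (1 + eta_water / (2 eta))}, where
#' \code{eta_water} is the fluid-drag correction of a Lagrangian node.
#' Inverting gives \code{eta = E tau - eta_water / 2}.
#'
#' @param E elastic modulus (Pa).
#' @param tau target relaxation time (s); must satisfy
#'   \code{E tau > eta_water / 2}.
#' @param eta_water fluid-drag viscosity correction (Pa s).
#' @return dashpot viscosity eta (Pa s).
#' @export
dashpot_viscosity_for_tau <- function(E, tau, eta_water = 1.02e3) {
  if (E * tau <= eta_water / 2)
    stop("dashpot_viscosity_for_tau: relaxation time unachievable, ",
         "need E*tau > eta_water/2")
  E * tau - eta_water / 2
}

#' Relaxation time of a Maxwell element network
#'
#' Forward form of the creep calibration:
#' \code{tau = eta (1 + eta_water/(2 eta)) / E}.
#'
#' @inheritParams dashpot_viscosity_for_tau
#' @param eta dashpot viscosity (Pa s).
#' @return relaxation time (s); \code{Inf} for a Stokes network.
#' @export
relaxation_time <- function(E, eta, eta_water = 1.02e3) {
  if (!is.finite(eta)) return(Inf)
  eta * (1 + eta_water / (2 * eta)) / E
}

#' Total elastic energy of the element network
#'
#' Sum of (1/2) k (L - d)^2 over elements with k = E d0^2 / d; a
#' dissipation diagnostic (non-increasing without driving or growth).
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param E elastic modulus (Pa).
#' @return energy (J, unit-thickness convention).
#' @export
elastic_energy <- function(mesh, E) {
  e <- mesh$edges
  L <- sqrt(rowSums((mesh$pos[e[, 2], , drop = FALSE] -
                       mesh$pos[e[, 1], , drop = FALSE])^2))
  sum(0.5 * E * mesh$d0^2 / mesh$d * (L - mesh$d)^2)
}
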