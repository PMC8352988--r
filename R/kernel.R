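# Regularized delta kernel and Lagrangian <-> Eulerian transfer operators.
#
# Grid convention: node-centered, doubly periodic points x_ij = (i*h, j*h)
# with i in [0, Nx), j in [0, Ny). Matrices are indexed [i+1, j+1]. All kernel
# support wraps modulo the grid size.
#
# Force bookkeeping: Lagrangian forces are point forces in newtons; spreading
# divides by h^2 (the 2D regularized delta), giving an Eulerian force per
# area for a unit-thickness slab. The micron-scale slab thickness enters only
# the biomass bookkeeping, not the hydrodynamics.

#' Peskin four-point kernel
#'
#' The piecewise regularized delta weight with compact support on
#' \code{|r| < 2}; continuous at \code{|r| = 1} and \code{|r| = 2} and a
#' partition of unity over integer shifts.
#'
#' @param r dimensionless offset (vector ok).
#' @return kernel weights.
#' @export
ib_phi <- function(r) {
  a <- abs(r)
  w <- numeric(length(a))
  i1 <- a <= 1
  i2 <- a > 1 & a < 2
  w[i1] <- (3 - 2 * a[i1] + sqrt(1 + 4 * a[i1] - 4 * a[i1]^2)) / 8
  w[i2] <- (5 - 2 * a[i2] - sqrt(-7 + 12 * a[i2] - 4 * a[i2]^2)) / 8
  dim(w) <- dim(r)
  w
}

# 16-point stencil (linear indices + weights) for a set of Lagrangian points.
# Returns list(lin = np x 16 matrix of 1-based linear indices, w = weights).
ib_stencil <- function(px, py, Nx, Ny, h) {
  gx <- px / h
  gy <- py / h
  i0 <- floor(gx)
  j0 <- floor(gy)
  offs <- -1:2
  ox <- outer(i0, offs, "+")          # np x 4
  oy <- outer(j0, offs, "+")
  wx <- ib_phi(gx - ox)
  wy <- ib_phi(gy - oy)
  ix <- ox %% Nx
  iy <- oy %% Ny
  cx <- rep(1:4, times = 4)
  cy <- rep(1:4, each = 4)
  lin <- ix[, cx, drop = FALSE] + Nx * iy[, cy, drop = FALSE] + 1
  w <- wx[, cx, drop = FALSE] * wy[, cy, drop = FALSE]
  list(lin = lin, w = w)
}

#' Spread Lagrangian point forces onto the Eulerian grid
#'
#' Computes \code{f(x_ij) = sum_m F_m * phi((x_i - X_m)/h) *
#' phi((y_j - Y_m)/h) / h^2} with periodic wrapping of the kernel support.
#' Total force is conserved: \code{sum(f) * h^2} equals the summed point
#' forces componentwise.
#'
#' @param points matrix (np x 2) of Lagrangian positions (m).
#' @param forces matrix (np x 2) of point forces (N).
#' @param Nx,Ny grid counts.
#' @param h grid spacing (m).
#' @return list with matrices \code{fx}, \code{fy} (Nx x Ny).
#' @export
spread_forces <- function(points, forces, Nx, Ny, h, stencil = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  if (!is.matrix(forces)) forces <- matrix(forces, ncol = 2)
  if (nrow(points) != nrow(forces))
    stop("spread_forces: points and forces must have the same number of rows")
  fx <- matrix(0, Nx, Ny)
  fy <- matrix(0, Nx, Ny)
  if (nrow(points) == 0) return(list(fx = fx, fy = fy))
  st <- if (is.null(stencil))
    ib_stencil(points[, 1], points[, 2], Nx, Ny, h) else stencil
  wv <- as.vector(st$w) / (h * h)
  vals <- cbind(wv * rep(forces[, 1], 16), wv * rep(forces[, 2], 16))
  acc <- rowsum(vals, group = as.vector(st$lin))
  idx <- as.integer(rownames(acc))
  fx[idx] <- acc[, 1]
  fy[idx] <- acc[, 2]
  list(fx = fx, fy = fy)
}

#' Interpolate Eulerian velocity to Lagrangian points
#'
#' \code{U(X_m) = sum_ij u(x_ij) delta_h(x_ij - X_m) h^2}. The kernel's
#' partition-of-unity property makes interpolation of a constant field exact,
#' and the operator is the adjoint (up to \code{h^2}) of
#' \code{\link{spread_forces}}.
#'
#' @param u,v velocity component matrices (Nx x Ny).
#' @param points matrix (np x 2) of Lagrangian positions (m).
#' @param h grid spacing (m).
#' @return matrix (np x 2) of point velocities.
#' @export
interp_velocity <- function(u, v, points, h, stencil = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  Nx <- nrow(u); Ny <- ncol(u)
  if (nrow(points) == 0) return(matrix(0, 0, 2))
  st <- if (is.null(stencil))
    ib_stencil(points[, 1], points[, 2], Nx, Ny, h) else stencil
  np <- nrow(points)
  uv <- matrix(u[st$lin], np, 16)
  vv <- matrix(v[st$lin], np, 16)
  cbind(rowSums(st$w * uv), rowSums(st$w * vv))
}
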