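# Incompressible Navier-Stokes on the doubly periodic node-centered grid.
#
# Time integrator: semi-implicit spectral projection. Advection is
# pseudo-spectral (2/3-rule dealiased) and explicit; diffusion is implicit;
# the projection onto divergence-free fields is exact in spectral space. At
# the Reynolds numbers of these simulations (Re <= 8e-4) the advection term
# is dynamically negligible, but it is always computed.

#' Create an Eulerian field
#'
#' Node-centered doubly periodic grid with points (i h, j h), i in [0, Nx),
#' j in [0, Ny). Holds velocity (u, v), pressure p, nutrient concentration c,
#' and cached spectral operators.
#'
#' @param Nx,Ny grid counts.
#' @param h grid spacing (m).
#' @return list of class \code{eulerian_field}.
#' @export
make_field <- function(Nx, Ny, h) {
  freqx <- c(0:floor(Nx / 2), -(ceiling(Nx / 2) - 1):-1)
  freqy <- c(0:floor(Ny / 2), -(ceiling(Ny / 2) - 1):-1)
  kx <- 2 * pi * freqx / (Nx * h)
  ky <- 2 * pi * freqy / (Ny * h)
  KX <- matrix(kx, Nx, Ny)
  KY <- matrix(ky, Nx, Ny, byrow = TRUE)
  K2 <- KX^2 + KY^2
  K2g <- K2; K2g[1, 1] <- 1           # guarded for the projection division
  # odd (derivative/projection) operators zero the Nyquist mode so that
  # spectra of real fields stay conjugate-symmetric under multiplication
  kxd <- kx; if (Nx %% 2 == 0) kxd[Nx / 2 + 1] <- 0
  kyd <- ky; if (Ny %% 2 == 0) kyd[Ny / 2 + 1] <- 0
  KXd <- matrix(kxd, Nx, Ny)
  KYd <- matrix(kyd, Nx, Ny, byrow = TRUE)
  K2d <- KXd^2 + KYd^2; K2dg <- K2d; K2dg[K2dg == 0] <- 1
  deal <- outer(abs(freqx) <= Nx / 3, abs(freqy) <= Ny / 3) * 1
  f <- list(Nx = Nx, Ny = Ny, h = h,
            u = matrix(0, Nx, Ny), v = matrix(0, Nx, Ny),
            p = matrix(0, Nx, Ny), c = matrix(0, Nx, Ny),
            Uh = NULL, Vh = NULL, spec_ok = FALSE,
            ops = list(KX = KXd, KY = KYd, K2 = K2, K2g = K2dg,
                       dealias = deal,
                       revx = c(1, Nx:2), revy = c(1, Ny:2),
                       npts = Nx * Ny))
  class(f) <- "eulerian_field"
  f
}

# forward FFT of two real fields packed into one complex transform
fft2_pair <- function(a, b, ops) {
  Z <- stats::fft(a + 1i * b)
  Zr <- Conj(Z[ops$revx, ops$revy])
  list(A = (Z + Zr) / 2, B = (Z - Zr) / (2i))
}

# inverse FFT returning two real fields from their packed spectra
ifft2_pair <- function(Ahat, Bhat, ops) {
  z <- stats::fft(Ahat + 1i * Bhat, inverse = TRUE) / ops$npts
  list(a = Re(z), b = Im(z))
}

#' Poiseuille driving acceleration
#'
#' The uniform body-force acceleration that produces a steady 2D Poiseuille
#' profile with maximum speed \code{u_max} between walls a distance \code{Ly}
#' apart: \code{g = 8 mu u_max / (rho Ly^2)}.
#'
#' @param u_max target maximum channel speed (m/s).
#' @param Ly wall separation (m).
#' @param mu fluid dynamic viscosity (Pa s).
#' @param rho fluid density (kg/m^3).
#' @return acceleration g (m/s^2).
#' @export
poiseuille_g <- function(u_max, Ly, mu, rho) {
  8 * mu * u_max / (rho * Ly^2)
}

#' Reynolds number of the biofilm in channel flow
#'
#' \code{Re = rho r_c u_max / mu}.
#'
#' @param rho fluid density (kg/m^3).
#' @param r_c biofilm radius (m).
#' @param u_max maximum channel speed (m/s).
#' @param mu dynamic viscosity (Pa s).
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, r_c, u_max, mu) {
  rho * r_c * u_max / mu
}

#' One Navier-Stokes time step
#'
#' Advances the velocity field by \code{dt} under the immersed-boundary body
#' force \code{(fx, fy)} (force per area, unit-thickness convention) and a
#' uniform driving acceleration \code{gx} in x. Explicit dealiased
#' pseudo-spectral advection, implicit diffusion, exact spectral projection.
#' The post-step discrete (spectral) divergence is zero to solver roundoff.
#'
#' @param field an \code{eulerian_field}.
#' @param fx,fy immersed-boundary force density matrices (or NULL).
#' @param dt time step (s).
#' @param mu dynamic viscosity (Pa s).
#' @param rho fluid density (kg/m^3).
#' @param gx uniform driving acceleration (m/s^2).
#' @return the updated field.
#' @note The field caches the velocity spectrum between steps. If you assign
#'   \code{u} or \code{v} directly, set \code{field$spec_ok <- FALSE} so the
#'   next step retransforms them.
#' @export
ns_step <- function(field, fx = NULL, fy = NULL, dt, mu, rho, gx = 0) {
  ops <- field$ops
  nu <- mu / rho
  if (isTRUE(field$spec_ok)) {
    Uh <- field$Uh; Vh <- field$Vh
  } else {
    uv <- fft2_pair(field$u, field$v, ops)
    Uh <- uv$A; Vh <- uv$B
  }
  # velocity gradients
  gu <- ifft2_pair(1i * ops$KX * Uh, 1i * ops$KY * Uh, ops)
  gv <- ifft2_pair(1i * ops$KX * Vh, 1i * ops$KY * Vh, ops)
  advx <- field$u * gu$a + field$v * gu$b
  advy <- field$u * gv$a + field$v * gv$b
  adv <- fft2_pair(advx, advy, ops)
  rhsU <- Uh - dt * adv$A * ops$dealias
  rhsV <- Vh - dt * adv$B * ops$dealias
  if (!is.null(fx)) {
    fh <- fft2_pair(fx, fy, ops)
    rhsU <- rhsU + (dt / rho) * fh$A
    rhsV <- rhsV + (dt / rho) * fh$B
  }
  if (gx != 0) rhsU[1, 1] <- rhsU[1, 1] + dt * gx * ops$npts
  den <- 1 + nu * dt * ops$K2
  Uh <- rhsU / den
  Vh <- rhsV / den
  # projection
  divh <- 1i * (ops$KX * Uh + ops$KY * Vh)
  phih <- -divh / ops$K2g
  phih[1, 1] <- 0
  Uh <- Uh - 1i * ops$KX * phih
  Vh <- Vh - 1i * ops$KY * phih
  out <- ifft2_pair(Uh, Vh, ops)
  field$u <- out$a
  field$v <- out$b
  field$Uh <- Uh
  field$Vh <- Vh
  field$spec_ok <- TRUE
  field$phih <- phih * (rho / dt)
  field
}

#' Pressure field of the last projection step
#'
#' Recovers the real-space pressure from the most recent \code{\link{ns_step}}
#' projection (computed lazily to keep the inner loop lean).
#'
#' @param field an \code{eulerian_field} advanced at least once.
#' @return pressure matrix (Pa).
#' @export
field_pressure <- function(field) {
  if (is.null(field$phih)) return(field$p)
  pr <- ifft2_pair(field$phih, 0 * field$phih, field$ops)
  pr$a
}

#' Maximum discrete divergence of the velocity field
#'
#' Spectral divergence, max norm; a projection-quality diagnostic.
#'
#' @param field an \code{eulerian_field}.
#' @return max |div u|.
#' @export
field_divergence <- function(field) {
  ops <- field$ops
  uv <- fft2_pair(field$u, field$v, ops)
  divh <- 1i * (ops$KX * uv$A + ops$KY * uv$B)
  d <- ifft2_pair(divh, 0 * divh, ops)
  max(abs(d$a))
}
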