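# Post-processing of trajectory records into migration rates, biomass
# ratios and the stiffness crossover.

#' Center-of-mass migration rate
#'
#' Ordinary least-squares slope of the center-of-mass coordinate versus
#' time over the stated window, reported in mm/h together with the
#' residual RMS.
#'
#' @param records trajectory data.frame from \code{\link{run_simulation}}
#'   (columns \code{t}, \code{com_x}, \code{com_y}).
#' @param axis \code{"x"} or \code{"y"}.
#' @param window numeric length-2 (t_start, t_end) in seconds; default the
#'   full record range.
#' @return list of class \code{migration_fit}: \code{slope} (mm/h),
#'   \code{slope_se} (mm/h), \code{intercept} (m), \code{residual_rms} (m),
#'   \code{window}.
#' @export
migration_rate <- function(records, axis = c("x", "y"), window = NULL) {
  axis <- match.arg(axis)
  col <- paste0("com_", axis)
  if (is.null(window)) window <- range(records$t)
  sel <- records$t >= window[1] & records$t <= window[2] &
    is.finite(records[[col]])
  if (sum(sel) < 10)
    stop("migration_rate: fewer than 10 records in the fit window")
  t <- records$t[sel]
  yv <- records[[col]][sel]
  fit <- stats::lm(yv ~ t)
  sm <- suppressWarnings(summary(fit))  # exact lines trip lm's SE warning
  to_mmh <- 3.6e6   # m/s -> mm/h
  out <- list(slope = unname(stats::coef(fit)[2]) * to_mmh,
              slope_se = sm$coefficients[2, 2] * to_mmh,
              intercept = unname(stats::coef(fit)[1]),
              residual_rms = sqrt(mean(stats::resid(fit)^2)),
              window = window, n = sum(sel))
  class(out) <- "migration_fit"
  out
}

#' @export
print.migration_fit <- function(x, ...) {
  cat(sprintf("migration: %.4f +/- %.4f mm/h (residual rms %.3g m, n = %d)\n",
              x$slope, x$slope_se, x$residual_rms, x$n))
  invisible(x)
}

#' Decompose migration into growth and shear contributions
#'
#' With a downstream source the biofilm migrates at about
#' \code{U_growth + U_shear}, with an upstream source at about
#' \code{-U_growth + U_shear}; hence \code{U_growth = (U_down - U_up)/2}
#' and \code{U_shear = (U_down + U_up)/2}, the latter expected to match the
#' full-stream rate.
#'
#' @param U_down,U_up,U_full migration rates (mm/h); \code{U_full} optional.
#' @return list with \code{U_growth}, \code{U_shear}, \code{U_full} and the
#'   consistency gap \code{|U_shear - U_full|} (NA when U_full absent).
#' @export
decompose_migration <- function(U_down, U_up, U_full = NA_real_) {
  list(U_growth = (U_down - U_up) / 2,
       U_shear = (U_down + U_up) / 2,
       U_full = U_full,
       shear_full_gap = abs((U_down + U_up) / 2 - U_full))
}

#' Biomass ratio between two runs at a given time
#'
#' \code{M_a(t)/M_b(t)} with biomass linearly interpolated between records.
#' With \code{records_b = NULL} the denominator is the initial biomass of
#' run a, giving relative growth \code{M(t)/M(0)}.
#'
#' @param records_a,records_b trajectory data.frames (columns t, M).
#' @param t_eval evaluation time (s); must lie inside both records' span.
#' @return the ratio (dimensionless).
#' @export
biomass_ratio <- function(records_a, records_b = NULL, t_eval) {
  mass_at <- function(rec, t) {
    if (t < min(rec$t) || t > max(rec$t))
      stop("biomass_ratio: t_eval outside record coverage")
    stats::approx(rec$t, rec$M, xout = t)$y
  }
  ma <- mass_at(records_a, t_eval)
  mb <- if (is.null(records_b)) records_a$M[1] else mass_at(records_b, t_eval)
  ma / mb
}

#' Crossover elastic modulus of the downstream/upstream growth ratio
#'
#' Log-E linear interpolation of the biomass-ratio curve to ratio = 1:
#' below the crossover a biofilm grows more with a downstream source, above
#' it more with an upstream source.
#'
#' @param E_values elastic moduli (Pa), increasing.
#' @param ratios downstream/upstream biomass ratios at those moduli.
#' @return crossover modulus (Pa), or \code{NA} with a warning when the
#'   ratios do not bracket 1.
#' @export
crossover_modulus <- function(E_values, ratios) {
  ord <- order(E_values)
  E_values <- E_values[ord]; ratios <- ratios[ord]
  s <- ratios - 1
  br <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != 0)
  if (length(br) == 0) {
    warning("crossover_modulus: no crossover in range")
    return(NA_real_)
  }
  i <- br[1]
  lE <- log10(E_values[i]) + (0 - s[i]) *
    (log10(E_values[i + 1]) - log10(E_values[i])) / (s[i + 1] - s[i])
  10^lE
}
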