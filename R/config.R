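# Simulation configuration: YAML parsing, validation, derived quantities.
#
# The packaged default profile carries the full parameter set of the study
# conditions (microchannel water at room temperature, a 150-micron
# semicircular biofilm, Monod kinetics for a single nutrient); every
# quantity is SI.

.required_keys <- c("mu", "rho", "Lx", "Ly", "h", "ds", "dt", "E",
                    "eta_water", "A", "B", "C", "D", "d_w", "r_c", "u_max",
                    "c0", "D_c", "mu_max", "K", "Y", "lambda_b", "v0", "n0",
                    "chi", "nutrient_config", "t_freeze", "t_end", "seed")

.positive_keys <- c("mu", "rho", "Lx", "Ly", "h", "ds", "dt", "E",
                    "eta_water", "A", "B", "C", "D", "d_w", "r_c", "c0",
                    "D_c", "mu_max", "K", "lambda_b", "v0", "n0", "chi")

#' Default simulation configuration
#'
#' The full-scale channel profile: a 1 cm x 3 mm channel on a 240 x 72 grid,
#' millisecond time step, a 150-micron semicircular biofilm meshed at
#' one-fifth of the grid spacing, and the standard nutrient kinetics.
#' Individual entries can be overridden via \code{...}.
#'
#' @param ... named overrides applied before validation.
#' @return a validated \code{sim_config} list.
#' @export
default_config <- function(...) {
  cfg <- list(
    mu = 9.31e-4,        # fluid dynamic viscosity (Pa s)
    rho = 1000,          # fluid density (kg/m^3)
    Lx = 1e-2,           # channel length (m)
    Ly = 3e-3,           # wall separation (m)
    h = 4.17e-5,         # Eulerian grid spacing (m)
    ds = 4.17e-5 / 5,    # Lagrangian biofilm spacing (m)
    dt = 1e-3,           # time step (s)
    E = 50,              # elastic modulus (Pa)
    eta = 5e4,           # dashpot viscosity (Pa s); Inf or "infinite" = Stokes
    tau_target = NULL,   # optional relaxation time (s) from which eta derives
    eta_water = 1.02e3,  # fluid-drag viscosity correction (Pa s)
    A = 8.33e-2,         # wall neighbor-spring stiffness (N/m)
    B = 6.25e-2,         # wall tether stiffness (N/m)
    C = 6.25e-2,         # biofilm bottom-node tether stiffness (N/m)
    D = 8.33e-2,         # freeze tether stiffness (N/m)
    d_w = 4.17e-5 / 2,   # wall node spacing (m)
    r_c = 1.5e-4,        # initial biofilm radius (m)
    u_max = 5e-6,        # target maximum channel speed (m/s)
    c0 = 1e-3,           # source concentration (kg/m^3)
    D_c = 1e-10,         # nutrient diffusivity (m^2/s)
    mu_max = 2e-4,       # maximum specific growth rate (1/s)
    K = 1e-4,            # half-saturation constant (kg/m^3)
    Y = 0.553,           # yield coefficient
    lambda_b = 1120,     # bacterial mass density (kg/m^3)
    v0 = 1.75e-18,       # bacterium volume (m^3)
    n0 = 2.1e17,         # bacterial number density (1/m^3)
    chi = 1e-6,          # slab thickness (m)
    nutrient_config = "none",
    margin = NULL,       # source strip offset from the biofilm center (m)
    t_freeze = 20,       # flow-development hold (s)
    t_end = 20,          # total simulated time (s)
    epsilon_merge = NULL, # vertex-merge distance (m), default ds/2
    seed = 1L,
    biofilm_center_x = NULL,  # default Lx/2
    record_stride = 100L,
    wall_clearance = 2L,  # extra domain rows beyond the wall separation
    has_biofilm = TRUE
  )
  over <- list(...)
  # a tau_target override replaces the default dashpot viscosity
  if ("tau_target" %in% names(over) && !("eta" %in% names(over)))
    cfg$eta <- NULL
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  validate_config(cfg)
}

#' Load a simulation configuration from a YAML file
#'
#' The file must provide every physical key; derived quantities (grid
#' counts, the effective grid spacing, defaults for the margin, merge
#' distance and biofilm center, and eta from a target relaxation time) are
#' filled by validation.
#'
#' @param path YAML file path.
#' @return a validated \code{sim_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 readers turn a bare key Y into logical TRUE; map it back
  nm <- names(cfg)
  nm[nm == "TRUE"] <- "Y"
  names(cfg) <- nm
  # strict YAML float resolution can leave exponents like 1.02e3 as strings
  for (k in names(cfg)) {
    if (is.character(cfg[[k]]) && !identical(cfg[[k]], "infinite") &&
        grepl("^[-+0-9.eE]+$", cfg[[k]]))
      cfg[[k]] <- as.numeric(cfg[[k]])
  }
  missing <- setdiff(.required_keys, names(cfg))
  if (length(missing) > 0)
    stop("load_config: missing key(s): ", paste(missing, collapse = ", "))
  validate_config(cfg)
}

#' Validate a configuration and fill derived quantities
#'
#' Checks positivity, the yield bound 0 <= Y <= 1, integer grid fit (the
#' printed spacing is normalized to \code{Lx/Nx}), \code{ds < h}, and the
#' Maxwell element specification: exactly one of \code{eta} /
#' \code{tau_target} unless \code{eta} is the sentinel \code{"infinite"}
#' selecting Stokes elements.
#'
#' @param cfg named list of parameters.
#' @return a \code{sim_config} with \code{Nx}, \code{Ny}, normalized
#'   \code{h}, resolved \code{eta} and defaults filled.
#' @export
validate_config <- function(cfg) {
  for (k in .positive_keys) {
    v <- cfg[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v <= 0)
      stop("config: field '", k, "' must be a positive number")
  }
  if (!is.numeric(cfg$dt) || cfg$dt <= 0)
    stop("config: field 'dt' must be a positive number")
  if (!is.numeric(cfg$Y) || cfg$Y < 0 || cfg$Y > 1)
    stop("config: field 'Y' must satisfy 0 <= Y <= 1")
  if (!is.numeric(cfg$u_max) || cfg$u_max < 0)
    stop("config: field 'u_max' must be non-negative")
  if (!(cfg$nutrient_config %in% c("none", "full", "down", "up")))
    stop("config: field 'nutrient_config' must be one of none/full/down/up")
  if (cfg$ds >= cfg$h)
    stop("config: field 'ds' must be smaller than the grid spacing h")
  # grid fit: the printed h may be a rounded form of Lx/Nx
  nx <- cfg$Lx / cfg$h
  ny <- cfg$Ly / cfg$h
  if (abs(nx - round(nx)) > 0.02 * round(nx))
    stop("config: field 'h' does not divide Lx into an integer grid")
  Nx <- as.integer(round(nx))
  h_eff <- cfg$Lx / Nx
  ny <- cfg$Ly / h_eff
  if (abs(ny - round(ny)) > 1e-8 * round(ny))
    stop("config: field 'h' does not divide Ly into an integer grid")
  cfg$Nx <- Nx
  cfg$Ny_channel <- as.integer(round(ny))
  # The discrete wall's effective no-slip plane sits about 0.8 h outside the
  # marker line (a property of the regularized kernel), so the periodic
  # domain carries a clearance row per effective wall side; the hydrodynamic
  # wall separation then equals Ly while Eq-31-style driving is unchanged.
  if (is.null(cfg$wall_clearance)) cfg$wall_clearance <- 2L
  cfg$Ny <- cfg$Ny_channel + as.integer(cfg$wall_clearance)
  cfg$h <- h_eff
  # viscoelastic element resolution (exact [[ indexing: $ would partially
  # match eta_water when eta is absent)
  eta_v <- cfg[["eta"]]
  tau_v <- cfg[["tau_target"]]
  eta_inf <- identical(eta_v, "infinite") ||
    (is.numeric(eta_v) && is.infinite(eta_v))
  has_eta <- !is.null(eta_v) && !eta_inf
  has_tau <- !is.null(tau_v)
  if (eta_inf) {
    if (has_tau)
      stop("config: field 'tau_target' conflicts with infinite eta ",
           "(Stokes elements have no relaxation time)")
    cfg$eta <- Inf
  } else if (has_eta && has_tau) {
    stop("config: specify exactly one of fields 'eta' and 'tau_target'")
  } else if (has_tau) {
    if (!is.numeric(tau_v) || tau_v <= 0)
      stop("config: field 'tau_target' must be a positive number")
    cfg$eta <- dashpot_viscosity_for_tau(cfg$E, tau_v, cfg$eta_water)
  } else if (!has_eta) {
    stop("config: one of fields 'eta' and 'tau_target' is required")
  } else if (!is.numeric(eta_v) || eta_v <= 0) {
    stop("config: field 'eta' must be a positive number or \"infinite\"")
  }
  if (is.null(cfg$biofilm_center_x)) cfg$biofilm_center_x <- cfg$Lx / 2
  if (is.null(cfg$margin)) cfg$margin <- 2 * cfg$r_c
  if (is.null(cfg$epsilon_merge)) cfg$epsilon_merge <- cfg$ds / 2
  if (is.null(cfg$record_stride)) cfg$record_stride <- 100L
  if (is.null(cfg$has_biofilm)) cfg$has_biofilm <- TRUE
  if (is.null(cfg$t_freeze) || cfg$t_freeze < 0)
    stop("config: field 't_freeze' must be non-negative")
  if (is.null(cfg$t_end) || cfg$t_end <= 0)
    stop("config: field 't_end' must be positive")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Write the resolved configuration to a YAML manifest
#'
#' @param config a \code{sim_config}.
#' @param path output file path.
#' @export
write_manifest <- function(config, path) {
  out <- unclass(config)
  out$eta <- if (is.infinite(out$eta)) "infinite" else out$eta
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$Nx, "x", x$Ny, "grid (h =", format(x$h, digits = 4),
      "m), dt =", x$dt, "s, t_end =", x$t_end, "s\n")
  cat("  E =", x$E, "Pa, eta =",
      if (is.infinite(x$eta)) "infinite (Stokes)" else format(x$eta),
      "Pa.s, u_max =", x$u_max, "m/s, nutrient:", x$nutrient_config, "\n")
  invisible(x)
}
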