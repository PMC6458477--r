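#' pnpaxon: electrodiffusion modelling of transcranial electrical stimulation
#'
#' The package simulates ion electrodiffusion around a single node of Ranvier
#' during transcranial electrical stimulation (TES).  Electric potential and
#' the concentrations of Na+, K+, Ca2+ and Cl- obey the Poisson-Nernst-Planck
#' equations on a two-dimensional axon cross-section; transmembrane transport
#' at the node is a Hodgkin-Huxley-type flux boundary condition whose gating
#' states are integrated with a stiff ODE solver at every membrane site.
#'
#' Start with [default_parameters()], [generate_mesh()] and [simulate_tes()].
#'
#' @keywords internal
#' @importFrom Matrix sparseMatrix Diagonal solve t colSums rowSums
#' @importFrom deSolve lsoda
#' @importFrom stats approx coef lm median setNames
#' @importFrom utils modifyList read.csv write.csv packageVersion
"_PACKAGE"

# ---------------------------------------------------------------------------
# Default parameter set
# ---------------------------------------------------------------------------

#' Default model configuration
#'
#' Returns the full parameter set of the TES electrodiffusion model:
#' physical constants, the four-ion table (valence, diffusivity, initial
#' intracellular and bulk extracellular concentrations, drift coefficient
#' `alpha = z*F/(R*T)`), time stepping, the TES protocol (0 V until the
#' activation time, then 0.1 V on the left extracellular boundary), the
#' domain geometry and mesh resolution controls.
#'
#' Concentrations are stored in mol/m^3, numerically equal to mM.  Lengths
#' are metres, potentials volts, and times at the configuration surface are
#' milliseconds (converted to seconds internally).
#'
#' The chloride leak conductance is calibrated in closed form so that the
#' total membrane current vanishes at the resting transmembrane voltage
#' (-70.23 mV) with the default concentrations; the resulting value is part
#' of the returned configuration.
#'
#' @param mesh_preset one of `"coarse"`, `"full"`, `"test"`; selects the
#'   mesh resolution block (see [mesh_resolution()]).
#' @return an object of class `tes_config` (a named list with components
#'   `constants`, `ions`, `stepping`, `tes`, `geometry`, `mesh`, `membrane`,
#'   `numerics`, `output`, `seed`).
#' @seealso [load_config()], [validate_config()], [simulate_tes()]
#' @export
#' @examples
#' cfg <- default_parameters()
#' cfg$constants$T            # 279.45 K
#' cfg$ions$K$D               # 1.96e-9 m^2/s
default_parameters <- function(mesh_preset = "coarse") {
  constants <- list(
    R        = 8.31454,      # gas constant, J/(mol K)
    T        = 279.450,      # temperature, K
    F        = 96485,        # Faraday constant, C/mol
    eps0     = 8.88542e-12,  # vacuum permittivity, C/(m V)
    eps_c    = 80,           # relative permittivity, cytosol/extracellular
    eps_memb = 2             # relative permittivity, membrane
  )
  ion <- function(name, z, D, intra, extra) {
    list(name = name, z = z, D = D,
         n_init_intra = intra, n_bulk_extra = extra,
         alpha = z * constants$F / (constants$R * constants$T))
  }
  ions <- list(
    Na = ion("Na", +1L, 1.33e-9, 12,     145),
    K  = ion("K",  +1L, 1.96e-9, 155,    4),
    Ca = ion("Ca", +2L, 0.5e-9,  0.0001, 1),
    Cl = ion("Cl", -1L, 2.0e-9,  166.8,  123.27)
  )
  stepping <- list(
    dt_outer     = 0.01,   # ms, outer PDE step
    dt_inner_max = 0.0005, # ms, maximal membrane-ODE step
    t_end        = 20,     # ms
    t_tes_on     = 2       # ms
  )
  tes <- list(
    amplitude = 0.1,  # V, left-boundary Dirichlet value once TES is on
    phi_right = 0     # V, right-boundary (ground) Dirichlet value
  )
  geometry <- list(
    axon_length                   = 4e-6,
    node_length                   = 1e-6,
    membrane_thickness_myelinated = 0.406e-6,
    membrane_thickness_node       = 0.005e-6,
    intracellular_halfheight      = 0.434e-6,
    domain_halfheight             = 2e-6
  )
  membrane <- list(
    rate_model = "hh1952",  # classic alpha/beta forms, voltage-shifted
    v_shift    = 65,        # mV added to V before the rate expressions
    V_rest     = -70.23,    # mV, resting transmembrane voltage
    g_Na       = 1200,      # S/m^2, maximal sodium conductance
    g_K        = 360,       # S/m^2, maximal potassium conductance
    g_Ca       = 0.2,       # S/m^2, maximal (m-gated) calcium conductance
    g_Cl       = NA_real_   # S/m^2, passive leak; calibrated below
  )
  numerics <- list(
    electrodes          = "open",   # "open": migration passes Gamma_L/R;
                                    # "reservoir": bulk Dirichlet at walls;
                                    # "blocking": literal zero total flux
    neutral_background  = TRUE,     # immobile charge neutralising each bulk
    init_double_layers  = TRUE,     # pre-form resting membrane double layers
    theta               = 1,        # theta-rule weight (1 = backward Euler)
    negativity_tol      = 0.05,     # abort if min(n) < -tol * bulk scale
    stabilize_poisson   = TRUE,     # implicit ohmic response in Poisson step
    init_relax_steps    = 1500,     # flux-free equilibration steps at init
    init_relax_dt       = 0.1,      # ms, step used during equilibration
    init_calib_iters    = 2,        # resting-charge calibration sweeps
    init_site_correction = FALSE    # per-site rest nulling (see vignette)
  )
  output <- list(
    checkpoint_every = 0.5   # ms, field checkpoint cadence
  )
  cfg <- structure(list(
    constants = constants, ions = ions, stepping = stepping, tes = tes,
    geometry = geometry, mesh = mesh_resolution(mesh_preset),
    membrane = membrane, numerics = numerics, output = output,
    seed = 1L
  ), class = "tes_config")
  cfg$membrane$g_Cl <- calibrate_leak_conductance(cfg)
  cfg
}

#' Mesh resolution presets
#'
#' Resolution controls for the structured axon mesh.  `h_bulk` is the target
#' element size away from the membrane, `h_debye` the element size inside the
#' refined band hugging both faces of the nodal membrane, `debye_band_width`
#' the thickness of that band.  `node_nx` fixes the number of columns across
#' the node of Ranvier (hence the number of membrane sites), `membrane_ny`
#' the number of element layers through the nodal membrane, `grade` the
#' geometric growth ratio of element size leaving a refined band.
#'
#' The `"full"` preset approaches the resolution of the reference
#' full-scale simulations and is far too large for routine testing;
#' `"coarse"` is
#' the default desk-scale preset; `"test"` is a minimal mesh for unit tests.
#'
#' @param preset `"coarse"`, `"full"` or `"test"`, or a list of overrides.
#' @return a list of resolution controls.
#' @export
mesh_resolution <- function(preset = "coarse") {
  if (is.list(preset)) {
    return(modifyList(mesh_resolution("coarse"), preset))
  }
  switch(preset,
    coarse = list(preset = "coarse", h_bulk = 0.12e-6, h_debye = 1e-9,
                  debye_band_width = 4e-9, node_nx = 32L, node_edge_dx = 5e-9,
                  membrane_ny = 3L, grade = 1.5),
    test   = list(preset = "test", h_bulk = 0.35e-6, h_debye = 2.5e-9,
                  debye_band_width = 5e-9, node_nx = 12L, node_edge_dx = 20e-9,
                  membrane_ny = 2L, grade = 1.9),
    full   = list(preset = "full", h_bulk = 0.02e-6, h_debye = 0.25e-9,
                  debye_band_width = 4e-9, node_nx = 425L, node_edge_dx = 1e-9,
                  membrane_ny = 8L, grade = 1.15),
    stop("unknown mesh preset: ", preset)
  )
}

# Closed-form rest-consistency calibration of the chloride leak: at V_rest
# with the default concentrations the gated Na, K and Ca currents are
# balanced exactly by the passive Cl current.
calibrate_leak_conductance <- function(cfg) {
  ct <- cfg$constants
  V <- cfg$membrane$V_rest
  g <- steady_state_gating(V, registry = gating_registry(cfg))
  E <- reversal_potentials(
    conc_intra = vapply(cfg$ions, function(i) i$n_init_intra, 0),
    conc_extra = vapply(cfg$ions, function(i) i$n_bulk_extra, 0),
    constants = ct)
  mv <- 1e-3  # mV -> V
  I_Na <- cfg$membrane$g_Na * g$m^3 * g$h * (V - E[["Na"]]) * mv
  I_K  <- cfg$membrane$g_K  * g$n^4        * (V - E[["K"]])  * mv
  I_Ca <- cfg$membrane$g_Ca * g$m          * (V - E[["Ca"]]) * mv
  -(I_Na + I_K + I_Ca) / ((V - E[["Cl"]]) * mv)
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

#' Validate a model configuration
#'
#' Checks every type invariant of the configuration and returns a character
#' vector of violations (empty when the configuration is valid).  Each entry
#' names the offending field and the rule it breaks.  Nothing is raised.
#'
#' @param config a `tes_config` object.
#' @return character vector of violations, `character(0)` if valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  ct <- config$constants
  for (f in c("R", "T", "F", "eps0", "eps_c", "eps_memb")) {
    x <- ct[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      bad(sprintf("constants$%s: must be a single strictly positive number", f))
  }
  expected_z <- c(Na = 1, K = 1, Ca = 2, Cl = -1)
  if (!setequal(names(config$ions), names(expected_z)))
    bad("ions: ion set must contain exactly Na, K, Ca, Cl for the default membrane model")
  for (nm in intersect(names(config$ions), names(expected_z))) {
    io <- config$ions[[nm]]
    if (!is.finite(io$D) || io$D <= 0)
      bad(sprintf("ions$%s$D: diffusivity must be > 0", nm))
    if (io$n_init_intra < 0 || io$n_bulk_extra < 0)
      bad(sprintf("ions$%s: concentrations must be >= 0", nm))
    if (io$z != expected_z[[nm]])
      bad(sprintf("ions$%s$z: valence must be %d", nm, expected_z[[nm]]))
    alpha_ref <- io$z * ct$F / (ct$R * ct$T)
    if (is.finite(alpha_ref) &&
        (!is.finite(io$alpha) || abs(io$alpha - alpha_ref) > 1e-9 * abs(alpha_ref)))
      bad(sprintf("ions$%s$alpha: must equal z*F/(R*T)", nm))
  }
  st <- config$stepping
  if (!(st$dt_inner_max > 0 && st$dt_inner_max <= st$dt_outer))
    bad("stepping: need 0 < dt_inner_max <= dt_outer")
  if (!(st$t_tes_on >= 0 && st$t_tes_on <= st$t_end))
    bad("stepping: need 0 <= t_tes_on <= t_end")
  ge <- config$geometry
  if (!(ge$node_length > 0 && ge$node_length < ge$axon_length))
    bad("geometry: need 0 < node_length < axon_length")
  if (!(ge$membrane_thickness_node < ge$membrane_thickness_myelinated))
    bad("geometry: nodal membrane must be thinner than the myelinated membrane")
  if (!(ge$intracellular_halfheight + ge$membrane_thickness_myelinated <
        ge$domain_halfheight))
    bad("geometry: intracellular space plus membrane must fit inside the domain")
  ms <- config$mesh
  if (!(ms$h_debye > 0 && ms$h_debye <= ms$h_bulk))
    bad("mesh: need 0 < h_debye <= h_bulk")
  mb <- config$membrane
  for (f in c("g_Na", "g_K", "g_Ca", "g_Cl"))
    if (!is.finite(mb[[f]]) || mb[[f]] < 0)
      bad(sprintf("membrane$%s: conductance must be a nonnegative number", f))
  if (!config$numerics$electrodes %in% c("open", "blocking", "reservoir"))
    bad("numerics$electrodes: must be \"open\", \"reservoir\" or \"blocking\"")
  v
}

stop_if_invalid <- function(config) {
  v <- validate_config(config)
  if (length(v))
    stop("invalid configuration:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  invisible(config)
}

# ---------------------------------------------------------------------------
# File I/O (YAML key-value schema, see docs/config.md)
# ---------------------------------------------------------------------------

#' Read a configuration file
#'
#' Reads a YAML configuration file and merges it over the defaults: any key
#' not present in the file keeps its default value, so an empty file yields
#' [default_parameters()].  Ion drift coefficients are recomputed from
#' `z*F/(R*T)` after merging so that constants overrides propagate.  The
#' merged configuration is validated; physically invalid values raise an
#' error listing the offending fields.
#'
#' The schema mirrors the structure of [default_parameters()]; it is
#' documented in `docs/config.md` at the repository root.
#'
#' @param path path to a YAML file.
#' @return a validated `tes_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("configuration parse failure in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (is.null(raw)) raw <- list()
  known <- c("constants", "ions", "stepping", "tes", "geometry", "mesh",
             "membrane", "numerics", "output", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- default_parameters()
  cfg_list <- unclass(cfg)
  merged <- modifyList(cfg_list, raw)
  merged <- structure(merged, class = "tes_config")
  # drift coefficients are derived quantities unless explicitly overridden
  for (nm in names(merged$ions)) {
    if (is.null(raw$ions[[nm]]$alpha))
      merged$ions[[nm]]$alpha <-
        merged$ions[[nm]]$z * merged$constants$F /
        (merged$constants$R * merged$constants$T)
  }
  # recalibrate the leak unless the file pinned it
  if (is.null(raw$membrane$g_Cl))
    merged$membrane$g_Cl <- calibrate_leak_conductance(merged)
  stop_if_invalid(merged)
  merged
}

#' Write a configuration file
#'
#' Serializes a configuration to YAML with enough precision that
#' `load_config(save_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config a `tes_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @export
print.tes_config <- function(x, ...) {
  cat("TES electrodiffusion model configuration\n")
  cat(sprintf("  temperature %.3f K, %d ion species (%s)\n",
              x$constants$T, length(x$ions), paste(names(x$ions), collapse = ", ")))
  cat(sprintf("  protocol: %.3g V on the left boundary after %g ms, %g ms total\n",
              x$tes$amplitude, x$stepping$t_tes_on, x$stepping$t_end))
  cat(sprintf("  stepping: dt_outer %g ms, membrane ODE dt <= %g ms\n",
              x$stepping$dt_outer, x$stepping$dt_inner_max))
  cat(sprintf("  mesh preset '%s' (h_bulk %.3g m, h_debye %.3g m)\n",
              x$mesh$preset, x$mesh$h_bulk, x$mesh$h_debye))
  invisible(x)
}

# All Table-style default values as one row per configuration field; used by
# the table-driven default tests and by the provenance writer.
config_parameter_table <- function(cfg = default_parameters()) {
  data.frame(
    field = c("constants.R", "constants.F", "constants.T", "constants.eps0",
              "constants.eps_c", "constants.eps_memb",
              "ions.Na.n_init_intra", "ions.Na.n_bulk_extra",
              "ions.K.n_init_intra", "ions.K.n_bulk_extra",
              "ions.Ca.n_init_intra", "ions.Ca.n_bulk_extra",
              "ions.Cl.n_init_intra", "ions.Cl.n_bulk_extra",
              "ions.Na.D", "ions.K.D", "ions.Ca.D", "ions.Cl.D",
              "stepping.dt_outer", "stepping.dt_inner_max",
              "stepping.t_tes_on", "stepping.t_end"),
    value = c(cfg$constants$R, cfg$constants$F, cfg$constants$T,
              cfg$constants$eps0, cfg$constants$eps_c, cfg$constants$eps_memb,
              cfg$ions$Na$n_init_intra, cfg$ions$Na$n_bulk_extra,
              cfg$ions$K$n_init_intra, cfg$ions$K$n_bulk_extra,
              cfg$ions$Ca$n_init_intra, cfg$ions$Ca$n_bulk_extra,
              cfg$ions$Cl$n_init_intra, cfg$ions$Cl$n_bulk_extra,
              cfg$ions$Na$D, cfg$ions$K$D, cfg$ions$Ca$D, cfg$ions$Cl$D,
              cfg$stepping$dt_outer, cfg$stepping$dt_inner_max,
              cfg$stepping$t_tes_on, cfg$stepping$t_end),
    stringsAsFactors = FALSE
  )
}
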