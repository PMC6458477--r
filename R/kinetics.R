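# Hodgkin-Huxley-type membrane kinetics at a node of Ranvier.
#
# The rate registry isolates every kinetic parameter in one place: the six
# alpha/beta transition-rate functions (classic 1952 forms, voltage-shifted
# so the squid convention rest sits at -65 mV), the maximal conductances and
# the gating pattern of each channel.  Sodium is gated by m^3 h, potassium by
# n^4, calcium by m (a persistent, activation-shared calcium channel) and
# chloride is a passive ohmic leak whose conductance is calibrated so total
# current vanishes at rest.  Everything is config-overridable.

#' Gating-rate registry
#'
#' Builds the set of voltage-dependent transition-rate functions and channel
#' parameters used by all kinetics operations.  Rates are in 1/ms and take
#' the transmembrane voltage in mV.  The removable singularities of the
#' alpha_m and alpha_n expressions are handled by their limiting values.
#'
#' @param config a `tes_config`; only the `membrane` block is used.
#' @return a list with functions `alpha_m`, `beta_m`, `alpha_n`, `beta_n`,
#'   `alpha_h`, `beta_h`, the conductances, and the voltage shift.
#' @export
gating_registry <- function(config = default_parameters()) {
  mb <- config$membrane
  shift <- mb$v_shift
  # x/(exp(x/s)-1) with the limit s at x -> 0
  relu_exp <- function(x, s) {
    out <- x / expm1(x / s)
    small <- abs(x) < 1e-7
    out[small] <- s - x[small] / 2
    out
  }
  list(
    alpha_m = function(V) { v <- V + shift; 0.1 * relu_exp(25 - v, 10) },
    beta_m  = function(V) { v <- V + shift; 4 * exp(-v / 18) },
    alpha_h = function(V) { v <- V + shift; 0.07 * exp(-v / 20) },
    beta_h  = function(V) { v <- V + shift; 1 / (exp((30 - v) / 10) + 1) },
    alpha_n = function(V) { v <- V + shift; 0.01 * relu_exp(10 - v, 10) },
    beta_n  = function(V) { v <- V + shift; 0.125 * exp(-v / 80) },
    g_Na = mb$g_Na, g_K = mb$g_K, g_Ca = mb$g_Ca, g_Cl = mb$g_Cl,
    v_shift = shift
  )
}

#' Evaluate the six transition rates at a voltage
#'
#' @param V transmembrane voltage, mV (vectorised).
#' @param registry a rate registry from [gating_registry()].
#' @return a list with components `alpha_m`, `beta_m`, `alpha_n`, `beta_n`,
#'   `alpha_h`, `beta_h` (1/ms).
#' @export
gating_rates <- function(V, registry = gating_registry()) {
  stopifnot(all(is.finite(V)))
  list(alpha_m = registry$alpha_m(V), beta_m = registry$beta_m(V),
       alpha_n = registry$alpha_n(V), beta_n = registry$beta_n(V),
       alpha_h = registry$alpha_h(V), beta_h = registry$beta_h(V))
}

#' Steady-state gating values
#'
#' Computes `g_inf = alpha_g / (alpha_g + beta_g)` for each gate.  At the
#' model's resting voltage (-70.23 mV) the sodium activation gate sits at
#' `m_inf` of about 0.0281.
#'
#' @inheritParams gating_rates
#' @return a list with components `m`, `n`, `h` in (0, 1) (vectorised in `V`).
#' @export
steady_state_gating <- function(V, registry = gating_registry()) {
  r <- gating_rates(V, registry)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       n = r$alpha_n / (r$alpha_n + r$beta_n),
       h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Nernst reversal potentials
#'
#' `E_i = (R*T)/(z_i*F) * ln(extra/intra)` in mV, per ion.
#'
#' @param conc_intra,conc_extra named numeric vectors of intracellular and
#'   extracellular concentrations (mol/m^3); names are ion names.
#' @param constants the `constants` block of a configuration.
#' @param z named integer vector of valences; defaults to the standard set.
#' @return named numeric vector of reversal potentials, mV.
#' @export
reversal_potentials <- function(conc_intra, conc_extra,
                                constants = default_parameters()$constants,
                                z = c(Na = 1, K = 1, Ca = 2, Cl = -1)) {
  nm <- names(conc_intra)
  if (is.null(nm)) nm <- names(z)[seq_along(conc_intra)]
  if (any(conc_intra <= 0) || any(conc_extra <= 0))
    stop("reversal_potentials: concentrations must be strictly positive")
  zz <- z[nm]
  1000 * constants$R * constants$T / (zz * constants$F) *
    log(conc_extra / conc_intra)
}

#' Per-ion membrane flux at one or more membrane sites
#'
#' Converts Hodgkin-Huxley channel currents to molar fluxes for the membrane
#' boundary condition.  Current densities are `g * p_open * (V - E_i)` with
#' open probabilities m^3 h (Na), n^4 (K), m (Ca) and 1 (Cl leak); molar flux
#' is current divided by `z_i*F`, so a negative value means influx into the
#' cell from the extracellular space.
#'
#' Reversal potentials are recomputed from the local concentrations, so the
#' calcium driving force follows the evolving intracellular calcium level.
#'
#' @param gating list with components `m`, `n`, `h` (scalars or vectors over
#'   sites).
#' @param V transmembrane voltage, mV.
#' @param conc_intra,conc_extra matrices (sites x ions) or named vectors of
#'   local concentrations, mol/m^3.
#' @param constants the `constants` block of a configuration.
#' @param registry rate registry carrying the conductances.
#' @return matrix (sites x ions) of fluxes, mol/(m^2 s), columns Na, K, Ca, Cl.
#' @export
membrane_flux <- function(gating, V, conc_intra, conc_extra,
                          constants = default_parameters()$constants,
                          registry = gating_registry()) {
  if (is.null(dim(conc_intra))) conc_intra <- rbind(conc_intra)
  if (is.null(dim(conc_extra))) conc_extra <- rbind(conc_extra)
  stopifnot(all(is.finite(V)), all(conc_intra > 0), all(conc_extra > 0))
  z <- c(Na = 1, K = 1, Ca = 2, Cl = -1)
  RTF <- 1000 * constants$R * constants$T / constants$F  # mV
  E <- sweep(log(conc_extra / conc_intra), 2, RTF / z[colnames(conc_intra)],
             `*`)
  mv <- 1e-3
  I <- cbind(
    Na = registry$g_Na * gating$m^3 * gating$h * (V - E[, "Na"]) * mv,
    K  = registry$g_K  * gating$n^4            * (V - E[, "K"])  * mv,
    Ca = registry$g_Ca * gating$m              * (V - E[, "Ca"]) * mv,
    Cl = registry$g_Cl *                         (V - E[, "Cl"]) * mv
  )
  sweep(I, 2, z[colnames(I)] * constants$F, `/`)
}

#' Advance the gating state over one outer time step
#'
#' Integrates `dg/dt = alpha_g(V)(1-g) - beta_g(V) g` for the three gates
#' with `lsoda` (adaptive, stiff-capable), constrained to internal steps no
#' larger than `dt_inner_max`.  `V_trace` may be a constant voltage (the
#' Gauss-Seidel driver freezes the potential within an outer step) or a
#' function of time (ms) over `[0, dt]`.
#'
#' @param gating list with scalar components `m`, `n`, `h`.
#' @param V_trace scalar voltage (mV) or `function(t_ms)` returning one.
#' @param dt outer step length, ms.
#' @param dt_inner_max maximal internal step, ms.
#' @param registry rate registry.
#' @param rtol,atol integrator tolerances.
#' @return list with components `m`, `n`, `h` at `t + dt`.
#' @export
advance_gating <- function(gating, V_trace, dt, dt_inner_max = dt,
                           registry = gating_registry(),
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(dt_inner_max > 0, dt_inner_max <= dt + 1e-15)
  Vf <- if (is.function(V_trace)) V_trace else function(t) V_trace
  rhs <- function(t, y, p) {
    V <- Vf(t)
    list(c(registry$alpha_m(V) * (1 - y[1]) - registry$beta_m(V) * y[1],
           registry$alpha_n(V) * (1 - y[2]) - registry$beta_n(V) * y[2],
           registry$alpha_h(V) * (1 - y[3]) - registry$beta_h(V) * y[3]))
  }
  y0 <- c(gating$m, gating$n, gating$h)
  out <- tryCatch(
    deSolve::lsoda(y0, c(0, dt), rhs, parms = NULL,
                   rtol = rtol, atol = atol, hmax = dt_inner_max),
    warning = function(w)
      stop("gating integrator failure at state (",
           paste(signif(y0, 6), collapse = ", "), "): ",
           conditionMessage(w), call. = FALSE))
  y <- out[nrow(out), -1]
  y <- pmin(pmax(as.numeric(y), 0), 1)  # guards roundoff at the bounds
  if (any(!is.finite(y)))
    stop("gating integrator produced a non-finite state")
  list(m = y[1], n = y[2], h = y[3])
}

# Exact single-gate relaxation g(t) = g_inf - (g_inf - g0) exp(-t/tau) for a
# constant voltage; the closed-form oracle used to verify advance_gating.
gate_relaxation_exact <- function(g0, alpha, beta, t) {
  ginf <- alpha / (alpha + beta)
  tau <- 1 / (alpha + beta)
  ginf - (ginf - g0) * exp(-t / tau)
}
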