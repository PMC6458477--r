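# Gauss-Seidel simulation driver: Poisson solve, membrane gating/flux
# update, Nernst-Planck step, repeated over the outer time grid.

# analytic Debye length for a bulk composition (m)
debye_length <- function(conc, ions, constants) {
  s <- 0
  for (nm in names(ions)) s <- s + ions[[nm]]$z^2 * conc[[nm]]
  sqrt(constants$eps_c * constants$eps0 * constants$R * constants$T /
       (constants$F^2 * s))
}

# full workspace for a run: poisson workspace + pairing + site bookkeeping
driver_workspace <- function(mesh, config) {
  work <- poisson_workspace(mesh, config)
  work$pairing <- pair_membrane_traces(mesh)
  work$site_loc_I <- work$sys$I$g2l[work$pairing$node_intra]
  work$site_loc_E <- work$sys$E$g2l[work$pairing$node_extra]
  work
}

# Gouy-Chapman-style resting double layers: each membrane face receives the
# capacitive charge c_f * V_rest (negative on the intracellular face,
# positive on the extracellular face), carried by the mobile ions in an
# exponential profile normalised so the discrete charge integral is exact.
seed_double_layers <- function(conc, mesh, config, work, scale = 1) {
  ct <- config$constants
  lv <- spec_levels(mesh$spec)
  V0 <- config$membrane$V_rest * 1e-3  # V
  d_node <- mesh$spec$membrane_thickness_node
  d_myel <- mesh$spec$membrane_thickness_myelinated
  cap <- function(d) ct$eps_memb * ct$eps0 / d
  V0 <- V0 * scale
  faces <- list(
    list(region = "I", y = lv$y1, xmin = lv$xl, xmax = lv$xr,
         sigma = cap(d_node) * V0),
    list(region = "E", y = lv$y2, xmin = lv$xl, xmax = lv$xr,
         sigma = -cap(d_node) * V0),
    list(region = "I", y = lv$y1, xmin = 0, xmax = lv$xl,
         sigma = cap(d_myel) * V0),
    list(region = "I", y = lv$y1, xmin = lv$xr, xmax = lv$L,
         sigma = cap(d_myel) * V0),
    list(region = "E", y = lv$y3, xmin = 0, xmax = lv$xl,
         sigma = -cap(d_myel) * V0),
    list(region = "E", y = lv$y3, xmin = lv$xr, xmax = lv$L,
         sigma = -cap(d_myel) * V0)
  )
  bulk <- list(
    I = lapply(config$ions, function(i) i$n_init_intra),
    E = lapply(config$ions, function(i) i$n_bulk_extra))
  zs <- vapply(config$ions, function(i) i$z, 0)
  for (fc in faces) {
    sys <- work$sys[[fc$region]]
    lam <- max(debye_length(bulk[[fc$region]], config$ions, ct),
               0.75 * mesh$res$h_debye)
    xy <- mesh$nodes[sys$gnodes, , drop = FALSE]
    dist <- if (fc$region == "I") fc$y - xy[, 2] else xy[, 2] - fc$y
    sel <- xy[, 1] >= fc$xmin - 1e-15 & xy[, 1] <= fc$xmax + 1e-15 &
           dist >= -1e-15
    prof <- numeric(sys$ndof)
    prof[sel] <- exp(-pmax(dist[sel], 0) / lam)
    q <- sum(sys$Mlump * prof)
    if (q <= 0) next
    rho <- prof * (fc$sigma * (fc$xmax - fc$xmin) / q)  # C/m^3, exact total
    nb <- unlist(bulk[[fc$region]])
    w <- zs^2 * nb / sum(zs^2 * nb)
    for (nm in names(config$ions))
      conc[[nm]][[fc$region]] <- conc[[nm]][[fc$region]] +
        rho / ct$F * w[[nm]] / zs[[nm]]
  }
  conc
}

# Add a small per-site double-layer dipole: dV[j] volts of extra membrane
# charge (c_node * dV) on the two node faces of site j's column, carried by
# the mobile ions like the main seeding.  Used to null the residual site-
# by-site error of the equilibrated rest state.
seed_site_dipoles <- function(conc, mesh, config, work, dV) {
  ct <- config$constants
  lv <- spec_levels(mesh$spec)
  cap <- ct$eps_memb * ct$eps0 / mesh$spec$membrane_thickness_node
  p <- work$pairing
  xs <- p$x
  width <- diff(c(lv$xl, (xs[-1] + xs[-length(xs)]) / 2, lv$xr))
  bulk <- list(
    I = lapply(config$ions, function(i) i$n_init_intra),
    E = lapply(config$ions, function(i) i$n_bulk_extra))
  zs <- vapply(config$ions, function(i) i$z, 0)
  for (rg in c("I", "E")) {
    sys <- work$sys[[rg]]
    lam <- max(debye_length(bulk[[rg]], config$ions, ct),
               0.75 * mesh$res$h_debye)
    xy <- mesh$nodes[sys$gnodes, , drop = FALSE]
    yface <- if (rg == "I") lv$y1 else lv$y2
    dist <- if (rg == "I") yface - xy[, 2] else xy[, 2] - yface
    sgn <- if (rg == "I") 1 else -1
    nb <- unlist(bulk[[rg]])
    w <- zs^2 * nb / sum(zs^2 * nb)
    col <- vapply(xy[, 1], function(xx) {
      j <- which.min(abs(xs - xx))
      if (abs(xs[j] - xx) < 1e-13) j else NA_integer_
    }, 0L)
    ok <- !is.na(col) & dist >= -1e-15
    prof <- numeric(sys$ndof)
    prof[ok] <- exp(-pmax(dist[ok], 0) / lam)
    for (j in seq_along(xs)) {
      sel <- ok & col == j
      if (!any(sel)) next
      q <- sum(sys$Mlump[sel] * prof[sel])
      rho <- numeric(sys$ndof)
      rho[sel] <- prof[sel] * (sgn * cap * dV[j] * width[j] / q)
      for (nm in names(config$ions))
        conc[[nm]][[rg]] <- conc[[nm]][[rg]] +
          rho / ct$F * w[[nm]] / zs[[nm]]
    }
  }
  conc
}

# flux-free relaxation of the coupled pair (TES off) towards the discrete
# electro-diffusive equilibrium; used only by the initializer
relax_equilibrate <- function(conc, mesh, config, work, nsteps, dt) {
  phi <- solve_poisson(mesh, conc, 0, config, work = work)
  for (k in seq_len(nsteps)) {
    phi <- solve_poisson(mesh, conc, 0, config, dt = dt, phi_prev = phi,
                         work = work)
    conc <- step_nernst_planck(mesh, conc, phi, NULL, dt,
                               theta = 1, config, work)
  }
  list(conc = conc, phi = phi)
}

site_concentrations <- function(conc, work) {
  ions <- names(conc)
  ci <- vapply(ions, function(nm) conc[[nm]]$I[work$site_loc_I],
               numeric(length(work$site_loc_I)))
  ce <- vapply(ions, function(nm) conc[[nm]]$E[work$site_loc_E],
               numeric(length(work$site_loc_E)))
  list(intra = ci, extra = ce)
}

#' Initialize the simulation state
#'
#' Sets each ion to its configured uniform initial concentration in the
#' intracellular and extracellular regions, seeds the resting membrane
#' double layers (so the run starts at electro-diffusive rest rather than
#' spending milliseconds charging the membrane), performs the initial
#' Poisson solve, and places every membrane site's gating state at its
#' steady state for the local initial transmembrane voltage.
#'
#' @param config a `tes_config`.
#' @param mesh a `tagged_mesh` built from the same geometry.
#' @param work internal workspace (built if missing).
#' @return a `sim_state` list: time, potential, concentration fields,
#'   per-site gating/voltage/flux, step counter and diagnostics.
#' @export
initialize_state <- function(config, mesh, work = NULL) {
  stop_if_invalid(config)
  if (is.null(work)) work <- driver_workspace(mesh, config)
  uniform <- function() lapply(config$ions, function(io)
    list(I = rep(io$n_init_intra, work$sys$I$ndof),
         E = rep(io$n_bulk_extra, work$sys$E$ndof)))
  conc <- uniform()
  phi <- NULL
  if (isTRUE(config$numerics$init_double_layers)) {
    # Seed the resting double layers, let the flux-free PDE pair relax them
    # to the discrete electro-diffusive equilibrium (membrane flux and TES
    # both off; the trapped intracellular charge is conserved), and
    # calibrate the seeded charge so the equilibrated mean transmembrane
    # voltage equals the resting value.  V responds linearly to the seeded
    # charge, so one correction converges.
    Vt <- config$membrane$V_rest
    nr <- config$numerics$init_relax_steps
    dtr <- config$numerics$init_relax_dt * 1e-3
    scale <- 1
    for (it in seq_len(config$numerics$init_calib_iters)) {
      conc <- seed_double_layers(uniform(), mesh, config, work, scale)
      r <- relax_equilibrate(conc, mesh, config, work, nr, dtr)
      conc <- r$conc; phi <- r$phi
      V <- (phi[work$pairing$node_intra] -
            phi[work$pairing$node_extra]) * 1000
      # target the node interior: the centre sites are the reference the
      # protocol watches, and the corner sites carry geometric structure
      Vref <- median(V[work$pairing$s >= 0.2 & work$pairing$s <= 0.8])
      if (abs(Vref - Vt) < 0.02) break
      scale <- scale * Vt / Vref
    }
    if (isTRUE(config$numerics$init_site_correction)) {
      # Null the residual per-site error of the equilibrated rest state
      # with small extra face dipoles.  The site voltages respond linearly
      # to the dipole strengths, so one influence-matrix solve is exact.
      trace <- function(ph)
        (ph[work$pairing$node_intra] - ph[work$pairing$node_extra]) * 1000
      plainV <- function(cc)
        trace(solve_poisson(mesh, cc, t = 0, config, work = work))
      ns <- nrow(work$pairing)
      V_now <- trace(phi)
      base_plain <- plainV(conc)
      probe <- rep(1e-3, ns)   # 1 mV everywhere
      gain <- plainV(seed_site_dipoles(conc, mesh, config, work, probe)) -
        base_plain             # mV response per mV of face dipole
      gain <- pmax(gain, 0.2)  # corner sites respond weakly
      for (it in 1:3) {
        dV <- 0.8 * (Vt - V_now) / gain * 1e-3     # V
        dV <- pmin(pmax(dV, -5e-3), 5e-3)
        conc <- seed_site_dipoles(conc, mesh, config, work, dV)
        new_plain <- plainV(conc)
        V_now <- V_now + (new_plain - base_plain)
        base_plain <- new_plain
        if (max(abs(V_now - Vt)) < 0.05) break
      }
      phi <- solve_poisson(mesh, conc, t = 0, config, dt = dtr,
                           phi_prev = phi, work = work)
    }
  }
  if (is.null(phi))
    phi <- solve_poisson(mesh, conc, t = 0, config, work = work)
  V <- (phi[work$pairing$node_intra] - phi[work$pairing$node_extra]) * 1000
  reg <- gating_registry(config)
  g <- steady_state_gating(V, reg)
  sc <- site_concentrations(conc, work)
  flux <- membrane_flux(g, V, sc$intra, sc$extra, config$constants, reg)
  structure(list(t = 0, phi = phi, conc = conc,
                 gating = g, V = V, flux = flux, step = 0L,
                 diagnostics = list()), class = "sim_state")
}

state_diagnostics <- function(state, config, work) {
  masses <- unlist(lapply(names(state$conc), function(nm) {
    c(setNames(sum(work$sys$I$Mlump * state$conc[[nm]]$I),
               paste0("mass_", nm, "_I")),
      setNames(sum(work$sys$E$Mlump * state$conc[[nm]]$E),
               paste0("mass_", nm, "_E")))
  }))
  c(t = state$t, masses,
    min_conc = min(vapply(state$conc, function(f) min(f$I, f$E), 0)),
    V_min = min(state$V), V_max = max(state$V))
}

#' Advance the simulation by one outer time step
#'
#' Executes the three Gauss-Seidel sub-steps in order: (1) the Poisson
#' solve with the current concentrations gives the new potential; (2) the
#' membrane gating ODEs advance under the new, frozen transmembrane voltage
#' (stiff inner integration, step at most `dt_inner_max`) and the per-site
#' fluxes are evaluated; (3) one backward-Euler Nernst-Planck step moves
#' the concentration fields with the frozen potential and the membrane flux
#' as a surface source.
#'
#' @param state a `sim_state`.
#' @param config a `tes_config`.
#' @param mesh the mesh the state lives on.
#' @param work internal workspace (built if missing).
#' @return the advanced `sim_state`.
#' @export
step_state <- function(state, config, mesh, work = NULL) {
  if (is.null(work)) work <- driver_workspace(mesh, config)
  dt <- config$stepping$dt_outer * 1e-3   # s
  t_new <- state$t + dt
  phi <- solve_poisson(mesh, state$conc, t_new, config,
                       dt = dt, phi_prev = state$phi, work = work)
  V <- (phi[work$pairing$node_intra] - phi[work$pairing$node_extra]) * 1000
  reg <- gating_registry(config)
  ns <- length(V)
  m <- n <- h <- numeric(ns)
  for (j in seq_len(ns)) {
    gj <- advance_gating(list(m = state$gating$m[j], n = state$gating$n[j],
                              h = state$gating$h[j]),
                         V[j], config$stepping$dt_outer,
                         config$stepping$dt_inner_max, reg)
    m[j] <- gj$m; n[j] <- gj$n; h[j] <- gj$h
  }
  g <- list(m = m, n = n, h = h)
  sc <- site_concentrations(state$conc, work)
  flux <- membrane_flux(g, V, sc$intra, sc$extra, config$constants, reg)
  conc <- step_nernst_planck(mesh, state$conc, phi, flux, dt,
                             theta = config$numerics$theta, config, work)
  rep_ <- attr(conc, "report")
  ref <- vapply(config$ions, function(i) max(i$n_init_intra, i$n_bulk_extra), 0)
  for (nm in names(config$ions)) {
    worst <- min(rep_[[paste0(nm, ".I")]], rep_[[paste0(nm, ".E")]])
    if (worst < -config$numerics$negativity_tol * ref[[nm]])
      stop(sprintf(
        "negative-concentration breach for %s at t = %.4f ms (min %.3g)",
        nm, t_new * 1000, worst))
  }
  structure(list(t = t_new, phi = phi, conc = conc, gating = g, V = V,
                 flux = flux, step = state$step + 1L,
                 diagnostics = state$diagnostics), class = "sim_state")
}

#' Run a full TES simulation
#'
#' Builds (or accepts) the mesh, initializes the state and marches the
#' coupled system to `t_end`, recording the transmembrane voltage, gating
#' variables and per-ion membrane fluxes at every membrane site and every
#' outer step, plus field checkpoints at the configured cadence.  The run
#' is deterministic: identical configuration and mesh give bit-identical
#' results.
#'
#' @param config a `tes_config`.
#' @param mesh optional pre-built `tagged_mesh`; built from the
#'   configuration when `NULL`.
#' @param progress print a progress line every millisecond of model time.
#' @return a `tes_result` object; see [site_time_series()],
#'   [transmembrane_voltage_profile()], [region_total()].
#' @export
simulate_tes <- function(config = default_parameters(), mesh = NULL,
                         progress = FALSE) {
  stop_if_invalid(config)
  if (is.null(mesh))
    mesh <- generate_mesh(build_domain_spec(config), config$mesh)
  work <- driver_workspace(mesh, config)
  state <- initialize_state(config, mesh, work)
  nsteps <- round(config$stepping$t_end / config$stepping$dt_outer)
  ck_every <- max(1L, round(config$output$checkpoint_every /
                            config$stepping$dt_outer))
  ns <- nrow(work$pairing)
  times <- numeric(nsteps + 1)
  Vm <- Mm <- Nm <- Hm <- matrix(NA_real_, nsteps + 1, ns)
  fluxes <- lapply(config$ions, function(i)
    matrix(NA_real_, nsteps + 1, ns))
  diagnostics <- vector("list", nsteps + 1)
  checkpoints <- list()
  record <- function(k, st) {
    times[k] <<- st$t
    Vm[k, ] <<- st$V; Mm[k, ] <<- st$gating$m
    Nm[k, ] <<- st$gating$n; Hm[k, ] <<- st$gating$h
    for (nm in names(fluxes)) fluxes[[nm]][k, ] <<- st$flux[, nm]
    diagnostics[[k]] <<- state_diagnostics(st, config, work)
  }
  record(1, state)
  checkpoints[[1]] <- list(t = state$t, phi = state$phi, conc = state$conc)
  for (k in seq_len(nsteps)) {
    state <- step_state(state, config, mesh, work)
    record(k + 1, state)
    if (k %% ck_every == 0 || k == nsteps)
      checkpoints[[length(checkpoints) + 1]] <-
        list(t = state$t, phi = state$phi, conc = state$conc)
    if (progress && k %% round(1 / config$stepping$dt_outer) == 0)
      message(sprintf("t = %.2f ms (V range %.2f .. %.2f mV)",
                      state$t * 1000, min(state$V), max(state$V)))
  }
  structure(list(
    config = config, mesh = mesh, pairing = work$pairing,
    times = times, V = Vm, m = Mm, n = Nm, h = Hm, flux = fluxes,
    checkpoints = checkpoints,
    diagnostics = do.call(rbind, diagnostics),
    provenance = run_provenance(config, mesh)
  ), class = "tes_result")
}

run_provenance <- function(config, mesh) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf)
  list(config_hash = unname(tools::md5sum(tf)),
       mesh = mesh$provenance,
       package_version = as.character(utils::packageVersion("pnpaxon")),
       r_version = R.version.string)
}
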