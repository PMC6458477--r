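# Independent small-scale verification oracles: the isolated point-membrane
# Hodgkin-Huxley model, Boltzmann-equilibrium and Debye-layer checks, and a
# manufactured-solution convergence test for the Poisson solver.

#' Generic rectangular strip mesh
#'
#' Builds a single-region structured triangle mesh for the small
#' verification problems.  The top edge carries both a `G1` facet row (bulk
#' concentration Dirichlet for the Nernst-Planck step) and a `GR` row
#' (potential Dirichlet for the Poisson solve) when requested; other edges
#' get inert `WALL` labels (natural zero-flux) unless overridden.
#'
#' @param xg,yg strictly increasing grid vectors (m).
#' @param region subdomain label for every cell, or a `function(x, y)` of
#'   cell centroids returning `"I"`, `"M"` or `"E"` (layered test problems).
#' @param top,bottom,left,right character vectors of facet labels per edge.
#' @return a `tagged_mesh`.
#' @export
make_strip_mesh <- function(xg, yg, region = "E",
                            top = c("G1", "GR"), bottom = "BOT",
                            left = "WALL", right = "WALL") {
  nx <- length(xg); ny <- length(yg)
  nid <- function(i, j) (j - 1L) * nx + i
  nodes <- cbind(x = rep(xg, ny), y = rep(yg, each = nx))
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- nid(i, j); b <- nid(i + 1L, j); cc <- nid(i + 1L, j + 1L)
  d <- nid(i, j + 1L)
  tri <- matrix(0L, 2 * length(a), 3)
  tri[seq(1, nrow(tri), 2), ] <- cbind(a, b, cc)
  tri[seq(2, nrow(tri), 2), ] <- cbind(a, cc, d)
  if (is.function(region)) {
    cx <- (xg[i] + xg[i + 1L]) / 2
    cy <- (yg[j] + yg[j + 1L]) / 2
    subdom <- rep(region(cx, cy), each = 2L)
  } else subdom <- rep(region, nrow(tri))
  edge_side <- if (is.function(region)) NA_character_ else region
  fac <- list()
  add <- function(n1, n2, label)
    fac[[length(fac) + 1L]] <<- data.frame(n1 = n1, n2 = n2, label = label,
                                           side = edge_side,
                                           cell = NA_integer_)
  ii <- seq_len(nx - 1L); jj <- seq_len(ny - 1L)
  for (lb in bottom) add(nid(ii, 1L), nid(ii + 1L, 1L), lb)
  for (lb in top) add(nid(ii, ny), nid(ii + 1L, ny), lb)
  for (lb in left) add(nid(1L, jj), nid(1L, jj + 1L), lb)
  for (lb in right) add(nid(nx, jj), nid(nx, jj + 1L), lb)
  mesh <- structure(list(
    nodes = nodes, tri = tri, subdomain = subdom,
    facets = do.call(rbind, fac), xg = xg, yg = yg, spec = NULL,
    res = list(preset = "strip"),
    provenance = list(n_nodes = nrow(nodes), n_cells = nrow(tri),
                      preset = "strip")
  ), class = "tagged_mesh")
  mesh$facets$cell <- rebuild_facet_cells(mesh)
  mesh
}

# ---------------------------------------------------------------------------
# Point-membrane Hodgkin-Huxley model
# ---------------------------------------------------------------------------

#' Isolated point-membrane model
#'
#' Integrates the space-clamped membrane equation
#' `C dV/dt = -sum_i I_i(V, gating)` with the same rate registry and
#' conductances as the full simulator, at fixed intracellular and
#' extracellular concentrations.  The capacitance per area is the nodal
#' membrane's dielectric value `eps_memb*eps0/thickness`.  This is the
#' classical equivalent-circuit reduction of the PNP membrane and serves as
#' the independent cross-check of the coupled model's resting behaviour.
#'
#' `V_offset` models a TES-like extracellular potential shift: the
#' transmembrane voltage `V = phi_I - phi_E` jumps by `-V_offset` at t = 0.
#'
#' @param config a `tes_config`.
#' @param duration duration, ms.
#' @param V_offset extracellular shift, mV.
#' @param V0 initial transmembrane voltage, mV (default: resting value of
#'   the configuration plus nothing; use any subthreshold value).
#' @param n_out number of output samples.
#' @return data.frame with columns `t` (ms), `V` (mV), `m`, `n`, `h`.
#' @export
point_membrane_run <- function(config = default_parameters(), duration = 50,
                               V_offset = 0, V0 = NULL, n_out = 501) {
  stopifnot(duration > 0)
  reg <- gating_registry(config)
  ct <- config$constants
  Cm <- ct$eps_memb * ct$eps0 / config$geometry$membrane_thickness_node
  ci <- vapply(config$ions, function(i) i$n_init_intra, 0)
  ce <- vapply(config$ions, function(i) i$n_bulk_extra, 0)
  E <- reversal_potentials(ci, ce, ct)
  if (is.null(V0)) V0 <- config$membrane$V_rest
  V0 <- V0 - V_offset
  g0 <- steady_state_gating(V0, reg)
  rhs <- function(t, y, p) {
    V <- y[1]; m <- y[2]; n <- y[3]; h <- y[4]
    mv <- 1e-3
    I <- reg$g_Na * m^3 * h * (V - E[["Na"]]) * mv +
         reg$g_K * n^4 * (V - E[["K"]]) * mv +
         reg$g_Ca * m * (V - E[["Ca"]]) * mv +
         reg$g_Cl * (V - E[["Cl"]]) * mv
    list(c(-I / Cm,
           reg$alpha_m(V) * (1 - m) - reg$beta_m(V) * m,
           reg$alpha_n(V) * (1 - n) - reg$beta_n(V) * n,
           reg$alpha_h(V) * (1 - h) - reg$beta_h(V) * h))
  }
  out <- deSolve::lsoda(c(V0, g0$m, g0$n, g0$h),
                        seq(0, duration, length.out = n_out), rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  data.frame(t = out[, 1], V = out[, 2], m = out[, 3], n = out[, 4],
             h = out[, 5])
}

#' Resting potential of the point-membrane model
#'
#' Integrates the point-membrane model from a subthreshold voltage until
#' the state is stationary and returns the equilibrium transmembrane
#' voltage.
#'
#' @param config a `tes_config`.
#' @param V0 starting voltage, mV.
#' @param duration integration span, ms (several gating time constants).
#' @return equilibrium voltage, mV.
#' @export
point_membrane_rest <- function(config = default_parameters(), V0 = -60,
                                duration = 400) {
  run <- point_membrane_run(config, duration = duration, V0 = V0)
  k <- nrow(run)
  dV <- abs(run$V[k] - run$V[k - 1]) / (run$t[k] - run$t[k - 1])
  if (dV > 1e-6)
    warning(sprintf("dV/dt = %.2g mV/ms at the end of the window", dV))
  run$V[k]
}

# ---------------------------------------------------------------------------
# Boltzmann equilibrium
# ---------------------------------------------------------------------------

#' Deviation of a steady concentration field from the Boltzmann profile
#'
#' For a frozen potential and closed boundaries, the zero-flux steady state
#' of the Nernst-Planck equation is `n = C exp(-alpha*phi)` with `C` fixed
#' by mass conservation.  Returns the maximum nodal deviation relative to
#' `C`, with `C` fitted by total-mass matching.
#'
#' @param phi nodal potential, V.
#' @param alpha drift coefficient of the ion, 1/V.
#' @param n_steady nodal steady concentrations.
#' @param mass_lump lumped-mass weights of the nodes (from the mesh).
#' @return maximum relative deviation (dimensionless).
#' @export
boltzmann_check <- function(phi, alpha, n_steady, mass_lump) {
  prof <- exp(-alpha * phi)
  C <- sum(mass_lump * n_steady) / sum(mass_lump * prof)
  max(abs(n_steady - C * prof)) / C
}

#' Relax the Nernst-Planck step to steady state under a frozen potential
#'
#' Repeated backward-Euler steps on a closed strip with an externally
#' prescribed potential; used to verify the Boltzmann equilibrium property
#' of [step_nernst_planck()].
#'
#' @param mesh a closed strip mesh (no `G1`/`GL`/`GR` facets).
#' @param phi frozen nodal potential, V.
#' @param config a `tes_config` (ion table and constants).
#' @param dt step, s.
#' @param nsteps number of steps.
#' @return per-ion fields as in [step_nernst_planck()], with the workspace
#'   in attribute `work`.
#' @export
relax_frozen_potential <- function(mesh, phi, config, dt, nsteps) {
  work <- poisson_workspace(mesh, config)
  rg <- mesh$subdomain[1]
  conc <- lapply(config$ions, function(io) {
    f <- list()
    f[[rg]] <- rep(if (rg == "I") io$n_init_intra else io$n_bulk_extra,
                   work$sys[[rg]]$ndof)
    f
  })
  for (k in seq_len(nsteps))
    conc <- step_nernst_planck(mesh, conc, phi, NULL, dt,
                               theta = config$numerics$theta, config, work)
  attr(conc, "work") <- work
  conc
}

# ---------------------------------------------------------------------------
# Debye-layer profile
# ---------------------------------------------------------------------------

#' Fitted vs analytic Debye screening length
#'
#' Equilibrates the four-ion extracellular electrolyte against a weakly
#' charged wall on a finely resolved strip (TES off, bulk reservoir on
#' top), fits an exponential to the near-wall potential decay, and
#' compares the fitted length to the analytic
#' `lambda_D = sqrt(eps*R*T / (F^2 sum_i z_i^2 n_i0))`.
#'
#' @param config a `tes_config`.
#' @param conc_scale multiply all bulk concentrations (scaling checks).
#' @param eps_scale multiply the electrolyte permittivity.
#' @param sigma wall surface charge, C/m^2 (small: linear screening).
#' @param height strip height, m.
#' @return list with `fitted`, `analytic` (m) and their `ratio`.
#' @export
debye_profile_check <- function(config = default_parameters(),
                                conc_scale = 1, eps_scale = 1,
                                sigma = 2e-3, height = 12e-9) {
  cfg <- config
  cfg$constants$eps_c <- cfg$constants$eps_c * eps_scale
  for (nm in names(cfg$ions))
    cfg$ions[[nm]]$n_bulk_extra <- cfg$ions[[nm]]$n_bulk_extra * conc_scale
  cfg$numerics$electrodes <- "blocking"
  ct <- cfg$constants
  lam_a <- debye_length(lapply(cfg$ions, function(i) i$n_bulk_extra),
                        cfg$ions, ct)
  yg <- cumsum(c(0, graded_steps(height, hA = lam_a / 12, bandA = lam_a,
                                 hB = height / 6, bandB = 0,
                                 hmax = height / 6, ratio = 1.25)))
  xg <- seq(0, 2e-9, length.out = 3)
  mesh <- make_strip_mesh(xg, yg)
  work <- poisson_workspace(mesh, cfg)
  conc <- lapply(cfg$ions, function(io)
    list(E = rep(io$n_bulk_extra, work$sys$E$ndof)))
  bottom <- mesh$facets[mesh$facets$label == "BOT", ]
  sc <- list(facets = bottom, sigma = rep(sigma, nrow(bottom)))
  dt <- 2e-9
  phi <- solve_poisson(mesh, conc, 0, cfg, surface_charge = sc, work = work)
  for (k in 1:150) {
    phi <- solve_poisson(mesh, conc, 0, cfg, dt = dt, phi_prev = phi,
                         surface_charge = sc, work = work)
    conc <- step_nernst_planck(mesh, conc, phi, NULL, dt, 1, cfg, work)
  }
  mid <- which(abs(mesh$nodes[, 1] - 1e-9) < 1e-12)
  y <- mesh$nodes[mid, 2]; p <- phi[mid]
  o <- order(y); y <- y[o]; p <- p[o]
  p <- p - p[length(p)]                    # reference: bulk/reservoir value
  sel <- y > 0.3 * lam_a & y < 3 * lam_a & p > 0
  if (sum(sel) < 4)
    stop("Debye fit failure: wall layer under-resolved")
  fit <- lm(log(p[sel]) ~ y[sel])
  fitted <- -1 / coef(fit)[[2]]
  list(fitted = fitted, analytic = lam_a, ratio = fitted / lam_a)
}

# ---------------------------------------------------------------------------
# Manufactured-solution convergence for the Poisson discretization
# ---------------------------------------------------------------------------

#' L2 errors of the Poisson solver on a manufactured solution
#'
#' Solves `-div(eps grad phi) = f` with
#' `phi* = sin(pi x / L) sin(pi y / H)` on a uniform strip at a sequence of
#' refinements and returns the L2 errors; piecewise-linear elements halve
#' the error by about 4 per refinement.
#'
#' @param n0 coarsest grid intervals per side.
#' @param levels number of refinement levels.
#' @param L,H domain size, m.
#' @return numeric vector of L2 errors, one per level.
#' @export
poisson_mms_convergence <- function(n0 = 8, levels = 3, L = 1e-6, H = 1e-6) {
  eps <- 1.0
  errs <- numeric(levels)
  for (lev in seq_len(levels)) {
    n <- n0 * 2^(lev - 1)
    mesh <- make_strip_mesh(seq(0, L, length.out = n + 1),
                            seq(0, H, length.out = n + 1))
    geom <- mesh_geom(mesh)
    ndof <- nrow(mesh$nodes)
    K <- assemble_stiffness(mesh$tri, geom, eps, ndof = ndof)
    M <- assemble_mass(mesh$tri, geom, ndof = ndof)
    x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
    exact <- sin(pi * x / L) * sin(pi * y / H)
    f <- eps * (pi^2 / L^2 + pi^2 / H^2) * exact
    rhs <- as.numeric(M %*% f)
    bnd <- which(x < 1e-15 | x > L - 1e-15 | y < 1e-15 | y > H - 1e-15)
    ad <- apply_dirichlet(K, rhs, bnd, rep(0, length(bnd)))
    phi <- as.numeric(Matrix::solve(ad$A, ad$rhs))
    e <- phi - exact
    errs[lev] <- sqrt(sum(as.numeric(M %*% e) * e))
  }
  errs
}
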