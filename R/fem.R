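# Piecewise-linear finite elements on the tagged triangle mesh.
#
# Both the electric potential and the ion concentrations use P1 simplex
# elements.  The potential lives on the whole domain; each concentration
# field lives on one bulk region (I or E), with the nodal membrane acting
# as a pair of flux boundaries.
#
# Assembly uses a fixed sparsity skeleton per system: triplet (i,j) index
# vectors are computed once, mapped to the slots of a dgCMatrix, and each
# time step only writes new values into @x.  This keeps the per-step cost
# dominated by the sparse solves, not by S4 matrix construction.

# per-cell geometry: areas and barycentric gradient components
mesh_geom <- function(mesh) {
  tr <- mesh$tri
  x1 <- mesh$nodes[tr[, 1], 1]; y1 <- mesh$nodes[tr[, 1], 2]
  x2 <- mesh$nodes[tr[, 2], 1]; y2 <- mesh$nodes[tr[, 2], 2]
  x3 <- mesh$nodes[tr[, 3], 1]; y3 <- mesh$nodes[tr[, 3], 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  inv2A <- 1 / (2 * area)
  list(area = area,
       bx = cbind((y2 - y3) * inv2A, (y3 - y1) * inv2A, (y1 - y2) * inv2A),
       by = cbind((x3 - x2) * inv2A, (x1 - x3) * inv2A, (x2 - x1) * inv2A))
}

# ---------------------------------------------------------------------------
# Skeleton-based sparse assembly
# ---------------------------------------------------------------------------

# Map triplets (I, J) to slots of the corresponding dgCMatrix once.
make_skeleton <- function(I, J, ndof) {
  key <- (J - 1) * ndof + I
  ord <- order(key)
  uk <- key[ord]
  new_grp <- c(TRUE, diff(uk) > 0)
  slot_sorted <- cumsum(new_grp)
  slots <- integer(length(key))
  slots[ord] <- slot_sorted
  skel <- sparseMatrix(i = I, j = J, x = rep(1, length(I)),
                       dims = c(ndof, ndof))
  skel@x[] <- 0
  diag_lookup <- function(nodes) {
    kd <- (nodes - 1) * ndof + nodes
    findInterval(kd, uk[new_grp])
  }
  list(skel = skel, slots = slots, nx = max(slot_sorted),
       rowind = skel@i + 1L, diag_lookup = diag_lookup)
}

# Sum triplet values into the skeleton's slots and return the matrix.
# Dirichlet rows keep their own diagonal entry (zeroing only the
# off-diagonals) so the system stays well scaled; the preserved diagonal
# values are returned in attribute "dirich_diag" for scaling the rhs.
assemble_fast <- function(sk, vals, dirich = NULL) {
  xs <- as.numeric(rowsum(vals, sk$slots))
  dv <- NULL
  if (!is.null(dirich)) {
    dv <- xs[dirich$diag_slots]
    xs[dirich$slot_mask] <- 0
    xs[dirich$diag_slots] <- dv
  }
  A <- sk$skel
  A@x <- xs
  if (!is.null(dv)) attr(A, "dirich_diag") <- dv
  A
}

# Classic one-off assembly (used by the small verification problems).
assemble_stiffness <- function(tri, geom, coef, cells = seq_len(nrow(tri)),
                               ndof = max(tri)) {
  tv <- cell_triplets(tri, geom, cells)
  sparseMatrix(i = tv$I, j = tv$J, x = stiffness_values(tv, coef),
               dims = c(ndof, ndof))
}

assemble_mass <- function(tri, geom, cells = seq_len(nrow(tri)),
                          ndof = max(tri)) {
  tv <- cell_triplets(tri, geom, cells)
  sparseMatrix(i = tv$I, j = tv$J, x = mass_values(tv),
               dims = c(ndof, ndof))
}

# triplet index vectors and per-cell geometry in block order: (a,b) blocks,
# a (test) outer, b (trial) inner, each block one value per cell
cell_triplets <- function(tri, geom, cells = seq_len(nrow(tri))) {
  tr <- tri[cells, , drop = FALSE]
  I <- J <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    I[[k]] <- tr[, a]; J[[k]] <- tr[, b]
  }
  list(I = unlist(I), J = unlist(J), a = rep(1:3, each = 3),
       b = rep.int(1:3, 3), ncell = length(cells),
       area = geom$area[cells],
       bx = geom$bx[cells, , drop = FALSE],
       by = geom$by[cells, , drop = FALSE])
}

stiffness_values <- function(tv, coef) {
  v <- vector("list", 9)
  for (k in 1:9) {
    a <- tv$a[k]; b <- tv$b[k]
    v[[k]] <- coef * tv$area * (tv$bx[, a] * tv$bx[, b] +
                                tv$by[, a] * tv$by[, b])
  }
  unlist(v)
}

mass_values <- function(tv) {
  v <- vector("list", 9)
  for (k in 1:9)
    v[[k]] <- tv$area / 12 * (1 + (tv$a[k] == tv$b[k]))
  unlist(v)
}

# drift values for int n grad(phi).grad(v): depends on the test index a only
drift_values <- function(tv, gphix, gphiy) {
  v <- vector("list", 9)
  for (k in 1:9) {
    a <- tv$a[k]
    v[[k]] <- tv$area / 3 * (gphix * tv$bx[, a] + gphiy * tv$by[, a])
  }
  unlist(v)
}

# cellwise gradient of a nodal field
cell_gradient <- function(tri, geom, v, cells = seq_len(nrow(tri))) {
  tr <- tri[cells, , drop = FALSE]
  gx <- geom$bx[cells, 1] * v[tr[, 1]] + geom$bx[cells, 2] * v[tr[, 2]] +
        geom$bx[cells, 3] * v[tr[, 3]]
  gy <- geom$by[cells, 1] * v[tr[, 1]] + geom$by[cells, 2] * v[tr[, 2]] +
        geom$by[cells, 3] * v[tr[, 3]]
  cbind(gx, gy)
}

# replace Dirichlet rows: A[d,] = e_d, rhs[d] = value (one-off variant)
apply_dirichlet <- function(A, rhs, idx, vals) {
  if (!length(idx)) return(list(A = A, rhs = rhs))
  mask <- rep(1, nrow(A)); mask[idx] <- 0
  A <- Diagonal(x = mask) %*% A + sparseMatrix(i = idx, j = idx,
                                               x = rep(1, length(idx)),
                                               dims = dim(A))
  rhs[idx] <- vals
  list(A = A, rhs = rhs)
}

make_dirichlet <- function(sk, rows) {
  list(rows = rows,
       slot_mask = sk$rowind %in% rows,   # rowind: row of each @x slot
       diag_slots = sk$diag_lookup(rows))
}

# ---------------------------------------------------------------------------
# Region systems: everything constant-in-time for one bulk region
# ---------------------------------------------------------------------------

region_system <- function(mesh, region, geom = mesh_geom(mesh),
                          electrodes = "open") {
  cells <- which(mesh$subdomain == region)
  gnodes <- sort(unique(as.vector(mesh$tri[cells, ])))
  g2l <- rep(NA_integer_, nrow(mesh$nodes))
  g2l[gnodes] <- seq_along(gnodes)
  ltri <- matrix(g2l[mesh$tri[cells, ]], ncol = 3)
  lgeom <- list(area = geom$area[cells],
                bx = geom$bx[cells, , drop = FALSE],
                by = geom$by[cells, , drop = FALSE])
  n <- length(gnodes)
  tv <- cell_triplets(ltri, lgeom)
  f <- mesh$facets[!is.na(mesh$facets$side) & mesh$facets$side == region, ]
  lcell <- match(f$cell, cells)
  facets <- data.frame(l1 = g2l[f$n1], l2 = g2l[f$n2], label = f$label,
                       cell = lcell, len = facet_lengths(mesh, f))
  el <- facets[facets$label %in% c("GL", "GR") & region == "E" &
               electrodes == "open", ]
  reservoir <- facets[facets$label %in% c("GL", "GR") & region == "E" &
                      electrodes == "reservoir", ]
  trip_I <- tv$I; trip_J <- tv$J
  ncv <- length(trip_I)
  if (nrow(el)) {
    trip_I <- c(trip_I, el$l1, el$l2, el$l1, el$l2)
    trip_J <- c(trip_J, el$l1, el$l2, el$l2, el$l1)
  }
  sk <- make_skeleton(trip_I, trip_J, n)
  M_vals <- c(mass_values(tv), numeric(length(trip_I) - ncv))
  K1_vals <- c(stiffness_values(tv, 1), numeric(length(trip_I) - ncv))
  M <- assemble_fast(sk, M_vals)
  g1 <- facets[facets$label == "G1", ]
  dir_idx <- sort(unique(c(g1$l1, g1$l2, reservoir$l1, reservoir$l2)))
  list(region = region, cells = cells, gnodes = gnodes, g2l = g2l,
       tri = ltri, geom = lgeom, ndof = n, tv = tv, sk = sk,
       M_vals = M_vals, K1_vals = K1_vals, n_cell_trip = ncv,
       M = M, Mlump = as.numeric(M %*% rep(1, n)),
       K1 = assemble_fast(sk, K1_vals),
       facets = facets, electrode = el,
       dirich = if (length(dir_idx)) make_dirichlet(sk, dir_idx) else NULL)
}

# conductivity sigma = F^2/(RT) sum_i z_i^2 D_i n_i, per cell of a region
region_conductivity <- function(sys, conc_region, ions, constants) {
  sig <- 0
  for (nm in names(ions)) {
    nc <- conc_region[[nm]]
    ncell <- (nc[sys$tri[, 1]] + nc[sys$tri[, 2]] + nc[sys$tri[, 3]]) / 3
    io <- ions[[nm]]
    sig <- sig + constants$F * io$z * io$alpha * io$D * ncell
  }
  sig
}

# immobile background charge density per region (C/m^3)
background_charge <- function(config) {
  if (!isTRUE(config$numerics$neutral_background))
    return(c(I = 0, E = 0))
  zs <- vapply(config$ions, function(i) i$z, 0)
  intra <- vapply(config$ions, function(i) i$n_init_intra, 0)
  extra <- vapply(config$ions, function(i) i$n_bulk_extra, 0)
  c(I = -config$constants$F * sum(zs * intra),
    E = -config$constants$F * sum(zs * extra))
}

# ---------------------------------------------------------------------------
# TES protocol
# ---------------------------------------------------------------------------

#' Dirichlet potential on the stimulation boundary
#'
#' The default protocol is a step: 0 V up to and including the activation
#' time, then the configured amplitude (0.1 V).  Alternative stimulation
#' waveforms plug in through `tes$waveform`, a `function(t_seconds)` used
#' verbatim once set.
#'
#' @param t time, seconds.
#' @param tes the `tes` block of a configuration.
#' @param t_tes_on activation time, ms.
#' @return potential on the left boundary, V.
#' @export
tes_boundary_value <- function(t, tes, t_tes_on = 2) {
  if (!is.null(tes$waveform)) return(tes$waveform(t))
  # the activation time itself is pre-stimulus ("t <= t_on" -> 0); the
  # tolerance guards against accumulated floating-point drift in t
  ifelse(t * 1000 > t_tes_on * (1 + 1e-9) + 1e-12, tes$amplitude, 0)
}

# ---------------------------------------------------------------------------
# Poisson solve
# ---------------------------------------------------------------------------

#' Solve the Poisson equation for the electric potential
#'
#' Solves `div(eps grad phi) = -F sum_i z_i n_i` (plus the immobile
#' background charge when configured) over the whole domain, with the TES
#' Dirichlet values on the left/right extracellular boundaries and natural
#' zero-Neumann conditions elsewhere.
#'
#' When `dt` and `phi_prev` are supplied, the ohmic charge response is
#' treated implicitly by a deferred correction:
#' `div((eps + dt*sigma) grad phi) = rhs + dt div(sigma grad phi_prev)`,
#' with `sigma` the local electrolyte conductivity.  The correction vanishes
#' at any self-consistent steady state, so fixed points are those of the
#' plain equation; it removes the dielectric-relaxation stiffness that makes
#' the lagged splitting explode at outer steps far above the Maxwell time.
#'
#' @param mesh a `tagged_mesh`.
#' @param conc per-ion concentration fields: named list, each
#'   `list(I = , E = )` of region-local nodal vectors (mol/m^3).
#' @param t time, seconds (selects the TES boundary value).
#' @param config a `tes_config`.
#' @param dt,phi_prev outer step (s) and previous potential for the
#'   stabilized splitting; omit both for a plain electrostatic solve.
#' @param surface_charge optional fixed surface charge: list with `facets`
#'   (rows of `mesh$facets`) and `sigma` (C/m^2 per facet).
#' @param work precomputed workspace from the driver (internal).
#' @return nodal potential over the whole mesh, V.
#' @export
solve_poisson <- function(mesh, conc, t, config, dt = NULL, phi_prev = NULL,
                          surface_charge = NULL, work = NULL) {
  if (is.null(work)) work <- poisson_workspace(mesh, config)
  ct <- config$constants
  ndof <- nrow(mesh$nodes)
  rho <- numeric(ndof)
  bg <- background_charge(config)
  for (rg in intersect(c("I", "E"), names(work$sys))) {
    sys <- work$sys[[rg]]
    loc <- numeric(sys$ndof)
    for (nm in names(config$ions))
      loc <- loc + config$ions[[nm]]$z * conc[[nm]][[rg]]
    rho[sys$gnodes] <- ct$F * loc + bg[[rg]]
  }
  rhs <- as.numeric(work$M_bulk %*% rho)
  if (!is.null(surface_charge)) {
    f <- surface_charge$facets
    len <- facet_lengths(mesh, f)
    w <- surface_charge$sigma * len / 2
    add <- numeric(ndof)
    for (kk in seq_len(nrow(f))) {
      add[f$n1[kk]] <- add[f$n1[kk]] + w[kk]
      add[f$n2[kk]] <- add[f$n2[kk]] + w[kk]
    }
    rhs <- rhs + add
  }
  vals <- work$K_eps_vals
  if (!is.null(dt) && !is.null(phi_prev) &&
      isTRUE(config$numerics$stabilize_poisson)) {
    sig_cell <- numeric(nrow(mesh$tri))
    for (rg in intersect(c("I", "E"), names(work$sys))) {
      sys <- work$sys[[rg]]
      sig_cell[sys$cells] <- region_conductivity(
        sys, lapply(conc, `[[`, rg), config$ions, ct)
    }
    K_sig <- assemble_fast(work$sk, stiffness_values(work$tv, sig_cell))
    vals <- vals + dt * stiffness_values(work$tv, sig_cell)
    rhs <- rhs + dt * as.numeric(K_sig %*% phi_prev)
  }
  bc <- tes_boundary_value(t, config$tes, config$stepping$t_tes_on)
  A <- assemble_fast(work$sk, vals, work$dirich)
  rhs[work$dirich$rows] <- c(rep(bc, length(work$gl_nodes)),
                             rep(config$tes$phi_right,
                                 length(work$gr_nodes))) *
    attr(A, "dirich_diag")
  as.numeric(Matrix::solve(A, rhs))
}

poisson_workspace <- function(mesh, config) {
  geom <- mesh_geom(mesh)
  ct <- config$constants
  eps <- ifelse(mesh$subdomain == "M", ct$eps_memb, ct$eps_c) * ct$eps0
  ndof <- nrow(mesh$nodes)
  bulk <- which(mesh$subdomain != "M")
  f <- mesh$facets
  tv <- cell_triplets(mesh$tri, geom)
  sk <- make_skeleton(tv$I, tv$J, ndof)
  gl <- sort(unique(c(f$n1[f$label == "GL"], f$n2[f$label == "GL"])))
  gr <- sort(unique(c(f$n1[f$label == "GR"], f$n2[f$label == "GR"])))
  regions <- intersect(c("I", "E"), unique(mesh$subdomain))
  sys <- lapply(setNames(regions, regions), function(rg)
    region_system(mesh, rg, geom, config$numerics$electrodes))
  list(geom = geom, tv = tv, sk = sk, sys = sys,
       K_eps_vals = stiffness_values(tv, eps),
       M_bulk = assemble_mass(mesh$tri, geom, bulk, ndof),
       gl_nodes = gl, gr_nodes = gr,
       dirich = make_dirichlet(sk, c(gl, gr)),
       pairing = tryCatch(pair_membrane_traces(mesh),
                          error = function(e) NULL))
}

# ---------------------------------------------------------------------------
# Nernst-Planck step
# ---------------------------------------------------------------------------

#' One theta-rule step of the Nernst-Planck equations
#'
#' Advances every ion concentration field by one implicit time step (theta
#' = 1 is backward Euler, the default) with the drift velocity taken from
#' the frozen potential `phi` (Gauss-Seidel decoupling), so each ion solves
#' one linear advection-diffusion system per region.  The membrane flux is
#' applied as a surface term on the nodal membrane: outward from the
#' intracellular region on the inner face and with opposite sign on the
#' extracellular face, so mass is exchanged, never created.  The bulk
#' Dirichlet values hold on the extracellular top boundary; the electrode
#' boundaries pass migration flux under the default `"open"` electrode
#' model and are fully closed under `"blocking"`.
#'
#' @param mesh a `tagged_mesh`.
#' @param n_prev per-ion fields, named list of `list(I = , E = )`.
#' @param phi nodal potential from the current outer iteration, V.
#' @param memb_flux matrix (sites x ions) of membrane fluxes, mol/(m^2 s),
#'   negative = influx; `NULL` for none.  Rows follow the pairing table.
#' @param dt time step, seconds.
#' @param theta implicitness weight in (0, 1].
#' @param config a `tes_config`.
#' @param work workspace from the driver (internal); built on the fly if
#'   missing.
#' @return fields with the same structure as `n_prev`; attribute `report`
#'   carries the per-region minimum concentrations.
#' @export
step_nernst_planck <- function(mesh, n_prev, phi, memb_flux, dt, theta = 1,
                               config = default_parameters(), work = NULL) {
  if (is.null(work)) work <- poisson_workspace(mesh, config)
  out <- n_prev
  report <- list()
  pairing <- work$pairing
  for (rg in names(work$sys)) {
    sys <- work$sys[[rg]]
    gphi <- cell_gradient(sys$tri, sys$geom, phi[sys$gnodes])
    Gv <- drift_values(sys$tv, gphi[, 1], gphi[, 2])
    nel <- length(sys$sk$slots) - sys$n_cell_trip
    Bv <- numeric(nel)
    if (nel > 0 && nrow(sys$electrode)) {
      el <- sys$electrode
      nrm <- ifelse(el$label == "GL", -1, 1)
      w <- -(gphi[el$cell, 1] * nrm) * el$len / 6
      Bv <- c(2 * w, 2 * w, w, w)
    }
    fl <- sys$facets[sys$facets$label == "G4", ]
    for (nm in names(config$ions)) {
      io <- config$ions[[nm]]
      Lv <- io$D * (sys$K1_vals +
                    io$alpha * c(Gv, numeric(nel)) +
                    io$alpha * c(numeric(sys$n_cell_trip), Bv))
      Av <- sys$M_vals + theta * dt * Lv
      b <- numeric(sys$ndof)
      if (!is.null(memb_flux) && nrow(fl) && !is.null(pairing)) {
        fnode <- numeric(sys$ndof)
        key <- if (rg == "I") pairing$node_intra else pairing$node_extra
        fnode[sys$g2l[key]] <- memb_flux[, nm] * (if (rg == "I") 1 else -1)
        ff <- (fnode[fl$l1] + fnode[fl$l2]) / 2 * fl$len / 2
        for (kk in seq_len(nrow(fl))) {
          b[fl$l1[kk]] <- b[fl$l1[kk]] + ff[kk]
          b[fl$l2[kk]] <- b[fl$l2[kk]] + ff[kk]
        }
      }
      rhs <- as.numeric(sys$M %*% n_prev[[nm]][[rg]]) - dt * b
      if (theta < 1) {
        L <- assemble_fast(sys$sk, Lv)
        rhs <- rhs - (1 - theta) * dt *
          as.numeric(L %*% n_prev[[nm]][[rg]])
      }
      A <- assemble_fast(sys$sk, Av, sys$dirich)
      if (!is.null(sys$dirich))
        rhs[sys$dirich$rows] <- io$n_bulk_extra * attr(A, "dirich_diag")
      nn <- as.numeric(Matrix::solve(A, rhs))
      out[[nm]][[rg]] <- nn
      report[[paste(nm, rg, sep = ".")]] <- min(nn)
    }
  }
  attr(out, "report") <- report
  out
}
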