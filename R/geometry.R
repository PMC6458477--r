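# Axon domain geometry and structured mesh generation.
#
# The domain is a 2D Cartesian slice: the axon lies along x, with the
# intracellular space at the bottom (its horizontal midline is the y = 0
# symmetry boundary), the membrane above it and the extracellular space on
# top.  The membrane is myelinated (thick) everywhere except the node of
# Ranvier, a 1 um segment centred at x = axon_length/2 where it thins to
# 5 nm and the extracellular space dips down to it.  Subdomains are labelled
# I (intracellular), M (membrane), E (extracellular); boundary and interface
# facets carry the labels GL, GR, G1, G2, G3, G4, G5.

#' Domain dimensions from a configuration
#'
#' Copies and validates the geometry block of a configuration.  The default
#' dimensions are: axon length 4 um, node of Ranvier 1 um, myelinated
#' membrane thickness 0.406 um, nodal membrane thickness 5 nm, intracellular
#' half-height 0.434 um, total domain half-height 2 um.
#'
#' @param config a `tes_config`.
#' @return an object of class `domain_spec`.
#' @export
build_domain_spec <- function(config = default_parameters()) {
  ge <- config$geometry
  spec <- structure(ge, class = "domain_spec")
  if (!(spec$node_length > 0 && spec$node_length < spec$axon_length))
    stop("geometry error: need 0 < node_length < axon_length")
  if (!(spec$membrane_thickness_node < spec$membrane_thickness_myelinated))
    stop("geometry error: nodal membrane must be thinner than myelin")
  if (!(spec$intracellular_halfheight + spec$membrane_thickness_myelinated <
        spec$domain_halfheight))
    stop("geometry error: membrane does not fit below the domain top")
  spec
}

# y levels of the horizontal material interfaces
spec_levels <- function(spec) {
  y1 <- spec$intracellular_halfheight
  list(y1 = y1,
       y2 = y1 + spec$membrane_thickness_node,
       y3 = y1 + spec$membrane_thickness_myelinated,
       H  = spec$domain_halfheight,
       xl = spec$axon_length / 2 - spec$node_length / 2,
       xr = spec$axon_length / 2 + spec$node_length / 2,
       L  = spec$axon_length)
}

# Step sizes along one segment of length L, refined towards one or both
# ends: a uniform band of size h at a refined end, then geometric growth by
# `ratio` capped at hmax, with a uniform filler in the middle.  The step
# list is scaled when the two fans overlap, so the breaks always fit L
# exactly.
graded_steps <- function(L, hA, bandA, hB, bandB, hmax, ratio) {
  fan <- function(h0, band, Lhalf) {
    s <- numeric(0)
    if (band > 0) s <- rep(min(h0, Lhalf), max(1L, round(band / h0)))
    h <- h0
    while (sum(s) < Lhalf && h < hmax * (1 - 1e-12)) {
      h <- min(h * ratio, hmax)
      s <- c(s, h)
    }
    s[cumsum(s) <= Lhalf * (1 + 1e-12)]
  }
  fa <- fan(hA, bandA, L / 2)
  fb <- fan(hB, bandB, L / 2)
  used <- sum(fa) + sum(fb)
  if (used >= L) {
    steps <- c(fa, rev(fb)) * (L / used)
  } else {
    mid <- L - used
    nmid <- max(1L, round(mid / hmax))
    steps <- c(fa, rep(mid / nmid, nmid), rev(fb))
  }
  steps
}

#' Generate the tagged axon mesh
#'
#' Builds a conforming triangulation of the axon domain on a structured,
#' graded tensor grid.  Element size equals `res$h_debye` inside a band of
#' width `res$debye_band_width` on both sides of the nodal membrane and
#' grows geometrically away from it; the grid is mirror-symmetric about the
#' node midline (triangle diagonals flip orientation across it, so the
#' triangulation itself is mirror-symmetric).  Every cell carries a
#' subdomain label and every boundary/interface facet a boundary label:
#'
#' * `GL`, `GR`: left/right edges of the extracellular space (electrodes);
#' * `G1`: top of the extracellular space (bulk reservoir);
#' * `G2`: exterior intracellular boundaries (including the y = 0 midline);
#' * `G3`: exterior membrane boundaries (left/right edges);
#' * `G4`: the nodal membrane interface (intracellular-facing and
#'   extracellular-facing faces, plus the two short end facets);
#' * `G5`: all other membrane/cytosol and membrane/extracellular interfaces.
#'
#' The `side` column of the facet table records which bulk region a facet
#' bounds (`I`, `E`, or `M` for facets interior to the membrane).
#'
#' @param spec a `domain_spec` from [build_domain_spec()].
#' @param res resolution controls from [mesh_resolution()].
#' @return an object of class `tagged_mesh`: nodes, triangles, per-cell
#'   subdomain labels, the facet table, grid vectors, and provenance.
#' @export
generate_mesh <- function(spec = build_domain_spec(),
                          res = mesh_resolution("coarse")) {
  if (!(res$h_debye > 0 && res$h_debye <= res$h_bulk))
    stop("mesh resolution error: need 0 < h_debye <= h_bulk")
  lv <- spec_levels(spec)
  dxn <- spec$node_length / (2L * ceiling(res$node_nx / 2))
  dxe <- if (!is.null(res$node_edge_dx)) res$node_edge_dx else dxn

  ## tensor grid, mirror-symmetric in x about the node centre; the node is
  ## refined towards its corners, where the myelin walls shape the
  ## extracellular potential
  half_node <- graded_steps(spec$node_length / 2, hA = dxe, bandA = 2 * dxe,
                            hB = dxn, bandB = 0, hmax = dxn,
                            ratio = res$grade)
  side_steps <- graded_steps(lv$xl, hA = res$h_bulk / 2, bandA = 0,
                             hB = dxe, bandB = 0,
                             hmax = res$h_bulk, ratio = res$grade)
  xg <- cumsum(c(0, side_steps, half_node, rev(half_node), rev(side_steps)))
  xg[length(xg)] <- lv$L
  yg <- cumsum(c(0,
    graded_steps(lv$y1, hA = res$h_bulk, bandA = 0,
                 hB = res$h_debye, bandB = res$debye_band_width,
                 hmax = res$h_bulk, ratio = res$grade),
    rep((lv$y2 - lv$y1) / res$membrane_ny, res$membrane_ny),
    graded_steps(lv$y3 - lv$y2, hA = res$h_debye,
                 bandA = res$debye_band_width, hB = res$h_bulk / 4, bandB = 0,
                 hmax = res$h_bulk, ratio = res$grade),
    graded_steps(lv$H - lv$y3, hA = res$h_bulk / 4, bandA = 0,
                 hB = res$h_bulk, bandB = 0,
                 hmax = res$h_bulk, ratio = res$grade)))
  # snap the material interfaces exactly
  for (yv in c(lv$y1, lv$y2, lv$y3, lv$H)) {
    k <- which.min(abs(yg - yv)); yg[k] <- yv
  }
  nx <- length(xg); ny <- length(yg)
  nid <- function(i, j) (j - 1L) * nx + i

  nodes <- cbind(x = rep(xg, ny), y = rep(yg, each = nx))

  ## cells: two CCW triangles per rectangle, diagonal mirrored across centre
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- nid(i, j); b <- nid(i + 1L, j); cc <- nid(i + 1L, j + 1L)
  d <- nid(i, j + 1L)
  xm <- (xg[i] + xg[i + 1L]) / 2
  ym <- (yg[j] + yg[j + 1L]) / 2
  left <- xm < lv$L / 2
  # diagonal a-c on the left half, b-d on the right half
  tri1 <- cbind(ifelse(left, a, a), ifelse(left, b, b), ifelse(left, cc, d))
  tri2 <- cbind(ifelse(left, a, b), ifelse(left, cc, cc), ifelse(left, d, d))
  tri <- matrix(0L, 2 * length(a), 3)
  tri[seq(1, nrow(tri), by = 2), ] <- tri1
  tri[seq(2, nrow(tri), by = 2), ] <- tri2
  in_node <- xm > lv$xl & xm < lv$xr
  reg <- ifelse(ym < lv$y1, "I",
         ifelse(ym < lv$y2, "M",
         ifelse(ym < lv$y3, ifelse(in_node, "E", "M"), "E")))
  subdomain <- rep(reg, each = 2)

  rect_id <- function(ii, jj) (jj - 1L) * (nx - 1L) + ii
  # cell id of the triangle of rectangle (ii,jj) containing a given edge
  rect_tri <- function(ii, jj, edge) {
    lft <- (xg[ii] + xg[ii + 1L]) / 2 < lv$L / 2
    k <- switch(edge,
                bottom = 1L,
                top    = 2L,
                left   = ifelse(lft, 2L, 1L),
                right  = ifelse(lft, 1L, 2L))
    2L * (rect_id(ii, jj) - 1L) + k
  }

  j1 <- match(lv$y1, yg); j2 <- match(lv$y2, yg); j3 <- match(lv$y3, yg)
  il <- which.min(abs(xg - lv$xl)); ir <- which.min(abs(xg - lv$xr))
  xg[il] <- lv$xl; xg[ir] <- lv$xr
  fac <- list()
  add <- function(n1, n2, label, side, cell)
    fac[[length(fac) + 1L]] <<- data.frame(n1 = n1, n2 = n2, label = label,
                                           side = side, cell = cell)
  ii <- seq_len(nx - 1L)
  xmid <- (xg[ii] + xg[ii + 1L]) / 2
  innode <- xmid > lv$xl & xmid < lv$xr
  ## horizontal interfaces
  add(nid(ii, j1), nid(ii + 1L, j1), ifelse(innode, "G4", "G5"), "I",
      rect_tri(ii, j1 - 1L, "top"))
  add(nid(ii[innode], j2), nid(ii[innode] + 1L, j2), "G4", "E",
      rect_tri(ii[innode], j2, "bottom"))
  add(nid(ii[!innode], j3), nid(ii[!innode] + 1L, j3), "G5", "E",
      rect_tri(ii[!innode], j3, "bottom"))
  ## vertical interfaces at the node edges
  jj <- j2:(j3 - 1L)
  add(nid(il, jj), nid(il, jj + 1L), "G5", "E", rect_tri(il, jj, "left"))
  add(nid(ir, jj), nid(ir, jj + 1L), "G5", "E",
      rect_tri(ir - 1L, jj, "right"))
  jm <- j1:(j2 - 1L)
  add(nid(il, jm), nid(il, jm + 1L), "G4", "M", NA_integer_)  # end caps
  add(nid(ir, jm), nid(ir, jm + 1L), "G4", "M", NA_integer_)
  ## outer boundary
  add(nid(ii, 1L), nid(ii + 1L, 1L), "G2", "I", rect_tri(ii, 1L, "bottom"))
  add(nid(ii, ny), nid(ii + 1L, ny), "G1", "E",
      rect_tri(ii, ny - 1L, "top"))
  jj <- seq_len(ny - 1L)
  yjm <- (yg[jj] + yg[jj + 1L]) / 2
  lab_side <- ifelse(yjm < lv$y1, "G2", ifelse(yjm < lv$y3, "G3", "GL"))
  side_reg <- ifelse(yjm < lv$y1, "I", ifelse(yjm < lv$y3, "M", "E"))
  add(nid(1L, jj), nid(1L, jj + 1L), lab_side, side_reg,
      rect_tri(rep(1L, ny - 1L), jj, "left"))
  lab_side[lab_side == "GL"] <- "GR"
  add(nid(nx, jj), nid(nx, jj + 1L), lab_side, side_reg,
      rect_tri(rep(nx - 1L, ny - 1L), jj, "right"))
  facets <- do.call(rbind, fac)

  structure(list(
    nodes = nodes, tri = tri, subdomain = subdomain, facets = facets,
    xg = xg, yg = yg, spec = spec, res = res,
    provenance = list(
      n_nodes = nrow(nodes), n_cells = nrow(tri),
      n_membrane_sites = ir - il + 1L,
      preset = res$preset)
  ), class = "tagged_mesh")
}

#' Pair intracellular and extracellular membrane traces
#'
#' Identifies, for every discretization point along the nodal membrane, the
#' matching node on the opposite face, so that the transmembrane voltage
#' `V = phi_I - phi_E` can be evaluated pointwise.  Sites are ordered by the
#' arc position `s` in [0, 1] measured left to right across the node.
#'
#' @param mesh a `tagged_mesh`.
#' @param tol relative tolerance on the transmembrane separation.
#' @return a data.frame with columns `s`, `x`, `node_intra`, `node_extra`.
#' @export
pair_membrane_traces <- function(mesh, tol = 0.1) {
  f <- mesh$facets
  fi <- f[f$label == "G4" & f$side == "I", ]
  fe <- f[f$label == "G4" & f$side == "E", ]
  if (nrow(fi) == 0) stop("pairing error: no intracellular-facing G4 facets")
  if (nrow(fe) == 0) stop("pairing error: no extracellular-facing G4 facets")
  ni <- sort(unique(c(fi$n1, fi$n2)))
  ne <- sort(unique(c(fe$n1, fe$n2)))
  xi <- mesh$nodes[ni, 1]; xe <- mesh$nodes[ne, 1]
  oi <- order(xi); ni <- ni[oi]; xi <- xi[oi]
  oe <- order(xe); ne <- ne[oe]; xe <- xe[oe]
  d <- mesh$spec$membrane_thickness_node
  match_e <- vapply(xi, function(x) which.min(abs(xe - x)), 0L)
  sep <- sqrt((xe[match_e] - xi)^2 +
              (mesh$nodes[ne[match_e], 2] - mesh$nodes[ni, 2])^2)
  bad <- which(sep < (1 - tol) * d | sep > (1 + tol) * d)
  if (length(bad))
    stop(sprintf(
      "pairing error: no opposing facet within tolerance at site x = %.4g m",
      xi[bad[1]]))
  lv <- spec_levels(mesh$spec)
  data.frame(s = (xi - lv$xl) / mesh$spec$node_length, x = xi,
             node_intra = ni, node_extra = ne[match_e])
}

#' Equispaced membrane sample sites
#'
#' Returns `k` sites at arc positions 0, 1/(k-1), ..., 1 along the node of
#' Ranvier, each snapped to the nearest membrane pairing site.
#'
#' @param mesh a `tagged_mesh` (or a pairing data.frame).
#' @param k number of sites, at least 2.
#' @return subset of the pairing table with a column `s_target`.
#' @export
membrane_sample_points <- function(mesh, k = 11) {
  if (!is.numeric(k) || k < 2) stop("k must be at least 2")
  pairing <- if (is.data.frame(mesh)) mesh else pair_membrane_traces(mesh)
  s_target <- seq(0, 1, length.out = k)
  idx <- vapply(s_target, function(s) which.min(abs(pairing$s - s)), 0L)
  out <- pairing[idx, ]
  out$s_target <- s_target
  rownames(out) <- NULL
  out
}

# measured area of a subdomain (sum of triangle areas)
mesh_area <- function(mesh, region) {
  g <- mesh_geom(mesh)
  sum(g$area[mesh$subdomain == region])
}

facet_lengths <- function(mesh, rows) {
  p1 <- mesh$nodes[rows$n1, , drop = FALSE]
  p2 <- mesh$nodes[rows$n2, , drop = FALSE]
  sqrt(rowSums((p2 - p1)^2))
}

#' @export
print.tagged_mesh <- function(x, ...) {
  cat(sprintf("tagged axon mesh ('%s'): %d nodes, %d cells\n",
              x$res$preset, nrow(x$nodes), nrow(x$tri)))
  tab <- table(x$subdomain)
  cat("  cells per subdomain:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  membrane sites along the node: %d\n",
              x$provenance$n_membrane_sites))
  invisible(x)
}

#' @export
plot.tagged_mesh <- function(x, ...) {
  cols <- c(I = "#4477aa55", M = "#cc444488", E = "#44aa7755")
  plot(NA, xlim = range(x$nodes[, 1]), ylim = range(x$nodes[, 2]),
       xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  for (r in names(cols)) {
    cells <- which(x$subdomain == r)
    if (!length(cells)) next
    xs <- t(cbind(matrix(x$nodes[t(x$tri[cells, ]), 1], ncol = 3,
                         byrow = TRUE), NA))
    ys <- t(cbind(matrix(x$nodes[t(x$tri[cells, ]), 2], ncol = 3,
                         byrow = TRUE), NA))
    graphics::polygon(xs, ys, col = cols[[r]], border = NA)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gmsh MSH 2.2 ASCII export/import (subdomain + boundary tags preserved)
# ---------------------------------------------------------------------------

msh_phys <- c(I = 1L, M = 2L, E = 3L, GL = 11L, GR = 12L, G1 = 13L,
              G2 = 14L, G3 = 15L, G4 = 16L, G5 = 17L)
msh_side <- c(I = 1L, M = 2L, E = 3L)

#' Write a tagged mesh in Gmsh MSH 2.2 ASCII format
#'
#' Triangles carry the subdomain as their physical tag; boundary/interface
#' line elements carry the boundary label as physical tag and the bounded
#' region as elementary tag, so tags survive a round trip.
#'
#' @param mesh a `tagged_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements"), con)
  f <- mesh$facets
  n_el <- nrow(f) + nrow(mesh$tri)
  writeLines(as.character(n_el), con)
  side_tag <- ifelse(is.na(f$side), 0L, msh_side[f$side])
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nrow(f)),
                     msh_phys[f$label], side_tag, f$n1, f$n2), con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d",
                     nrow(f) + seq_len(nrow(mesh$tri)),
                     msh_phys[mesh$subdomain], msh_phys[mesh$subdomain],
                     mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh written by [write_msh()]
#'
#' @param path an MSH 2.2 ASCII file.
#' @return a `tagged_mesh` (without generator provenance).
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  ni <- which(lines == "$Nodes")
  nn <- as.integer(lines[ni + 1L])
  nod <- read.table(text = lines[(ni + 2L):(ni + 1L + nn)])
  nodes <- cbind(x = nod$V2, y = nod$V3)
  ei <- which(lines == "$Elements")
  ne <- as.integer(lines[ei + 1L])
  el <- strsplit(lines[(ei + 2L):(ei + 1L + ne)], " ", fixed = TRUE)
  types <- vapply(el, function(z) as.integer(z[2]), 0L)
  inv_phys <- setNames(names(msh_phys), msh_phys)
  lin <- do.call(rbind, lapply(el[types == 1L], as.integer))
  tri <- do.call(rbind, lapply(el[types == 2L], as.integer))
  inv_side <- setNames(names(msh_side), msh_side)
  facets <- data.frame(
    n1 = lin[, 6], n2 = lin[, 7],
    label = unname(inv_phys[as.character(lin[, 4])]),
    side = ifelse(lin[, 5] == 0L, NA_character_,
                  unname(inv_side[as.character(lin[, 5])])),
    cell = NA_integer_)
  mesh <- structure(list(
    nodes = nodes, tri = tri[, 6:8, drop = FALSE],
    subdomain = unname(inv_phys[as.character(tri[, 4])]),
    facets = facets, xg = sort(unique(nodes[, 1])),
    yg = sort(unique(nodes[, 2])), spec = NULL,
    res = list(preset = "imported"),
    provenance = list(n_nodes = nrow(nodes), n_cells = nrow(tri),
                      preset = "imported")
  ), class = "tagged_mesh")
  mesh$facets$cell <- rebuild_facet_cells(mesh)
  mesh
}

# recover, for each facet, the adjacent cell in the region named by `side`
rebuild_facet_cells <- function(mesh) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tr <- mesh$tri
  edges <- rbind(cbind(tr[, 1], tr[, 2]), cbind(tr[, 2], tr[, 3]),
                 cbind(tr[, 3], tr[, 1]))
  ecell <- rep(seq_len(nrow(tr)), 3)
  ereg <- mesh$subdomain[ecell]
  ek <- paste(key(edges[, 1], edges[, 2]), ereg)
  lookup <- split(ecell, ek)
  f <- mesh$facets
  fk <- paste(key(f$n1, f$n2), f$side)
  out <- rep(NA_integer_, nrow(f))
  hit <- fk %in% names(lookup)
  out[hit] <- vapply(lookup[fk[hit]], function(v) v[[1]], 0L)
  out
}
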