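test_that("the domain spec carries the axon dimensions and checks them", {
  spec <- build_domain_spec(default_parameters())
  expect_identical(spec$node_length, 1e-6)
  expect_identical(spec$membrane_thickness_node, 5e-9)
  # frozen ratio of domain to intracellular half-height: 2/0.434
  expect_equal(spec$domain_halfheight / spec$intracellular_halfheight,
               4.608295, tolerance = 1e-6)

  bad <- default_parameters()
  bad$geometry$node_length <- 5e-6
  expect_error(build_domain_spec(bad), "node_length")
  bad <- default_parameters()
  bad$geometry$membrane_thickness_node <- 1e-6
  expect_error(build_domain_spec(bad), "thinner")
})

test_that("subdomains partition the mesh and areas are exact", {
  mesh <- tiny_mesh()
  spec <- mesh$spec
  expect_true(all(mesh$subdomain %in% c("I", "M", "E")))
  aI <- mesh_area(mesh, "I"); aM <- mesh_area(mesh, "M")
  aE <- mesh_area(mesh, "E")
  expect_equal(aI + aM + aE,
               spec$axon_length * spec$domain_halfheight, tolerance = 1e-12)
  # rectangular intracellular interior: area within 1% (exact here)
  expect_equal(aI, spec$axon_length * spec$intracellular_halfheight,
               tolerance = 0.01)
  aM_expected <- (spec$axon_length - spec$node_length) *
    spec$membrane_thickness_myelinated +
    spec$node_length * spec$membrane_thickness_node
  expect_equal(aM, aM_expected, tolerance = 1e-12)
})

test_that("every boundary facet carries exactly one label", {
  mesh <- tiny_mesh()
  f <- mesh$facets
  key <- paste(pmin(f$n1, f$n2), pmax(f$n1, f$n2), f$side)
  expect_false(any(duplicated(key)))
  expect_true(all(f$label %in% c("GL", "GR", "G1", "G2", "G3", "G4", "G5")))
})

test_that("the nodal membrane interface has the expected arc length", {
  mesh <- tiny_mesh()
  g4 <- mesh$facets[mesh$facets$label == "G4", ]
  expect_equal(sum(facet_lengths(mesh, g4)),
               2 * mesh$spec$node_length +
               2 * mesh$spec$membrane_thickness_node, tolerance = 1e-9)
  # flux-carrying faces bound exactly one bulk cell each
  faces <- g4[g4$side %in% c("I", "E"), ]
  expect_true(all(!is.na(faces$cell)))
  expect_true(all(mesh$subdomain[faces$cell] == faces$side))
})

test_that("Debye-band refinement at least doubles when h_debye halves", {
  res1 <- mesh_resolution("test")
  res2 <- res1; res2$h_debye <- res1$h_debye / 2
  spec <- build_domain_spec(default_parameters())
  band_cells <- function(mesh) {
    lv <- pnpaxon:::spec_levels(mesh$spec)
    g <- pnpaxon:::mesh_geom(mesh)
    cy <- (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
           mesh$nodes[mesh$tri[, 3], 2]) / 3
    bw <- mesh$res$debye_band_width
    sum((abs(cy - lv$y1) < bw | abs(cy - lv$y2) < bw) &
        mesh$subdomain != "M")
  }
  m1 <- generate_mesh(spec, res1)
  m2 <- generate_mesh(spec, res2)
  expect_gte(band_cells(m2), 2 * band_cells(m1))
})

test_that("membrane pairing matches opposite faces within tolerance", {
  mesh <- tiny_mesh()
  p <- pair_membrane_traces(mesh)
  expect_true(all(diff(p$s) > 0))
  expect_equal(p$s[1], 0)
  expect_equal(p$s[nrow(p)], 1)
  sep <- abs(mesh$nodes[p$node_extra, 2] - mesh$nodes[p$node_intra, 2])
  d <- mesh$spec$membrane_thickness_node
  expect_true(all(sep >= 0.9 * d & sep <= 1.1 * d))
  # mirror symmetry about the node centre
  expect_equal(p$s, rev(1 - p$s), tolerance = 1e-9)
})

test_that("pairing fails informatively when a face is missing", {
  mesh <- tiny_mesh()
  broken <- mesh
  broken$facets <- mesh$facets[!(mesh$facets$label == "G4" &
                                 mesh$facets$side == "E"), ]
  expect_error(pair_membrane_traces(broken), "pairing error")
})

test_that("membrane_sample_points returns snapped equispaced sites", {
  mesh <- tiny_mesh()
  sp <- membrane_sample_points(mesh, 11)
  expect_identical(sp$s_target, seq(0, 1, by = 0.1))
  expect_true(all(abs(sp$s - sp$s_target) <= 0.5 / mesh$res$node_nx + 1e-9))
  sp2 <- membrane_sample_points(mesh, 2)
  expect_equal(sp2$s, c(0, 1), tolerance = 1e-9)
  sp3 <- membrane_sample_points(mesh, 3)
  expect_equal(sp3$s[2], 0.5, tolerance = 1e-9)  # node centre is a column
  expect_error(membrane_sample_points(mesh, 1), "at least 2")
})

test_that("the mesh survives an MSH round trip with tags intact", {
  mesh <- tiny_mesh()
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(mesh, f)
  m2 <- read_msh(f)
  expect_equal(m2$nodes, mesh$nodes, ignore_attr = TRUE)
  expect_identical(m2$tri[, 1:3], mesh$tri)
  expect_identical(m2$subdomain, mesh$subdomain)
  expect_identical(m2$facets$label, mesh$facets$label)
  expect_identical(m2$facets$side, mesh$facets$side)
  # adjacency is reconstructed, not copied
  ok <- !is.na(mesh$facets$cell)
  expect_identical(mesh$subdomain[m2$facets$cell[ok]],
                   mesh$subdomain[mesh$facets$cell[ok]])
})

test_that("the grid is mirror-symmetric about the node midline", {
  mesh <- tiny_mesh()
  L <- mesh$spec$axon_length
  expect_equal(sort(mesh$xg), sort(L - mesh$xg), tolerance = 1e-12)
})
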