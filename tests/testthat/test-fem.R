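# Discretization checks for the Poisson and Nernst-Planck solvers on small
# strip meshes with known solutions.

neutral_conc <- function(n_nodes) {
  # synthetic electro-neutral composition: 100 Na+, 100 Cl-, traces zeroed
  list(Na = list(E = rep(100, n_nodes)), K = list(E = rep(0, n_nodes)),
       Ca = list(E = rep(0, n_nodes)), Cl = list(E = rep(100, n_nodes)))
}

strip_cfg <- function() {
  cfg <- default_parameters("test")
  cfg$numerics$neutral_background <- FALSE
  cfg$numerics$electrodes <- "blocking"
  cfg
}

test_that("TES boundary value follows the step protocol", {
  tes <- default_parameters()$tes
  expect_identical(tes_boundary_value(1e-3, tes), 0)
  expect_identical(tes_boundary_value(2e-3, tes), 0)   # t = 2 ms inclusive
  expect_identical(tes_boundary_value(2.5e-3, tes), 0.1)
  tes$waveform <- function(t) sin(t)
  expect_identical(tes_boundary_value(0.5, tes), sin(0.5))
})

test_that("electro-neutral concentrations with grounded boundaries give
           phi identically zero", {
  cfg <- strip_cfg()
  mesh <- make_strip_mesh(seq(0, 1e-6, length.out = 9),
                          seq(0, 1e-6, length.out = 9),
                          top = "GR", bottom = "GR",
                          left = "GR", right = "GR")
  phi <- solve_poisson(mesh, neutral_conc(nrow(mesh$nodes)), 0, cfg)
  expect_lt(max(abs(phi)), 1e-15)
})

test_that("a homogeneous strip between the electrodes carries a linear
           potential", {
  cfg <- strip_cfg()
  mesh <- make_strip_mesh(seq(0, 2e-6, length.out = 17),
                          seq(0, 1e-6, length.out = 5),
                          top = "WALL", bottom = "WALL",
                          left = "GL", right = "GR")
  phi <- solve_poisson(mesh, neutral_conc(nrow(mesh$nodes)), 2.5e-3, cfg)
  x <- mesh$nodes[, 1]
  expect_equal(phi, 0.1 * (1 - x / 2e-6), tolerance = 1e-9)
  mid <- abs(x - 1e-6) < 1e-12
  expect_equal(unique(round(phi[mid], 12)), 0.05)
})

test_that("the manufactured solution converges at second order in L2", {
  errs <- poisson_mms_convergence(n0 = 8, levels = 3)
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.3 & ratios < 4.7))
})

test_that("with Table-1 permittivities the membrane carries the dominant
           potential drop", {
  # vertical stack: electrolyte / myelin-thickness membrane / electrolyte,
  # driven across the stack; the drop partitions like a capacitive divider,
  # so the low-permittivity membrane takes nearly all of it
  cfg <- strip_cfg()
  H <- 1e-6
  y_lo <- 0.3e-6; y_hi <- y_lo + 0.406e-6
  mesh <- make_strip_mesh(seq(0, 0.1e-6, length.out = 3),
                          sort(unique(c(seq(0, H, length.out = 41),
                                        y_lo, y_hi))),
                          region = function(x, y)
                            ifelse(y > y_lo & y < y_hi, "M",
                                   ifelse(y <= y_lo, "I", "E")),
                          top = "GR", bottom = "GL",
                          left = "WALL", right = "WALL")
  work <- pnpaxon:::poisson_workspace(mesh, cfg)
  conc <- list(Na = list(I = 0, E = 0), K = list(I = 0, E = 0),
               Ca = list(I = 0, E = 0), Cl = list(I = 0, E = 0))
  conc <- lapply(conc, function(f) list(
    I = rep(0, work$sys$I$ndof), E = rep(0, work$sys$E$ndof)))
  phi <- solve_poisson(mesh, conc, 2.5e-3, cfg, work = work)  # 0.1 V across
  y <- mesh$nodes[, 2]
  drop_memb <- mean(phi[abs(y - y_lo) < 1e-12]) -
               mean(phi[abs(y - y_hi) < 1e-12])
  expect_gt(abs(drop_memb), 0.8 * cfg$tes$amplitude)
})

test_that("a uniform field with zero drift and zero flux is a fixed point", {
  cfg <- strip_cfg()
  mesh <- make_strip_mesh(seq(0, 1e-6, length.out = 9),
                          seq(0, 1e-6, length.out = 9),
                          top = "WALL", bottom = "WALL")
  n0 <- lapply(cfg$ions, function(io)
    list(E = rep(io$n_bulk_extra, nrow(mesh$nodes))))
  phi <- rep(0, nrow(mesh$nodes))
  n1 <- step_nernst_planck(mesh, n0, phi, NULL, 1e-5, 1, cfg)
  for (nm in names(n0))
    expect_equal(n1[[nm]]$E, n0[[nm]]$E, tolerance = 1e-12)
})

test_that("pure diffusion of a Gaussian blob matches the heat kernel", {
  cfg <- strip_cfg()
  L <- 4e-6
  mesh <- make_strip_mesh(seq(0, L, length.out = 61),
                          seq(0, L, length.out = 61),
                          top = "WALL", bottom = "WALL")
  work <- pnpaxon:::poisson_workspace(mesh, cfg)
  x <- mesh$nodes[, 1] - L / 2; y <- mesh$nodes[, 2] - L / 2
  s0 <- 0.3e-6
  blob <- exp(-(x^2 + y^2) / (2 * s0^2))
  n0 <- lapply(cfg$ions, function(io) list(E = 1 + blob))
  phi <- rep(0, nrow(mesh$nodes))
  dt <- 5e-7; nsteps <- 20
  n <- n0
  for (k in seq_len(nsteps))
    n <- step_nernst_planck(mesh, n, phi, NULL, dt, 1, cfg, work)
  D <- cfg$ions$K$D
  s2 <- s0^2 + 2 * D * dt * nsteps
  exact <- 1 + s0^2 / s2 * exp(-(x^2 + y^2) / (2 * s2))
  expect_lt(max(abs(n$K$E - exact)) / (max(exact) - 1), 0.05)
})

test_that("backward Euler stays bounded when the step doubles", {
  cfg <- strip_cfg()
  L <- 4e-6
  mesh <- make_strip_mesh(seq(0, L, length.out = 31),
                          seq(0, L, length.out = 31),
                          top = "WALL", bottom = "WALL")
  x <- mesh$nodes[, 1] - L / 2; y <- mesh$nodes[, 2] - L / 2
  blob <- exp(-(x^2 + y^2) / (2 * (0.3e-6)^2))
  geom <- pnpaxon:::mesh_geom(mesh)
  M <- pnpaxon:::assemble_mass(mesh$tri, geom)
  l2 <- function(v) sqrt(sum(as.numeric(M %*% v) * v))
  run <- function(dt, nsteps) {
    n <- lapply(cfg$ions, function(io) list(E = 1 + blob))
    phi <- rep(0, nrow(mesh$nodes))
    for (k in seq_len(nsteps))
      n <- step_nernst_planck(mesh, n, phi, NULL, dt, 1, cfg)
    n$K$E
  }
  a <- run(5e-7, 16)
  b <- run(1e-6, 8)
  # the L2 norm of the deviation never grows under backward Euler
  expect_lt(l2(b - 1), l2(blob))
  expect_lt(l2(a - 1), l2(blob))
  expect_lt(max(abs(b - 1)), max(blob) * 1.001)
})

test_that("total mass is conserved on a closed domain to solver tolerance", {
  cfg <- strip_cfg()
  mesh <- make_strip_mesh(seq(0, 2e-6, length.out = 21),
                          seq(0, 2e-6, length.out = 21),
                          top = "WALL", bottom = "WALL")
  work <- pnpaxon:::poisson_workspace(mesh, cfg)
  Ml <- work$sys$E$Mlump
  x <- mesh$nodes[, 1]
  phi <- 0.025 * x / 2e-6           # frozen potential ramp drives drift
  n <- lapply(cfg$ions, function(io)
    list(E = io$n_bulk_extra * (1 + 0.3 * sin(pi * x / 2e-6))))
  m0 <- vapply(n, function(f) sum(Ml * f$E), 0)
  for (k in 1:25)
    n <- step_nernst_planck(mesh, n, phi, NULL, 1e-6, 1, cfg, work)
  m1 <- vapply(n, function(f) sum(Ml * f$E), 0)
  expect_equal(m1, m0, tolerance = 1e-12)
})

test_that("with the frozen ramp the steady state is the Boltzmann profile,
           and the divalent exponent is twice the monovalent one", {
  cfg <- strip_cfg()
  H <- 0.2e-6
  mesh <- make_strip_mesh(seq(0, 0.05e-6, length.out = 3),
                          seq(0, H, length.out = 41),
                          top = "WALL", bottom = "WALL")
  y <- mesh$nodes[, 2]
  phi <- 0.025 * y / H                       # ~ kT/e across the strip
  conc <- relax_frozen_potential(mesh, phi, cfg, dt = 2e-6, nsteps = 400)
  work <- attr(conc, "work")
  Ml <- work$sys$E$Mlump
  dev_Na <- boltzmann_check(phi, cfg$ions$Na$alpha, conc$Na$E, Ml)
  dev_Ca <- boltzmann_check(phi, cfg$ions$Ca$alpha, conc$Ca$E, Ml)
  dev_Cl <- boltzmann_check(phi, cfg$ions$Cl$alpha, conc$Cl$E, Ml)
  expect_lt(dev_Na, 0.01)
  expect_lt(dev_Ca, 0.01)
  expect_lt(dev_Cl, 0.01)
  # log-slope ratio Ca vs Na equals the valence ratio
  slope <- function(v) coef(lm(log(v) ~ y))[[2]]
  expect_equal(slope(conc$Ca$E) / slope(conc$Na$E), 2, tolerance = 0.02)
})
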