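# Driver behaviour on the minimal mesh; the full coarse protocol is
# exercised by the acceptance suite.

test_that("initialization sets the prescribed uniform concentrations", {
  cfg <- tiny_cfg()
  cfg$numerics$init_double_layers <- FALSE
  mesh <- tiny_mesh()
  st <- initialize_state(cfg, mesh)
  expect_true(all(st$conc$Ca$I == 1e-4))
  expect_true(all(st$conc$K$E == 4))
  expect_true(all(st$conc$Na$I == 12))
  expect_true(all(st$conc$Cl$E == 123.27))
})

test_that("the default initializer perturbs only the membrane layers", {
  run <- tiny_run()
  mesh <- run$mesh
  ck0 <- run$checkpoints[[1]]
  lv <- pnpaxon:::spec_levels(mesh$spec)
  geomE <- pnpaxon:::region_system(mesh, "E")
  far <- abs(mesh$nodes[geomE$gnodes, 2] - lv$y3) > 0.1e-6 &
         mesh$nodes[geomE$gnodes, 2] > lv$y3
  expect_equal(median(ck0$conc$K$E[far]), 4, tolerance = 1e-3)
  geomI <- pnpaxon:::region_system(mesh, "I")
  farI <- mesh$nodes[geomI$gnodes, 2] < lv$y1 - 0.1e-6
  expect_equal(median(ck0$conc$Ca$I[farI]), 1e-4, tolerance = 1e-2)
})

test_that("gating starts at the fixed point of the rate equations", {
  run <- tiny_run()
  reg <- gating_registry(run$config)
  r <- gating_rates(run$V[1, ], reg)
  expect_lt(max(abs(r$alpha_m * (1 - run$m[1, ]) - r$beta_m * run$m[1, ])),
            1e-9)
  expect_lt(max(abs(r$alpha_n * (1 - run$n[1, ]) - r$beta_n * run$n[1, ])),
            1e-9)
})

test_that("the run executes t_end/dt_outer outer steps and is recorded at
           every step", {
  run <- tiny_run()
  nsteps <- round(run$config$stepping$t_end / run$config$stepping$dt_outer)
  expect_identical(length(run$times), as.integer(nsteps) + 1L)
  expect_equal(max(run$times), run$config$stepping$t_end * 1e-3)
  expect_equal(diff(run$times)[1], run$config$stepping$dt_outer * 1e-3)
  expect_false(anyNA(run$V))
})

test_that("the stimulation boundary switches exactly across t_tes_on", {
  run <- tiny_run()
  mesh <- run$mesh
  f <- mesh$facets
  gl <- unique(c(f$n1[f$label == "GL"], f$n2[f$label == "GL"]))
  ts <- vapply(run$checkpoints, `[[`, 0, "t")
  t_on <- run$config$stepping$t_tes_on * 1e-3
  pre <- which(ts <= t_on * 1.01)    # activation time itself is pre-stimulus
  post <- which(ts > t_on * 1.01)
  expect_lt(max(abs(run$checkpoints[[max(pre)]]$phi[gl])), 1e-12)
  expect_equal(unique(round(run$checkpoints[[min(post)]]$phi[gl], 12)),
               run$config$tes$amplitude)
})

test_that("two runs with identical inputs are bit-identical", {
  cfg <- tiny_cfg()
  cfg$stepping$t_end <- 0.3
  cfg$stepping$t_tes_on <- 0.1
  cfg$numerics$init_relax_steps <- 30
  mesh <- tiny_mesh()
  r1 <- simulate_tes(cfg, mesh)
  r2 <- simulate_tes(cfg, mesh)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$flux, r2$flux)
  expect_identical(r1$checkpoints[[length(r1$checkpoints)]]$conc,
                   r2$checkpoints[[length(r2$checkpoints)]]$conc)
})

test_that("without stimulation the state stays at rest", {
  cfg <- tiny_cfg()
  cfg$stepping$t_end <- 1
  cfg$stepping$t_tes_on <- 1   # stimulus never activates within the run
  run <- simulate_tes(cfg, tiny_mesh())
  drift <- abs(sweep(run$V, 2, run$V[1, ]))
  expect_lt(max(drift / abs(run$V[1, ])), 0.01)
})

test_that("intracellular mass changes only through the membrane flux", {
  run <- tiny_run()
  d <- as.data.frame(run$diagnostics)
  dt <- run$config$stepping$dt_outer * 1e-3
  p <- run$pairing
  dx <- diff(p$x)
  for (ion in c("Na", "Ca")) {
    mass <- d[[paste0("mass_", ion, "_I")]]
    fl <- run$flux[[ion]]
    # trapezoid of site flux along the node, forward in time
    line_int <- as.numeric((fl[, -1, drop = FALSE] +
                            fl[, -ncol(fl), drop = FALSE]) %*% dx / 2)
    expected <- -dt * line_int[-1]   # step k -> k+1 uses the new flux
    expect_lt(max(abs(diff(mass) - expected)) / max(abs(expected)), 1e-6)
  }
})
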