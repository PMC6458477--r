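reg <- gating_registry(default_parameters())

test_that("transition rates are positive and continuous at the removable
           singularities", {
  V <- seq(-150, 100, by = 0.5)
  r <- gating_rates(V, reg)
  for (nm in names(r)) expect_true(all(r[[nm]] >= 0), info = nm)
  # alpha_m's 0/0 point sits at v = 25 (V = -40 with the default shift)
  expect_equal(reg$alpha_m(-40), 1, tolerance = 1e-6)
  expect_equal(reg$alpha_m(-40), reg$alpha_m(-40 + 1e-5), tolerance = 1e-4)
  # alpha_n's singular point at v = 10 (V = -55)
  expect_equal(reg$alpha_n(-55), 0.1, tolerance = 1e-6)
  expect_equal(reg$alpha_n(-55), reg$alpha_n(-55 - 1e-5), tolerance = 1e-4)
})

test_that("rates close the sodium channel at strongly hyperpolarized V", {
  expect_lt(reg$alpha_m(-150), 1e-2)
  expect_gt(reg$beta_m(-150), 50)
})

test_that("steady-state gating lies in (0,1) and matches the rate ratio", {
  for (V in c(-120, -70.23, -40, 0, 40)) {
    g <- steady_state_gating(V, reg)
    r <- gating_rates(V, reg)
    expect_true(all(unlist(g) > 0 & unlist(g) < 1))
    expect_equal(g$m, r$alpha_m / (r$alpha_m + r$beta_m))
  }
})

test_that("Nernst potentials match the closed-form evaluation", {
  cfg <- default_parameters()
  ci <- vapply(cfg$ions, function(i) i$n_init_intra, 0)
  ce <- vapply(cfg$ions, function(i) i$n_bulk_extra, 0)
  E <- reversal_potentials(ci, ce, cfg$constants)
  # frozen values computed independently from (1000*R*T/(z*F))*log(out/in)
  expect_equal(E[["Na"]], 60.0068, tolerance = 1e-6)
  expect_equal(E[["K"]], -88.06899, tolerance = 1e-6)
  expect_equal(E[["Ca"]], 110.8992, tolerance = 1e-6)
  expect_equal(E[["Cl"]], 7.282672, tolerance = 1e-6)
  # equal concentrations on both sides: zero driving force
  expect_equal(unname(reversal_potentials(c(Na = 3), c(Na = 3),
                                          cfg$constants)), 0)
  expect_error(reversal_potentials(c(Na = 0), c(Na = 1), cfg$constants),
               "positive")
})

test_that("membrane flux vanishes at the reversal potential and has the
           resting sign pattern", {
  cfg <- default_parameters()
  ci <- vapply(cfg$ions, function(i) i$n_init_intra, 0)
  ce <- vapply(cfg$ions, function(i) i$n_bulk_extra, 0)
  E <- reversal_potentials(ci, ce, cfg$constants)
  g <- steady_state_gating(-70.23, reg)
  for (nm in names(E)) {
    fx <- membrane_flux(g, E[[nm]], ci, ce, cfg$constants, reg)
    expect_equal(unname(fx[1, nm]), 0, tolerance = 1e-18)
  }
  # at rest: Na and Ca flow in (negative), K flows out (positive)
  fx <- membrane_flux(g, -70.23, ci, ce, cfg$constants, reg)
  expect_lt(fx[1, "Na"], 0)
  expect_lt(fx[1, "Ca"], 0)
  expect_gt(fx[1, "K"], 0)
})

test_that("flux magnitudes are coherent with the gates", {
  cfg <- default_parameters()
  ci <- vapply(cfg$ions, function(i) i$n_init_intra, 0)
  ce <- vapply(cfg$ions, function(i) i$n_bulk_extra, 0)
  V <- -55  # depolarized
  g <- steady_state_gating(V, reg)
  f1 <- membrane_flux(g, V, ci, ce, cfg$constants, reg)
  g2 <- g; g2$m <- 2 * g$m
  f2 <- membrane_flux(g2, V, ci, ce, cfg$constants, reg)
  expect_gt(abs(f2[1, "Ca"]), abs(f1[1, "Ca"]))   # Ca influx grows with m
  expect_gt(abs(f2[1, "Na"]), abs(f1[1, "Na"]))   # Na influx grows with m
  g3 <- g; g3$h <- min(1, 1.5 * g$h)              # less inactivation
  f3 <- membrane_flux(g3, V, ci, ce, cfg$constants, reg)
  expect_gt(abs(f3[1, "Na"]), abs(f1[1, "Na"]))
  g4 <- g; g4$n <- min(1, 1.5 * g$n)
  f4 <- membrane_flux(g4, V, ci, ce, cfg$constants, reg)
  expect_gt(f4[1, "K"], f1[1, "K"])               # K efflux grows with n
})

test_that("batch flux evaluation equals site-by-site evaluation", {
  cfg <- default_parameters()
  set.seed(7)
  ns <- 6
  Vv <- runif(ns, -90, -40)
  g <- list(m = runif(ns), n = runif(ns), h = runif(ns))
  ci <- matrix(rep(vapply(cfg$ions, function(i) i$n_init_intra, 0),
                   each = ns), ns, dimnames = list(NULL, names(cfg$ions)))
  ce <- matrix(rep(vapply(cfg$ions, function(i) i$n_bulk_extra, 0),
                   each = ns), ns, dimnames = list(NULL, names(cfg$ions)))
  batch <- membrane_flux(g, Vv, ci, ce, cfg$constants, reg)
  for (j in seq_len(ns)) {
    single <- membrane_flux(list(m = g$m[j], n = g$n[j], h = g$h[j]), Vv[j],
                            ci[j, , drop = FALSE], ce[j, , drop = FALSE],
                            cfg$constants, reg)
    expect_identical(unname(batch[j, ]), unname(single[1, ]))
  }
})

test_that("advance_gating reproduces the closed-form relaxation", {
  V <- -50
  r <- gating_rates(V, reg)
  g0 <- list(m = 0.1, n = 0.6, h = 0.4)
  dt <- 0.25
  g1 <- advance_gating(g0, V, dt, 0.0005, reg, rtol = 1e-10, atol = 1e-12)
  exact <- list(
    m = gate_relaxation_exact(g0$m, r$alpha_m, r$beta_m, dt),
    n = gate_relaxation_exact(g0$n, r$alpha_n, r$beta_n, dt),
    h = gate_relaxation_exact(g0$h, r$alpha_h, r$beta_h, dt))
  for (nm in c("m", "n", "h"))
    expect_equal(g1[[nm]], exact[[nm]], tolerance = 1e-8)
})

test_that("the resting steady state is a fixed point of advance_gating", {
  V <- -70.23
  g0 <- steady_state_gating(V, reg)
  g1 <- advance_gating(g0, V, 1, 0.0005, reg)
  for (nm in c("m", "n", "h"))
    expect_equal(g1[[nm]], g0[[nm]], tolerance = 1e-9)
})

test_that("halving the inner step cap leaves the result within integrator
           tolerance", {
  g0 <- list(m = 0.2, n = 0.3, h = 0.7)
  a <- advance_gating(g0, -45, 0.01, 0.0005, reg)
  b <- advance_gating(g0, -45, 0.01, 0.00025, reg)
  for (nm in c("m", "n", "h")) expect_equal(a[[nm]], b[[nm]],
                                            tolerance = 1e-7)
})

test_that("gates remain in [0,1] for arbitrary voltage traces", {
  set.seed(42)
  for (rep in 1:12) {
    g <- list(m = runif(1), n = runif(1), h = runif(1))
    Vs <- runif(8, -140, 90)
    for (V in Vs) {
      g <- advance_gating(g, V, 0.05, 0.0005, reg)
      expect_true(all(unlist(g) >= 0 & unlist(g) <= 1))
    }
  }
})

test_that("m equilibrates faster than n and h after a step depolarization", {
  V0 <- -70.23; V1 <- -50
  g0 <- steady_state_gating(V0, reg)
  ginf <- steady_state_gating(V1, reg)
  frac_done <- function(g, nm) abs(g[[nm]] - g0[[nm]]) /
    abs(ginf[[nm]] - g0[[nm]])
  t99 <- sapply(c("m", "n", "h"), function(nm) {
    g <- g0; t <- 0
    while (frac_done(g, nm) < 0.99 && t < 100) {
      g <- advance_gating(g, V1, 0.05, 0.0005, reg)
      t <- t + 0.05
    }
    t
  })
  expect_lt(t99[["m"]], t99[["n"]])
  expect_lt(t99[["m"]], t99[["h"]])
})

test_that("relaxation from a perturbed state converges to the steady state", {
  V <- -70.23
  ginf <- steady_state_gating(V, reg)
  g <- list(m = 0.5, n = 0.9, h = 0.1)
  for (k in 1:150) g <- advance_gating(g, V, 1, 0.0005, reg)  # 150 ms >> tau
  for (nm in c("m", "n", "h"))
    expect_equal(g[[nm]], ginf[[nm]], tolerance = 1e-6)
})
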