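test_that("single-reaction equilibrium extent matches the bisection oracle", {
  # frozen from the oracle: z with z^2/((5-z)(2-z)) = 0.18
  eq <- phosphorolysis_equilibrium(K = 0.18, nucleoside0 = 5, phosphate0 = 2)
  expect_equal(eq$z, 0.9006578, tolerance = 1e-6)
  expect_equal(eq$z^2 / ((5 - eq$z) * (2 - eq$z)), 0.18, tolerance = 1e-10)

  set.seed(11)
  for (i in 1:50) {
    K <- runif(1, 0.01, 2)
    n0 <- runif(1, 0.1, 50); p0 <- runif(1, 0.1, 50)
    b0 <- runif(1, 0, 5); pp0 <- runif(1, 0, 5)
    eq <- phosphorolysis_equilibrium(K, n0, p0, b0, pp0)
    expect_equal(eq$z, oracle_single_extent(K, n0, p0, b0, pp0),
                 tolerance = 1e-8)
    expect_true(all(unlist(eq[-1]) >= -1e-12))
  }
})

test_that("single-reaction limits behave: no phosphate and very large K", {
  expect_equal(phosphorolysis_equilibrium(0.18, 5, 0)$z, 0)
  expect_equal(phosphorolysis_equilibrium(1e12, 5, 2)$z, 2, tolerance = 1e-4)
  expect_equal(phosphorolysis_equilibrium(1e12, 2, 5)$z, 2, tolerance = 1e-4)
})

test_that("coupled solver reproduces the analytical-condition conversion", {
  sys <- transglycosylation_system(0.18, 0.081, donor0 = 5, base0 = 5,
                                   phosphate0 = 2)
  st <- solve_transglycosylation_equilibrium(sys)
  conv <- yield_from_state(st, 5)
  # frozen after confirmation by the independent grid oracle
  oracle <- oracle_coupled_equilibrium(0.18, 0.081, 5, 5, 2)
  expect_equal(st[["N2"]], oracle[["x"]], tolerance = 1e-7)
  expect_equal(conv, 0.5783461, tolerance = 1e-6)
  expect_gt(conv, 0.55)   # printed band of the analytical reactions
  expect_lt(conv, 0.60)
})

test_that("coupled solver agrees with the 2-D grid oracle on random systems", {
  set.seed(101)
  for (i in 1:100) {
    sys <- random_system()
    st <- solve_transglycosylation_equilibrium(sys)
    oracle <- oracle_coupled_equilibrium(sys$K_donor, sys$K_product,
                                         sys$donor0, sys$base0,
                                         sys$phosphate0)
    expect_lt(abs(st[["N2"]] - oracle[["x"]]), 1e-6)
    expect_lt(abs(st[["P1P"]] - oracle[["y"]]), 1e-6)
  }
})

test_that("every equilibrium state satisfies conservation and mass action", {
  set.seed(202)
  for (i in 1:100) {
    sys <- random_system()
    st <- solve_transglycosylation_equilibrium(sys)
    expect_true(all(st >= 0))
    expect_lt(max(abs(conservation_deviations(st, sys))), 1e-9)
    scale <- max(sys$K_donor, 1) * max(sys$donor0, sys$base0,
                                       sys$phosphate0)^2
    expect_lt(max(abs(mass_action_residuals(st, sys))), 1e-9 * scale)
  }
})

test_that("degenerate compositions solve trivially", {
  sys0 <- transglycosylation_system(0.18, 0.081, 5, 5, 0)
  st0 <- solve_transglycosylation_equilibrium(sys0)
  expect_equal(st0[["N2"]], 0)
  expect_equal(st0[["P1P"]], 0)
  expect_equal(st0[["N1"]], 5)

  # base0 -> 0 degenerates to the single-reaction closed form
  eq <- phosphorolysis_equilibrium(0.18, 5, 2)
  sysb <- transglycosylation_system(0.18, 0.081, 5, 0, 2)
  stb <- solve_transglycosylation_equilibrium(sysb)
  expect_equal(stb[["P1P"]], eq$z, tolerance = 1e-9)
  expect_equal(stb[["N1"]], eq$nucleoside, tolerance = 1e-9)
  expect_equal(stb[["N2"]], 0)
})

test_that("symmetric system at vanishing phosphate converges to 50% yield", {
  for (p0 in c(0.1, 0.01, 0.001)) {
    sys <- transglycosylation_system(0.15, 0.15, donor0 = 5, base0 = 5,
                                     phosphate0 = p0)
    conv <- yield_from_state(solve_transglycosylation_equilibrium(sys), 5)
    expect_equal(conv, 0.5, tolerance = 5 * p0)
  }
  sys <- transglycosylation_system(0.15, 0.15, 5, 5, 1e-6)
  expect_equal(yield_from_state(solve_transglycosylation_equilibrium(sys), 5),
               0.5, tolerance = 1e-5)
})

test_that("equilibrium yield is monotone in phosphate and donor loading", {
  yields_p <- vapply(seq(0.2, 5, length.out = 12), function(p0) {
    sys <- transglycosylation_system(0.18, 0.081, 25, 5, p0)
    yield_from_state(solve_transglycosylation_equilibrium(sys), 5)
  }, numeric(1))
  expect_true(all(diff(yields_p) <= 1e-12))

  yields_d <- vapply(seq(5, 50, length.out = 12), function(d0) {
    sys <- transglycosylation_system(0.18, 0.081, d0, 5, 0.5)
    yield_from_state(solve_transglycosylation_equilibrium(sys), 5)
  }, numeric(1))
  expect_true(all(diff(yields_d) >= -1e-12))
})

test_that("state constructor enforces conservation and non-negativity", {
  sys <- transglycosylation_system(0.18, 0.081, 5, 5, 2)
  expect_error(species_state(-1, 6, 0, 5, 2, 0, system = sys), "negative")
  expect_error(species_state(4, 1, 2, 3, 2, 0, system = sys),
               "conservation")
  expect_error(yield_from_state(
    solve_transglycosylation_equilibrium(sys), 0), "positive")
})

test_that("system constructor validates its inputs", {
  expect_error(transglycosylation_system(-0.1, 0.08, 5, 5, 2), "K_donor")
  expect_error(transglycosylation_system(0.18, 0, 5, 5, 2), "K_product")
  expect_error(transglycosylation_system(0.18, 0.08, -5, 5, 2), "donor0")
})

test_that("scenario YAML round-trips through the solver to CSV", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scenarios:",
    "  - donor_id: 1a",
    "    product_id: 3a",
    "    K_donor: 0.18",
    "    K_product: 0.081",
    "    donor0: 5",
    "    base0: 5",
    "    phosphate0: 2"), cfg)
  systems <- read_scenarios(cfg)
  expect_length(systems, 1)
  out <- tempfile(fileext = ".csv")
  res <- write_equilibrium_csv(systems, out)
  back <- read.csv(out)
  expect_equal(back$yield, res$yield, tolerance = 1e-9)
  expect_equal(res$yield, 0.5783461, tolerance = 1e-6)
})
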