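test_that("zero release keeps the whole system at zero", {
  g <- closed_object_landscape()
  lib <- make_decay_library(c(100, 10))
  sc <- release_scenario("N1", "constant", rate = 0)
  r <- simulate_transport(g, lib, sc, c(0, 100), max_step = 10)
  expect_true(all(r$inventories == 0))
  expect_true(all(r$decayed == 0))
})

test_that("single-compartment constant release follows (S/k)(1 - exp(-kt))", {
  g <- closed_object_landscape()
  lam <- decay_constant(50)
  lib <- make_decay_library(50)
  sc <- release_scenario("N1", "constant", rate = 1)
  r <- simulate_transport(g, lib, sc, c(0, 400), max_step = 10)
  a <- state_series(r, "N1", "obj1", "REGOLITH_LOW")
  expected <- (1 / lam) * (1 - exp(-lam * (r$times - r$times[1])))
  expect_equal(a, expected, tolerance = 1e-9)
})

test_that("bateman solution matches closed forms and a matrix-exponential oracle", {
  # one member: pure exponential decay
  t <- seq(0, 100, by = 5)
  expect_equal(as.numeric(bateman_solution(0.01, 2, t)), 2 * exp(-0.01 * t))
  # secular equilibrium: short-lived daughter activity approaches parent's
  lam <- c(1e-4, 10)
  A <- bateman_solution(lam, c(1, 0), c(5, 50))
  expect_equal(A[2, 2] / A[2, 1], 1, tolerance = 1e-3)
  # two-member chain against the matrix exponential of the decay matrix
  lam <- c(0.02, 0.005)
  M <- matrix(c(-lam[1], lam[2], 0, -lam[2]), 2, 2)  # activity-unit coupling
  for (tt in c(1, 10, 100, 500)) {
    direct <- as.numeric(Matrix::expm(M * tt) %*% c(1, 0))
    expect_equal(as.numeric(bateman_solution(lam, c(1, 0), tt)), direct,
                 tolerance = 1e-10)
  }
})

test_that("steady state solves K A = -S and flags trap compartments", {
  K <- matrix(-0.1, 1, 1)
  expect_equal(as.numeric(steady_state(K, 1)), 10)
  expect_equal(as.numeric(steady_state(K, 0)), 0)
  Kbad <- matrix(c(-1, 1, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(steady_state(Kbad, c(1, 0)), "no loss path.*b")
})

test_that("long integration of a frozen system converges to the direct steady state", {
  lib <- reference_nuclides()
  g <- generate_landscape(1, seed = 9)
  t_frozen <- 6000
  sys <- assemble_system_matrix(g, lib, "Ra226syn", t_frozen)
  S <- numeric(length(sys$state_names))
  S[match("Ra226syn|obj1.REGOLITH_LOW", sys$state_names)] <- 1
  A_direct <- steady_state(sys$K, S)
  sc <- release_scenario("Ra226syn", "constant", rate = 1)
  r <- simulate_transport(g, lib, sc, c(0, 2e5), max_step = 5000,
                          fine_window = 0, freeze_at = t_frozen)
  A_long <- r$inventories[nrow(r$inventories), ]
  keep <- A_direct > 1e-10 * sum(A_direct)
  expect_equal(unname(A_long[keep]), unname(A_direct[keep]), tolerance = 1e-3)
})

test_that("solution is exactly linear in the release rate", {
  fx <- small_fixture()
  sc1 <- release_scenario("Ra226syn", "constant", rate = 1)
  sc2 <- release_scenario("Ra226syn", "constant", rate = 2)
  r1 <- simulate_transport(fx$graph, fx$library, sc1, c(-9000, -8000),
                           max_step = 100)
  r2 <- simulate_transport(fx$graph, fx$library, sc2, c(-9000, -8000),
                           max_step = 100)
  expect_equal(2 * r1$inventories, r2$inventories, tolerance = 1e-12)
})

test_that("a delayed pulse reproduces the shifted response of an early pulse", {
  # time-invariance + superposition on a frozen system
  fx <- small_fixture()
  shift <- 300
  sc0 <- release_scenario("I129syn", "pulse", amount = 1, duration = 1, start = 0)
  sc1 <- release_scenario("I129syn", "pulse", amount = 1, duration = 1, start = shift)
  grid <- seq(0, 1000, by = 50)
  r0 <- simulate_transport(fx$graph, fx$library, sc0, c(0, 1000), max_step = 50,
                           freeze_at = 5000, output_grid = grid)
  r1 <- simulate_transport(fx$graph, fx$library, sc1, c(0, 1300), max_step = 50,
                           freeze_at = 5000, output_grid = grid + shift)
  i0 <- match(grid, r0$times)
  i1 <- match(grid + shift, r1$times)
  expect_equal(r1$inventories[i1, ], r0$inventories[i0, ], tolerance = 1e-8)
})

test_that("assembled matrices stay Metzler and inventories non-negative across random configurations", {
  lib <- reference_nuclides()
  set.seed(99)
  for (i in 1:20) {
    g <- generate_landscape(sample(1:3, 1), seed = sample.int(1e6, 1),
                            area_total = 10^runif(1, 4.5, 6))
    for (t in runif(10, -9000, 9400)) {
      sys <- assemble_system_matrix(g, lib, "Ra226syn", t)
      off <- sys$K; diag(off) <- 0
      expect_true(all(off >= 0))
      expect_true(all(diag(sys$K) <= 0))
    }
  }
  # short simulations preserve non-negativity
  for (seed in 1:5) {
    g <- generate_landscape(1, seed = seed)
    sc <- release_scenario("Ra226syn", "constant", rate = 1)
    r <- simulate_transport(g, lib, sc, c(-7000, -6000), max_step = 100)
    expect_true(all(r$inventories >= 0))
  }
})

test_that("mass balance holds for a closed decaying system", {
  g <- closed_object_landscape()
  lib <- make_decay_library(30)
  sc <- release_scenario("N1", "pulse", amount = 1, duration = 1)
  r <- simulate_transport(g, lib, sc, c(0, 600), max_step = 20)
  expect_lt(mass_balance_audit(r), 1e-9)
  # essentially everything has decayed after 20 half-lives
  expect_equal(unname(r$decayed[nrow(r$decayed), 1]), 1, tolerance = 1e-5)
})
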