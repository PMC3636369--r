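test_that("sampling is reproducible, prefix-stable and passes constants through", {
  dists <- list(
    param_dist("a", "constant", best_estimate = 3),
    param_dist("b", "uniform", best_estimate = 5, min = 0, max = 10),
    param_dist("c", "loguniform", best_estimate = 1, min = 0.01, max = 100))
  s1 <- sample_parameters(dists, 20, seed = 123)
  s2 <- sample_parameters(dists, 20, seed = 123)
  expect_identical(s1, s2)
  expect_true(all(s1$a == 3))
  expect_true(all(s1$b >= 0 & s1$b <= 10))
  expect_true(all(s1$c >= 0.01 & s1$c <= 100))
  # extending n keeps the first draws (per-parameter streams)
  s3 <- sample_parameters(dists, 40, seed = 123)
  expect_equal(s3[1:20, ], s1)
  # different seed differs
  expect_false(identical(sample_parameters(dists, 20, seed = 124), s1))
})

test_that("lognormal sample mean matches exp(mu + sigma^2/2)", {
  d <- list(param_dist("x", "lognormal", best_estimate = 1, meanlog = 0, sdlog = 0.5))
  s <- sample_parameters(d, 10000, seed = 42)
  mu_true <- exp(0 + 0.5^2 / 2)
  se <- sqrt((exp(0.5^2) - 1) * exp(0.5^2)) / sqrt(10000)
  expect_lt(abs(mean(s$x) - mu_true), 3 * se)
})

test_that("best estimates outside the support are rejected", {
  expect_error(param_dist("x", "uniform", best_estimate = 20, min = 0, max = 10),
               "outside the support")
})

test_that("latin hypercube sampling stratifies every parameter", {
  dists <- list(param_dist("u", "uniform", best_estimate = 0.5, min = 0, max = 1))
  s <- sample_parameters(dists, 10, seed = 1, method = "lhs")
  # exactly one draw per decile
  expect_equal(sort(floor(s$u * 10)), 0:9)
})

test_that("parameter paths address scalars inside the configuration", {
  fx <- small_fixture()
  cfg <- list(graph = fx$graph, library = fx$library, habits = exposure_habits())
  cfg2 <- apply_parameter_values(cfg, c("library/Ra226syn/element/kd/regolith_low" = 9.9,
                                        "habits/water_intake" = 0.7))
  expect_equal(cfg2$library$Ra226syn$element$kd$regolith_low, 9.9)
  expect_equal(cfg2$habits$water_intake, 0.7)
  expect_error(apply_parameter_values(cfg, c("library/nope/half_life" = 1)),
               "not found")
  expect_error(apply_parameter_values(cfg, c("graph/objects/obj1/compartments" = 1)),
               "not a scalar")
})

test_that("rank sensitivity identifies monotone drivers and flags inert or constant inputs", {
  set.seed(7)
  n <- 1000
  samples <- data.frame(driver = runif(n, 1, 2), inert = runif(n),
                        fixed = rep(5, n))
  ldf <- exp(samples$driver)  # strictly increasing in the driver only
  sens <- rank_sensitivity(samples, ldf)
  expect_equal(sens$parameter[1], "driver")
  expect_equal(sens$rho[sens$parameter == "driver"], 1)
  expect_lt(abs(sens$rho[sens$parameter == "inert"]), 0.1)
  expect_true(sens$constant[sens$parameter == "fixed"])
  expect_equal(sens$rho[sens$parameter == "fixed"], 0)
})

test_that("zero-variance distributions collapse the Monte Carlo to the baseline", {
  fx <- small_fixture()
  dists <- list(
    param_dist("library/Ra226syn/element/kd/regolith_low", "constant", best_estimate = 2),
    param_dist("habits/water_intake", "constant", best_estimate = 0.6))
  mc <- run_probabilistic(fx$graph, fx$library, "Ra226syn", dists, n = 3, seed = 5,
                          max_step = coarse$max_step, fine_step = coarse$fine_step,
                          fine_window = coarse$fine_window)
  expect_equal(mc$samples$ldf, rep(mc$baseline$ldf, 3), tolerance = 1e-12)
  expect_equal(unname(mc$summary["n_failed"]), 0)
})

test_that("a parameter multiplying dose monotonically attains rank correlation 1", {
  fx <- small_fixture()
  dists <- list(
    param_dist("library/I129syn/dose_coeff/ingestion", "loguniform",
               best_estimate = 1.1e-7, min = 1e-8, max = 1e-6))
  mc <- run_probabilistic(fx$graph, fx$library, "I129syn", dists, n = 8, seed = 11,
                          max_step = coarse$max_step, fine_step = coarse$fine_step,
                          fine_window = coarse$fine_window)
  sens <- rank_sensitivity(mc)
  expect_equal(sens$rho[1], 1)
})
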