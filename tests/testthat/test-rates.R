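test_that("dissolved fraction partitions pore water and solids", {
  expect_equal(dissolved_fraction(0, 1000, 500), 1.0)
  expect_equal(dissolved_fraction(1, 1000, 1000), 0.5)
  expect_equal(dissolved_fraction(0.2, 1000, 100), 1 / 3)
  expect_error(dissolved_fraction(0, 0, 0), "zero")
})

test_that("dissolved and sorbed fractions are exact complements", {
  set.seed(1)
  for (i in 1:50) {
    kd <- 10^runif(1, -4, 1); m <- 10^runif(1, 0, 9); v <- 10^runif(1, 0, 6)
    f <- dissolved_fraction(kd, m, v)
    sorbed <- kd * m / (v + kd * m)
    expect_equal(f + sorbed, 1)
  }
})

test_that("advective rate moves the dissolved share and is retarded by sorption", {
  expect_equal(advective_rate(100, 1000, 0, 0), 0.1)
  expect_equal(advective_rate(100, 1000, 1, 1000), 0.05)
  expect_equal(advective_rate(0, 1000), 0)
  expect_error(advective_rate(-1, 1000), ">= 0")
  # strictly decreasing in kd at fixed flux and geometry
  kds <- sort(10^runif(20, -4, 1))
  rates <- vapply(kds, function(k) advective_rate(100, 1000, k, 1e4), numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("diffusive exchange is symmetric on pore-water concentration", {
  expect_equal(diffusive_rates(0, 10, 1, 100, 200), c(0, 0))
  r <- diffusive_rates(1, 50, 0.5, 300, 300)
  expect_equal(r[1], r[2])
  expect_equal(diffusive_rates(1, 10, 1, 100, 200), c(0.1, 0.05))
  expect_error(diffusive_rates(1, 10, 0, 100, 200), "length")
})

test_that("particle rates move only the sorbed phase", {
  # nothing sorbed to particles -> no sedimentation transfer
  expect_equal(particle_rates(1, 0, 100, 1e4, 10, 0, 1e5, 10, 1)[["k_sed"]], 0)
  expect_equal(particle_rates(1, 0, 100, 1e4, 10, 1, 1e5, 10, 1)[["k_res"]], 0)
  r <- particle_rates(1, 0, 100, 1e4, 10, 1, 1e5, 10, 1)
  expect_equal(r[["k_sed"]], 100 / (1e4 + 10), tolerance = 1e-12)
  expect_error(particle_rates(0, 1, 100, 1e4, 10, 1, 0, 10, 1), "no solid mass")
})

test_that("biota rates reflect production-driven uptake and turnover", {
  expect_equal(biota_rates(0, 5, 1, 100), c(k_uptake = 0, k_return = 0))
  r <- biota_rates(10, 5, 0, 100)
  expect_equal(r[["k_uptake"]], 0)
  expect_equal(r[["k_return"]], 2)
  expect_error(biota_rates(10, 5, -1, 100), "negative CR")
  expect_error(biota_rates(10, 0, 1, 100), "biomass")
})

test_that("gas rates pass through degassing and ventilation", {
  expect_equal(gas_rates(0, 1e3), c(k_degas = 0, k_vent = 1e3))
  expect_error(gas_rates(-1, 0), ">= 0")
})

test_that("wetland growth rate tracks aquatic-area shrinkage", {
  expect_equal(wetland_growth_rate(1e5, 0), 0)
  # area halving linearly over 500 a from A0: dA/dt = -A0/1000
  A0 <- 2e5
  expect_equal(wetland_growth_rate(A0, -A0 / 1000), 1e-3)
  expect_equal(wetland_growth_rate(A0, A0 / 1000), 0)  # growing area
  expect_equal(wetland_growth_rate(0, -10), 0)         # fully terrestrial
})
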