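# thermal response functions

test_that("temperature factor peaks at the optimum and is symmetric", {
  tp <- thermal_params(T0 = 23, beta = 20)
  expect_equal(temperature_factor(23, tp), 1)
  expect_equal(temperature_factor(43, tp), exp(-1))
  expect_equal(temperature_factor(3, tp), temperature_factor(43, tp))
  grid <- seq(-10, 45, by = 0.5)
  tf <- temperature_factor(grid, tp)
  expect_true(all(tf > 0 & tf <= 1))
  expect_equal(grid[which.max(tf)], 23)
  # even about T0 on a symmetric grid
  expect_equal(temperature_factor(23 + 0:15, tp),
               temperature_factor(23 - 0:15, tp))
  expect_error(temperature_factor(NaN, tp), "finite")
})

test_that("growth rate scales the intrinsic rate by the factor", {
  tp <- thermal_params()
  expect_equal(growth_rate_at(23, 8, tp), 8)
  expect_equal(growth_rate_at(35, 0, tp), 0)
  expect_equal(growth_rate_at(43, 8, tp), 8 * exp(-1))
  expect_true(all(growth_rate_at(seq(-10, 45), 8, tp) <= 8))
  expect_error(growth_rate_at(20, -1, tp), ">= 0")
})

test_that("Arrhenius durations behave and stay positive on [-10, 45]", {
  tp <- thermal_params(arrhenius = list(
    egg_duration = c(a = 30, b = 0),
    nymph_preovip_duration = c(a = 30, b = 0.05),
    adult_lifespan = c(a = 30, b = 0.05)))
  expect_equal(stage_duration(17, "egg_duration", tp), 30)
  expect_equal(stage_duration(20, "nymph_preovip_duration", tp), 30 * exp(-1))
  expect_lte(stage_duration(28, "adult_lifespan", tp),
             stage_duration(15, "adult_lifespan", tp))
  expect_error(stage_duration(20, "pupa_duration", tp), "unknown stage")
  for (st in c("egg_duration", "nymph_preovip_duration", "adult_lifespan")) {
    d <- stage_duration(seq(-10, 45, by = 1), st, thermal_params())
    expect_true(all(is.finite(d) & d > 0))
  }
})

test_that("duration-rate reciprocal is an exact involution", {
  expect_equal(rate_from_duration(20), 0.05)
  expect_equal(rate_from_duration(1), 1)
  expect_equal(rate_from_duration(8), 0.125)
  x <- c(0.3, 1, 7.7, 123.4)
  expect_equal(rate_from_duration(rate_from_duration(x)), x,
               tolerance = 1e-15)
  expect_error(rate_from_duration(0), "> 0")
  expect_error(rate_from_duration(-3), "> 0")
})

test_that("developmental threshold includes the boundary", {
  expect_equal(stage_indicator(11, 11), 1)
  expect_equal(stage_indicator(10.99, 11), 0)
  expect_equal(stage_indicator(30, 8), 1)
})

test_that("thermal rates are reciprocal durations with gating indicators", {
  tp <- thermal_params(arrhenius = list(
    egg_duration = c(a = 10, b = 0),
    nymph_preovip_duration = c(a = 20, b = 0),
    adult_lifespan = c(a = 25, b = 0)))
  r <- thermal_rates(15, tp, noise_scale = 0)
  expect_equal(r$mu, 0.04)
  expect_equal(r$omega1, 0.1)
  expect_equal(r$omega2, 0.05)
  expect_equal(r$psi1, 1)  # 15 >= 11
  expect_equal(r$psi2, 1)
  r2 <- thermal_rates(9, tp, noise_scale = 0)
  expect_equal(r2$psi1, 0)
  expect_equal(r2$psi2, 1)
  expect_error(thermal_rates(15, tp, noise_scale = -0.1), ">= 0")
})

test_that("noisy thermal rates are seeded and unbiased", {
  tp <- thermal_params()
  set.seed(99)
  a <- thermal_rates(20, tp, noise_scale = 0.1)
  set.seed(99)
  b <- thermal_rates(20, tp, noise_scale = 0.1)
  expect_identical(a, b)

  set.seed(1)
  f <- draw_thermal_factors(0.1, n = 1e5)
  # mean-1 multiplicative factors: sample mean within 3 standard errors
  se <- apply(f, 2, sd) / sqrt(nrow(f))
  expect_true(all(abs(colMeans(f) - 1) < 3 * se + 1e-3))
  expect_true(all(f > 0))
})
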