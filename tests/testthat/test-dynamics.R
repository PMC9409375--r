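# deterministic core: RHS, integration, cycle metrics, crop integral

test_that("RHS has the extinction fixed point and closed-form limits", {
  p <- model_params()
  zero <- c(C = 0, P = 0, W = 0, E = 0, N = 0)
  expect_equal(unname(rhs_autonomous(zero, p)), rep(0, 5))
  expect_error(rhs_autonomous(c(C = -1, P = 0, W = 0, E = 0, N = 0), p),
               "non-negative")

  # no feeding: crop decouples to logistic-with-harvest
  p0 <- set_params(p, a1 = 0)
  st <- c(C = 300, P = 0, W = 0, E = 0, N = 0)
  d <- rhs_autonomous(st, p0)
  expect_equal(d[["C"]], p0$r * 300 * (1 - 300 / p0$K) - p0$h * 300)
  Cstar <- p0$K * (1 - p0$h / p0$r)
  expect_equal(rhs_autonomous(c(C = Cstar, P = 0, W = 0, E = 0, N = 0),
                              p0)[["C"]], 0, tolerance = 1e-10)

  # decoupled adults decay exponentially
  p1 <- set_params(p, a1 = 0)
  traj <- integrate_model(p1, init = c(C = 0, P = 40, W = 0, E = 0, N = 0),
                          t_end = 30, dt_out = 0.5)
  expect_equal(traj$P, 40 * exp(-p1$mu * traj$time), tolerance = 1e-6)
})

test_that("temperature-forced RHS gates maturation below thresholds", {
  p <- model_params()
  st <- c(C = 400, P = 30, W = 10, E = 80, N = 20)
  d <- rhs_temperature(st, p, T = 5)  # below both thresholds
  expect_equal(d[["N"]], 0)
  expect_equal(d[["E"]],
               p$c1 * p$a1 * 400 * 30 / (p$b1 + 400) -
                 p$a2 * 80 * 10 / (p$b2 + 80))
  # at the optimum the crop term matches the autonomous one
  rates23 <- thermal_rates(p$thermal$T0, p$thermal, noise_scale = 0)
  d23 <- rhs_temperature(st, p, T = p$thermal$T0, rates = rates23)
  expect_equal(d23[["C"]], rhs_autonomous(st, p)[["C"]])
  # maturation flux conservation between E and N at a warm temperature
  dT <- rhs_temperature(st, p, T = 25)
  rates <- thermal_rates(25, p$thermal, noise_scale = 0)
  flux <- rates$psi1 * rates$omega1 * st[["E"]]
  expect_equal(dT[["N"]], flux - rates$psi2 * rates$omega2 * st[["N"]])
})

test_that("integration reaches the harvested-logistic equilibrium", {
  p <- set_params(model_params(), a1 = 0)
  traj <- integrate_model(p, init = c(C = p$K / 2, P = 0, W = 0, E = 0,
                                      N = 0), t_end = 50)
  Cstar <- p$K * (1 - p$h / p$r)
  expect_lt(abs(traj$C[nrow(traj)] - Cstar) / Cstar, 0.001)
})

test_that("without attraction and initial enemies W stays identically zero", {
  p <- set_params(model_params(), lam = 0)
  init <- default_init(p)
  traj <- integrate_model(p, init = init, t_end = 200)
  expect_true(all(abs(traj$W) < 1e-8))
  # and the rest of the system ignores the enemy parameters
  p2 <- set_params(p, a2 = p$a2 * 3, b2 = p$b2 * 2, c2 = p$c2 * 2,
                   delta = p$delta * 5)
  traj2 <- integrate_model(p2, init = init, t_end = 200)
  expect_equal(traj2$C, traj$C, tolerance = 1e-6)
  expect_equal(traj2$P, traj$P, tolerance = 1e-6)
})

test_that("output resolution does not change the solution", {
  p <- model_params()
  t1 <- integrate_model(p, t_end = 100, dt_out = 0.5)
  t2 <- integrate_model(p, t_end = 100, dt_out = 0.25)
  shared <- t2$time %in% t1$time
  expect_equal(t2$C[shared], t1$C, tolerance = 1e-5)
})

test_that("cycle metrics read period and amplitude off a known signal", {
  # synthetic trajectory: 40-day sine on C, constant elsewhere
  tt <- seq(0, 800, by = 0.2)
  traj <- structure(
    data.frame(time = tt, C = 100 + 20 * sin(2 * pi * tt / 40),
               P = 5, W = 2, E = 3, N = 4),
    class = c("tri_trajectory", "data.frame"))
  m <- cycle_metrics(traj, transient = 100)
  expect_true(m$oscillating)
  expect_equal(m$period, 40, tolerance = 0.02)
  expect_equal(m$amplitude[["C"]], 20, tolerance = 0.01)
  expect_equal(m$amplitude[["P"]], 0)

  # amplitude invariant to a transient prefix
  traj2 <- traj
  traj2$C[tt < 100] <- 100 + 60 * exp(-tt[tt < 100] / 10)
  m2 <- cycle_metrics(traj2, transient = 100)
  expect_equal(m2$amplitude[["C"]], m$amplitude[["C"]], tolerance = 1e-6)

  flat <- structure(data.frame(time = tt, C = 50, P = 1, W = 1, E = 1, N = 1),
                    class = c("tri_trajectory", "data.frame"))
  mf <- cycle_metrics(flat, transient = 0)
  expect_false(mf$oscillating)
  expect_equal(unname(mf$amplitude), rep(0, 5))

  expect_error(cycle_metrics(flat, transient = 1e4), "too short")
})

test_that("crop integral is the trapezoidal area with additivity", {
  tt <- seq(0, 10, by = 0.1)
  make <- function(Cv) structure(
    data.frame(time = tt, C = Cv, P = 0, W = 0, E = 0, N = 0),
    class = c("tri_trajectory", "data.frame"))
  expect_equal(crop_integral(make(rep(5, length(tt))), 0, 10), 50)
  expect_equal(crop_integral(make(tt), 0, 10), 50)       # triangle
  tr <- make(3 + sin(tt))
  expect_equal(crop_integral(tr, 0, 4) + crop_integral(tr, 4, 10),
               crop_integral(tr, 0, 10), tolerance = 1e-10)
  expect_error(crop_integral(tr, 5, 5), "empty")
  expect_error(crop_integral(tr, 0, 11), "outside")
})

test_that("a degenerate one-value scan returns metrics and no bifurcation", {
  p <- model_params()
  hs <- hopf_scan(p, "a2", values = p$a2, t_end = 600, transient = 300)
  expect_length(hs$metrics, 1)
  expect_true(is.na(hs$critical_value))
})
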