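# reaction channels and the tau-leap engine

random_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    c(C = sample(0:2000, 1), P = sample(0:500, 1), W = sample(0:500, 1),
      E = sample(0:500, 1), N = sample(0:500, 1)))
}

test_that("channel decomposition reproduces the forced RHS exactly", {
  p <- model_params()
  ch <- build_channels(p)
  expect_length(ch, 12)
  for (T in c(5, 14, 23, 30)) {
    rates <- channel_rates(p, T)
    for (st in random_states(5, seed = round(T))) {
      drift <- Reduce(`+`, lapply(ch, function(cc)
        cc$change * cc$propensity(st, p, rates)))
      expect_equal(drift[c("C", "P", "W", "E", "N")],
                   rhs_temperature(st, p, T),
                   tolerance = 1e-12)
    }
  }
})

test_that("propensities vanish at the zero state and stages are conserved", {
  p <- model_params()
  ch <- build_channels(p)
  rates <- channel_rates(p, 23)
  zero <- c(C = 0, P = 0, W = 0, E = 0, N = 0)
  a <- vapply(ch, function(cc) cc$propensity(zero, p, rates), numeric(1))
  expect_true(all(a == 0))
  egg_mat <- ch[[which(vapply(ch, `[[`, character(1), "name") ==
                         "egg_maturation")]]
  expect_equal(sum(egg_mat$change), 0)           # E+N conserved
  expect_equal(unname(egg_mat$change[c("E", "N")]), c(-1, 1))
  expect_true(all(vapply(ch, function(cc)
    all(cc$change %in% c(-1, 0, 1)), logical(1))))
})

test_that("tau_leap_step fires Poisson events with the right mean", {
  p <- model_params()
  ch <- build_channels(p)
  rates <- channel_rates(p, 23)
  st <- c(C = 500, P = 50, W = 20, E = 100, N = 40)

  # zero propensities leave the state unchanged
  zero <- c(C = 0, P = 0, W = 0, E = 0, N = 0)
  out <- tau_leap_step(zero, ch, p, rates, tau = 0.5)
  expect_equal(unname(out[1:5]), unname(zero))

  # a single channel with propensity a over tau has mean a*tau
  one_ch <- list(list(name = "egg_in",
                      propensity = function(state, p, rates) 5,
                      change = c(C = 0, P = 0, W = 0, E = 1, N = 0)))
  set.seed(11)
  incr <- replicate(4000, {
    tau_leap_step(st, one_ch, p, rates, tau = 2)[["E"]] - st[["E"]]
  })
  expect_lt(abs(mean(incr) - 10), 3 * sd(incr) / sqrt(length(incr)))

  set.seed(5); a <- tau_leap_step(st, ch, p, rates, tau = 0.05)
  set.seed(5); b <- tau_leap_step(st, ch, p, rates, tau = 0.05)
  expect_identical(a, b)
})

test_that("stochastic runs are seed-reproducible", {
  p <- model_params()
  ts <- synthetic_anqing(seed = 2)
  a <- simulate_stochastic(p, ts, seed = 31)
  b <- simulate_stochastic(p, ts, seed = 31)
  expect_identical(a$C, b$C)
  expect_identical(a$N, b$N)
  e1 <- run_ensemble(p, ts, n_runs = 4, master_seed = 9)
  e2 <- run_ensemble(p, ts, n_runs = 4, master_seed = 9)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$seeds, e2$seeds)
  e3 <- run_ensemble(p, ts, n_runs = 4, master_seed = 10)
  expect_false(identical(e1$states[, , 1], e3$states[, , 1]))
  # single runs reproduce ensemble members from their stored seeds
  tr <- simulate_stochastic(p, ts, seed = e1$seeds[2])
  expect_equal(unname(as.matrix(tr[, c("C", "P", "W", "E", "N")])),
               unname(e1$states[, , 2]))
})

test_that("development freezes when all temperatures are below threshold", {
  p <- model_params()
  dates <- seq(as.Date("2021-01-01"), by = "day", length.out = 60)
  cold <- temperature_series(dates, rep(5, 60))  # below both thresholds? no:
  # 5 < 8 < 11, so psi1 = psi2 = 0 and no maturation events can fire
  init <- c(C = 500, P = 40, W = 0, E = 0, N = 0)
  tr <- simulate_stochastic(p, cold, init = init, seed = 4)
  expect_true(all(tr$N == 0))   # nothing matures into nymphs
  expect_gt(max(tr$E), 0)       # eggs are still laid
})

test_that("tau-leap ensemble mean tracks the forced ODE at constant T", {
  # mean-field check: large populations, no run-level noise
  p <- model_params("seasonal")
  n_days <- 60
  dates <- seq(as.Date("2021-01-01"), by = "day", length.out = n_days)
  tsc <- temperature_series(dates, rep(23, n_days))
  ens <- run_ensemble(p, tsc, n_runs = 120, master_seed = 12,
                      noise_scale = 0)
  ode <- integrate_model(p, t_end = n_days, temperature = tsc)
  last <- ode[nrow(ode), ]
  m <- t(ens$states[n_days + 1, , ])
  for (v in c("C", "P", "W", "E", "N")) {
    se <- max(sd(m[, v]) / sqrt(nrow(m)), 1e-6)
    expect_lt(abs(mean(m[, v]) - last[[v]]), 4 * se + 0.05 * abs(last[[v]]))
  }
})

test_that("demographic noise shrinks as populations scale up", {
  p0 <- model_params("seasonal")
  n_days <- 50
  dates <- seq(as.Date("2021-01-01"), by = "day", length.out = n_days)
  tsc <- temperature_series(dates, rep(23, n_days))
  rel_sd <- function(scale) {
    ps <- set_params(p0, K = p0$K * scale, b1 = p0$b1 * scale,
                     b2 = p0$b2 * scale)
    ens <- run_ensemble(ps, tsc, n_runs = 60, master_seed = 3,
                        noise_scale = 0, init = default_init(ps))
    x <- ens$states[n_days + 1, "C", ]
    sd(x) / mean(x)
  }
  expect_gt(rel_sd(1 / 30), rel_sd(1))
})
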