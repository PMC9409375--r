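# outbreak detection, event distributions, EAT

make_traj <- function(PN, E = NULL, days = 366) {
  if (is.null(E)) E <- rep(1, days)
  structure(data.frame(time = seq_len(days), C = 100, P = PN, W = 0,
                       E = E, N = 0),
            class = c("tri_trajectory", "data.frame"))
}

bump <- function(center, width = 15, height = 100, days = 366) {
  d <- seq_len(days)
  height * exp(-((d - center) / width)^2)
}

test_that("double-bump pest series yields both outbreak days", {
  tr <- make_traj(bump(140) + bump(270, height = 80))
  pk <- detect_outbreaks(tr)
  expect_lte(abs(pk$first_peak_day - 140), 3)
  expect_lte(abs(pk$second_peak_day - 270), 3)

  flat <- make_traj(rep(3, 366))
  pk0 <- detect_outbreaks(flat)
  expect_true(is.na(pk0$first_peak_day) && is.na(pk0$second_peak_day))

  single <- detect_outbreaks(make_traj(bump(150)))
  expect_lte(abs(single$first_peak_day - 150), 3)
  expect_true(is.na(single$second_peak_day))
})

test_that("nearby sub-peaks are pruned by separation and prominence", {
  # a shoulder 20 days after the main peak must not count twice
  tr <- make_traj(bump(140) + 0.7 * bump(160) + bump(280, height = 90))
  pk <- detect_outbreaks(tr)
  expect_lte(abs(pk$first_peak_day - 143), 6)
  expect_lte(abs(pk$second_peak_day - 280), 3)
  # small ripples below the prominence floor are ignored
  set.seed(2)
  tr2 <- make_traj(bump(140) + bump(270) + 3 * sin(seq_len(366)))
  pk2 <- detect_outbreaks(tr2)
  expect_lte(abs(pk2$first_peak_day - 140), 3)
  expect_lte(abs(pk2$second_peak_day - 270), 3)
})

test_that("egg trough sits at the interior minimum with earliest-tie rule", {
  E <- 50 - bump(188, width = 25, height = 40)
  tr <- make_traj(bump(140) + bump(270), E = E)
  expect_lte(abs(detect_egg_trough(tr, 140, 270) - 188), 3)

  # monotone egg series: boundary-adjacent interior minimum
  trm <- make_traj(bump(140) + bump(270), E = seq(10, 100, length.out = 366))
  expect_equal(detect_egg_trough(trm, 140, 270), 141)

  # exact tie resolves to the earlier day
  Et <- rep(50, 366); Et[c(180, 200)] <- 10
  # use an unsmoothed window so the tie survives smoothing symmetrically
  trt <- make_traj(bump(140) + bump(270), E = Et)
  expect_equal(detect_egg_trough(trt, 140, 270, smooth_window = 1), 180)

  expect_error(detect_egg_trough(tr, NA, 270), "present")
})

test_that("event distributions summarize ensembles of event days", {
  expect_error(event_distribution(c(140, 150), min_n = 100), "need")
  days <- rep(145, 150)
  ed <- event_distribution(days)
  expect_equal(ed$median, 145)
  expect_equal(unname(ed$ci), c(145, 145))

  set.seed(3)
  days2 <- round(rnorm(400, 150, 7))
  ed2 <- event_distribution(days2)
  expect_equal(ed2$median, median(days2))
  # order invariance
  ed3 <- event_distribution(rev(days2))
  expect_equal(ed3$median, ed2$median)
  # KDE integrates to ~1
  area <- sum(diff(ed2$kde$x) * (head(ed2$kde$y, -1) + tail(ed2$kde$y, -1)) / 2)
  expect_lt(abs(area - 1), 0.01)
})

test_that("daily average EAT matches the defining sum", {
  dates <- seq(as.Date("2020-01-01"), by = "day", length.out = 10)
  ts <- temperature_series(dates, c(10, 10, 10, 10, 10, 10, 10,
                                    17.8, 19.8, 21.8))
  expect_equal(daily_avg_eat(ts, day = 10, n = 3, B = 7.8), 12)
  expect_equal(daily_avg_eat(ts, day = 10, n = 1, B = 7.8), 14)
  tsb <- temperature_series(dates, rep(7.8, 10))
  expect_equal(daily_avg_eat(tsb, day = 5, n = 5, B = 7.8), 0)
  expect_error(daily_avg_eat(ts, day = 5, n = 10, B = 7.8), "history")
  # negative terms are not floored
  tsn <- temperature_series(dates, rep(5, 10))
  expect_equal(daily_avg_eat(tsn, day = 10, n = 4, B = 7.8), 5 - 7.8)
})

test_that("EAT frequencies normalize and need a non-empty ensemble", {
  ts <- synthetic_anqing(seed = 1)
  ev <- data.frame(run = 1:60, first = round(rnorm(60, 145, 5)),
                   second = round(rnorm(60, 270, 15)), trough = NA)
  ef <- outbreak_eat_frequency(ev, ts, n_values = c(10, 80))
  for (el in ef) {
    expect_equal(sum(el$eat$freq), 1, tolerance = 1e-9)
    expect_true(all(is.finite(el$eat$eat)))
  }
  empty <- data.frame(run = integer(), first = integer(),
                      second = integer(), trough = integer())
  expect_error(outbreak_eat_frequency(empty, ts), "no outbreak")
})
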