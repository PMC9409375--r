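#' Reaction-channel decomposition of the temperature-forced model
#'
#' Decomposes the forced right-hand side into 12 reaction channels, each a
#' propensity function (events per day) and an integer state-change vector
#' over (C, P, W, E, N).  The propensity-weighted sum of change vectors
#' reproduces the deterministic right-hand side exactly, so the tau-leap
#' scheme is mean-exact.  Logistic crop growth is split into a birth and a
#' density-death channel (a single channel would have a negative propensity
#' above carrying capacity); egg parasitism and enemy recruitment are
#' separate channels so that both means match the rate equations without
#' non-integer increments.
#'
#' Each propensity has signature `function(state, p, rates)` where `rates`
#' is a [thermal_rates()] result augmented with elements `rT` (realized crop
#' growth rate), `a1` and `lam` (possibly modulated by an intervention).
#'
#' @param p a [model_params()] object.
#' @return A list of 12 channels, each `list(name, propensity, change)`.
#' @export
#' @examples
#' p <- model_params()
#' ch <- build_channels(p)
#' vapply(ch, `[[`, character(1), "name")
build_channels <- function(p) {
  ch <- function(name, propensity, ...) {
    change <- c(C = 0, P = 0, W = 0, E = 0, N = 0)
    repl <- c(...)
    change[names(repl)] <- repl
    list(name = name, propensity = propensity, change = change)
  }
  feed_flux <- function(state, p, rates)
    rates$a1 * state[["C"]] * (state[["P"]] + state[["N"]]) / (p$b1 + state[["C"]])
  par_flux <- function(state, p, rates)
    p$a2 * state[["E"]] * state[["W"]] / (p$b2 + state[["E"]])
  list(
    ch("crop_birth",
       function(state, p, rates) rates$rT * state[["C"]], C = +1),
    ch("crop_density_death",
       function(state, p, rates) rates$rT * state[["C"]]^2 / p$K, C = -1),
    ch("crop_consumption", feed_flux, C = -1),
    ch("harvest",
       function(state, p, rates) p$h * state[["C"]], C = -1),
    ch("oviposition",
       function(state, p, rates)
         p$c1 * rates$a1 * state[["C"]] * state[["P"]] / (p$b1 + state[["C"]]),
       E = +1),
    ch("egg_maturation",
       function(state, p, rates) rates$psi1 * rates$omega1 * state[["E"]],
       E = -1, N = +1),
    ch("nymph_maturation",
       function(state, p, rates) rates$psi2 * rates$omega2 * state[["N"]],
       N = -1, P = +1),
    ch("adult_death",
       function(state, p, rates) rates$mu * state[["P"]], P = -1),
    ch("parasitism", par_flux, E = -1),
    ch("enemy_recruitment",
       function(state, p, rates) p$c2 * par_flux(state, p, rates), W = +1),
    ch("enemy_attraction",
       function(state, p, rates) rates$lam * feed_flux(state, p, rates),
       W = +1),
    ch("enemy_dispersal",
       function(state, p, rates) p$delta * state[["W"]], W = -1))
}

#' Augment thermal rates with realized crop growth and intervention levels
#'
#' @param p a [model_params()] object.
#' @param T temperature (degC).
#' @param rates a [thermal_rates()] result; computed noise-free when `NULL`.
#' @param a1,lam overrides for the feeding and attraction rates (used by
#'   semiochemical schedules); default to the values in `p`.
#' @return The `rates` list with `rT`, `a1`, `lam` added.
#' @export
channel_rates <- function(p, T, rates = NULL, a1 = p$a1, lam = p$lam) {
  if (is.null(rates)) rates <- thermal_rates(T, p$thermal, noise_scale = 0)
  rates$rT <- p$r * temperature_factor(T, p$thermal)
  rates$a1 <- a1
  rates$lam <- lam
  rates
}

#' One Poisson tau-leap step
#'
#' Advances an integer state by `tau` days: every channel fires a Poisson
#' number of events with mean `propensity * tau`, and the state-change
#' vectors are applied.  Species driven below zero are clamped to zero; the
#' number of clamped species is recorded in the `clamps` attribute.
#'
#' @param state named non-negative integer-valued vector `c(C, P, W, E, N)`.
#' @param channels channel list from [build_channels()] or
#'   [predator_variant_channels()].
#' @param p a [model_params()] object.
#' @param rates augmented rates from [channel_rates()].
#' @param tau leap length in days (> 0).
#' @return Updated state vector with attribute `clamps`.
#' @export
tau_leap_step <- function(state, channels, p, rates, tau) {
  if (tau <= 0) stop("`tau` must be > 0")
  if (any(state < 0)) stop("state must be non-negative")
  new <- state
  for (chn in channels) {
    a <- chn$propensity(state, p, rates)
    if (a < 0) stop("negative propensity in channel ", chn$name)
    if (a > 0) new <- new + chn$change * rpois(1L, a * tau)
  }
  clamps <- sum(new < 0)
  new[new < 0] <- 0
  attr(new, "clamps") <- clamps
  new
}

# per-day rate table for the compiled kernel; factors are run-level
# multiplicative noise; schedule_a1/schedule_lam are per-day modulated rates
.day_rate_table <- function(p, temps, factors, a1_daily = NULL,
                            lam_daily = NULL) {
  tp <- p$thermal
  Tv <- temps$temp_c
  n <- length(Tv)
  rT <- p$r * temperature_factor(Tv, tp)
  mu <- factors[["mu"]] / stage_duration(Tv, "adult_lifespan", tp)
  w1 <- factors[["omega1"]] / stage_duration(Tv, "egg_duration", tp) *
    stage_indicator(Tv, tp$Ttheta1)
  w2 <- factors[["omega2"]] / stage_duration(Tv, "nymph_preovip_duration", tp) *
    stage_indicator(Tv, tp$Ttheta2)
  a1 <- if (is.null(a1_daily)) rep(p$a1, n) else a1_daily
  lam <- if (is.null(lam_daily)) rep(p$lam, n) else lam_daily
  cbind(rT = rT, mu = mu, w1 = w1, w2 = w2, a1 = a1, lam = lam)
}

#' Stochastic simulation of one season
#'
#' Poisson tau-leap simulation of the temperature-forced model over a daily
#' temperature series, stepping `1/tau` times per day with the day's
#' constant temperature, and recording the state at the end of each day.
#' The run-level thermal noise factors (relative dispersion
#' `noise_scale`) are drawn once at the start of the run.
#'
#' @param p a [model_params()] object.
#' @param temps a [temperature_series()] (its length sets the horizon).
#' @param init initial state (integer-valued); default [default_init()].
#' @param tau leap length in days; must divide one day evenly.
#' @param seed optional integer seed.
#' @param noise_scale relative dispersion of run-level thermal factors;
#'   defaults to the `variation_cv` of the thermal parameters.
#' @param schedule optional [release_schedule()] applied during the run.
#' @param variant `"parasitoid"` (egg parasitism, default) or `"predator"`
#'   (consumption of nymphs and adults).
#' @return A `tri_trajectory` with one row per day (day 0 = initial state),
#'   plus attributes `clamps` and `factors`.
#' @export
#' @examples
#' ts <- synthetic_anqing(seed = 1)
#' traj <- simulate_stochastic(model_params(), ts, seed = 1)
#' head(traj)
simulate_stochastic <- function(p, temps, init = default_init(p), tau = 0.05,
                                seed = NULL,
                                noise_scale = p$thermal$variation_cv,
                                schedule = NULL,
                                variant = c("parasitoid", "predator")) {
  stopifnot(inherits(p, "model_params"))
  if (!inherits(temps, "temperature_series") || nrow(temps) == 0)
    stop("`temps` must be a non-empty temperature_series")
  variant <- match.arg(variant)
  steps_per_day <- round(1 / tau)
  if (abs(steps_per_day * tau - 1) > 1e-9)
    stop("`tau` must divide 1 day evenly (e.g. 0.05)")
  if (!is.null(seed)) set.seed(seed)
  factors <- draw_thermal_factors(noise_scale, 1L)[1, ]
  n <- nrow(temps)
  a1_daily <- lam_daily <- NULL
  if (!is.null(schedule)) {
    lv <- schedule_levels(schedule, n)
    ep <- schedule$efficacy
    if (schedule$mode == "attractant") {
      lam_daily <- ifelse(lv > 0, lambda_modulated(lv, ep), p$lam)
    } else {
      a1_daily <- ifelse(lv > 0, repellent_modulated(p$a1, lv, ep), p$a1)
    }
  }
  tab <- .day_rate_table(p, temps, factors, a1_daily, lam_daily)
  pars <- p[c("K", "b1", "b2", "a2", "c1", "c2", "h", "delta")]
  res <- .tau_leap_run_cpp(as.numeric(round(init[state_names])), tab, pars,
                           tau, steps_per_day,
                           if (variant == "parasitoid") 0L else 1L)
  st <- res$states
  colnames(st) <- state_names
  out <- data.frame(time = 0:n, st)
  out$temperature <- c(temps$temp_c[1], temps$temp_c)
  structure(out, class = c("tri_trajectory", "data.frame"),
            clamps = res$clamps, steps = res$steps, factors = factors,
            variant = variant)
}

#' Run a seeded stochastic ensemble
#'
#' Per-run seeds are derived reproducibly from the master seed, so the same
#' master seed yields a bitwise-identical ensemble and each run can be
#' reproduced in isolation with [simulate_stochastic()] and its stored seed.
#'
#' @inheritParams simulate_stochastic
#' @param n_runs number of independent runs (>= 1).
#' @param master_seed integer master seed.
#' @param warn_clamp_frac warn when the fraction of clamped steps exceeds
#'   this (default 0.1%), suggesting a smaller `tau`.
#' @return A `tri_ensemble`: list with `states` (array day x species x run,
#'   day 0 first), `seeds`, `factors`, `tau`, `variant`, `temps`.
#' @export
run_ensemble <- function(p, temps, n_runs, tau = 0.05, master_seed = 1L,
                         noise_scale = p$thermal$variation_cv,
                         schedule = NULL,
                         variant = c("parasitoid", "predator"),
                         init = default_init(p), warn_clamp_frac = 1e-3) {
  stopifnot(n_runs >= 1)
  variant <- match.arg(variant)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  n <- nrow(temps)
  states <- array(NA_real_, dim = c(n + 1, 5, n_runs),
                  dimnames = list(NULL, state_names, NULL))
  factors <- matrix(NA_real_, n_runs, 3,
                    dimnames = list(NULL, c("mu", "omega1", "omega2")))
  clamps <- 0; steps <- 0
  for (i in seq_len(n_runs)) {
    tr <- simulate_stochastic(p, temps, init = init, tau = tau,
                              seed = seeds[i], noise_scale = noise_scale,
                              schedule = schedule, variant = variant)
    states[, , i] <- as.matrix(tr[, state_names])
    factors[i, ] <- attr(tr, "factors")
    clamps <- clamps + attr(tr, "clamps")
    steps <- steps + attr(tr, "steps")
  }
  if (steps > 0 && clamps / steps > warn_clamp_frac)
    warning(sprintf(paste0("%.2f%% of tau-leap steps clamped a species at 0;",
                           " consider a smaller tau"), 100 * clamps / steps))
  structure(list(states = states, seeds = seeds, factors = factors,
                 tau = tau, variant = variant, temps = temps,
                 clamp_frac = if (steps > 0) clamps / steps else 0),
            class = "tri_ensemble")
}

#' @export
print.tri_ensemble <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<tri_ensemble> %d runs x %d days (%s model)\n",
              d[3], d[1] - 1, x$variant))
  cat(sprintf("  tau = %g day, clamp fraction %.2g\n", x$tau, x$clamp_frac))
  invisible(x)
}

#' Extract one run of an ensemble as a trajectory
#' @param ensemble a `tri_ensemble`.
#' @param run run index.
#' @return A `tri_trajectory` data.frame.
#' @export
ensemble_run <- function(ensemble, run) {
  stopifnot(inherits(ensemble, "tri_ensemble"))
  d <- dim(ensemble$states)
  if (run < 1 || run > d[3]) stop("run index out of range")
  out <- data.frame(time = 0:(d[1] - 1), ensemble$states[, , run])
  names(out) <- c("time", state_names)
  structure(out, class = c("tri_trajectory", "data.frame"))
}

#' Ensemble to long-format data frame
#' @param ensemble a `tri_ensemble`.
#' @return data.frame with columns run, day, C, P, W, E, N.
#' @export
ensemble_long <- function(ensemble) {
  d <- dim(ensemble$states)
  do.call(rbind, lapply(seq_len(d[3]), function(i) {
    cbind(run = i, day = 0:(d[1] - 1),
          as.data.frame(ensemble$states[, , i]))
  }))
}
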