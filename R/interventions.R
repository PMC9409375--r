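#' Semiochemical efficacy parameters
#'
#' Michaelis-Menten-type dose response of the semiochemical: at level `SCs`
#' the modulation factor is `vmax * SCs / (SCs + Km)`.
#'
#' @param vmax maximal fold-modulation (dimensionless, > 0).
#' @param Km half-saturation semiochemical level (units per day, > 0).
#' @param lam0 baseline enemy attraction rate.
#' @return list of class `efficacy_params`.
#' @export
efficacy_params <- function(vmax = 12, Km = 12, lam0 = 0.3) {
  stopifnot(vmax > 0, Km > 0, lam0 > 0)
  structure(list(vmax = vmax, Km = Km, lam0 = lam0),
            class = "efficacy_params")
}

#' Attractant-modulated enemy attraction rate
#'
#' `lambda(SCs) = lam0 * (1 + vmax * SCs/(SCs + Km))`; equals the baseline
#' at `SCs = 0` and saturates at `lam0 * (1 + vmax)`.
#'
#' @param SCs semiochemical level (units per day, >= 0); vectorized.
#' @param ep an [efficacy_params()] object.
#' @return Modulated attraction rate (dimensionless).
#' @export
#' @examples
#' lambda_modulated(12, efficacy_params())  # 0.3 * (1 + 12 * 12/24) = 2.1
lambda_modulated <- function(SCs, ep = efficacy_params()) {
  if (any(SCs < 0)) stop("`SCs` must be >= 0")
  ep$lam0 * (1 + ep$vmax * SCs / (SCs + ep$Km))
}

#' Repellent-modulated feeding rate
#'
#' Mirror image of the attractant law: the feeding rate is divided by
#' `1 + vmax * SCs/(SCs + Km)`, so it equals `a1_base` with no treatment
#' and decreases monotonically with the semiochemical level.
#'
#' @param a1_base untreated feeding rate (per day).
#' @inheritParams lambda_modulated
#' @return Suppressed feeding rate (per day).
#' @export
repellent_modulated <- function(a1_base, SCs, ep = efficacy_params()) {
  if (any(SCs < 0)) stop("`SCs` must be >= 0")
  a1_base / (1 + ep$vmax * SCs / (SCs + ep$Km))
}

#' Sample slow-release durations
#'
#' Durations follow a normal distribution (default mean 60 days, SD 20),
#' truncated to at least one day by resampling.  The paired daily release
#' level is `dosage / D`, so every schedule delivers the same total dosage.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (days).
#' @return Numeric vector of durations (days, >= 1).
#' @export
sample_duration <- function(n = 1, mean = 60, sd = 20) {
  if (sd == 0) return(rep(mean, n))
  d <- rnorm(n, mean, sd)
  bad <- d < 1
  while (any(bad)) {
    d[bad] <- rnorm(sum(bad), mean, sd)
    bad <- d < 1
  }
  d
}

#' Construct a semiochemical release schedule
#'
#' A fixed total dosage is spread uniformly over `duration` days starting at
#' `start_day`: the daily level is `dosage / duration` inside the window and
#' zero outside, so `duration * level = dosage` exactly.
#'
#' @param start_day first day of application (day of year).
#' @param duration release duration in days (>= 1).
#' @param dosage total semiochemical amount (default 720 units).
#' @param mode `"attractant"` (raises the enemy attraction rate) or
#'   `"repellent"` (suppresses the feeding rate).
#' @param efficacy an [efficacy_params()] object.
#' @return list of class `release_schedule` with the daily level `SCs`.
#' @export
release_schedule <- function(start_day, duration, dosage = 720,
                             mode = c("attractant", "repellent"),
                             efficacy = efficacy_params()) {
  mode <- match.arg(mode)
  stopifnot(duration >= 1, dosage > 0, start_day >= 1)
  structure(list(start_day = start_day, duration = duration,
                 dosage = dosage, SCs = dosage / duration, mode = mode,
                 efficacy = efficacy),
            class = "release_schedule")
}

#' Daily semiochemical levels over a season
#'
#' @param schedule a [release_schedule()].
#' @param n_days season length in days.
#' @return Numeric vector of length `n_days`: `SCs` inside the release
#'   window `[start_day, start_day + duration)`, zero outside.
#' @export
schedule_levels <- function(schedule, n_days) {
  stopifnot(inherits(schedule, "release_schedule"))
  d <- seq_len(n_days)
  ifelse(d >= schedule$start_day &
           d < schedule$start_day + schedule$duration, schedule$SCs, 0)
}

#' Reaction channels of the predator variant
#'
#' The predator model replaces egg parasitism by Holling type II predation
#' on the active stages (nymphs and adults, shared half-saturation `b2`):
#' adults are removed at `a2*P*W/(b2+P+N)`, nymphs at `a2*N*W/(b2+P+N)`,
#' and predators are recruited at `c2*a2*(P+N)*W/(b2+P+N)`.  Attraction and
#' dispersal channels are unchanged; the egg balance keeps only oviposition
#' and maturation.  All parameters keep the same values as the parasitoid
#' model.
#'
#' @param p a [model_params()] object.
#' @return A list of 13 channels in [build_channels()] format.
#' @export
predator_variant_channels <- function(p) {
  base <- build_channels(p)
  keep <- !vapply(base, function(ch)
    ch$name %in% c("parasitism", "enemy_recruitment"), logical(1))
  ch <- function(name, propensity, ...) {
    change <- c(C = 0, P = 0, W = 0, E = 0, N = 0)
    repl <- c(...)
    change[names(repl)] <- repl
    list(name = name, propensity = propensity, change = change)
  }
  c(base[keep],
    list(ch("predation_adults",
            function(state, p, rates)
              p$a2 * state[["P"]] * state[["W"]] /
                (p$b2 + state[["P"]] + state[["N"]]),
            P = -1),
         ch("predation_nymphs",
            function(state, p, rates)
              p$a2 * state[["N"]] * state[["W"]] /
                (p$b2 + state[["P"]] + state[["N"]]),
            N = -1),
         ch("predator_recruitment",
            function(state, p, rates)
              p$c2 * p$a2 * (state[["P"]] + state[["N"]]) * state[["W"]] /
                (p$b2 + state[["P"]] + state[["N"]]),
            W = +1)))
}

# full-year crop integral of a daily trajectory
.year_yield <- function(traj) crop_integral(traj)

#' Slow-release semiochemical experiment
#'
#' Treated runs each draw their own release duration from N(mean, sd)
#' (truncated at one day) with daily level `dosage/duration`, applied from
#' `start_day`; control runs are untreated.  Both arms use per-run seeds
#' derived from the master seed.  Reports the Spearman rank correlation
#' between duration and full-year tea yield (crop integral) among treated
#' runs, and a Mann-Whitney test of treated versus control yields.
#'
#' @inheritParams run_ensemble
#' @param start_day first day of application.
#' @param mode `"attractant"` or `"repellent"`.
#' @param duration_mean,duration_sd release-duration distribution (days).
#' @param dosage total dosage (units).
#' @param efficacy an [efficacy_params()] object.
#' @return list of class `release_experiment`: `treated` (data.frame run,
#'   duration, yield, post_yield), `control` (data.frame run, yield,
#'   post_yield), `correlation` (Spearman test), `location_test`
#'   (Mann-Whitney), medians.
#' @export
run_release_experiment <- function(p, temps, start_day, n_runs = 200,
                                   mode = c("attractant", "repellent"),
                                   master_seed = 1L, tau = 0.05,
                                   duration_mean = 60, duration_sd = 20,
                                   dosage = 720,
                                   efficacy = efficacy_params(lam0 = p$lam),
                                   noise_scale = p$thermal$variation_cv) {
  mode <- match.arg(mode)
  n_days <- nrow(temps)
  if (start_day < 1 || start_day >= n_days) stop("`start_day` outside year")
  set.seed(master_seed)
  durations <- sample_duration(n_runs, duration_mean, duration_sd)
  seeds_t <- sample.int(.Machine$integer.max - 1L, n_runs)
  seeds_c <- sample.int(.Machine$integer.max - 1L, n_runs)
  days_left <- n_days - start_day
  one <- function(seed, schedule) {
    tr <- simulate_stochastic(p, temps, tau = tau, seed = seed,
                              noise_scale = noise_scale, schedule = schedule)
    c(yield = .year_yield(tr),
      post = crop_integral(tr, start_day, n_days) / days_left)
  }
  treated <- t(vapply(seq_len(n_runs), function(i)
    one(seeds_t[i], release_schedule(start_day, durations[i], dosage, mode,
                                     efficacy)),
    numeric(2)))
  control <- t(vapply(seeds_c, one, numeric(2), schedule = NULL))
  cor_test <- suppressWarnings(
    cor.test(durations, treated[, "yield"], method = "spearman"))
  loc_test <- suppressWarnings(
    wilcox.test(treated[, "yield"], control[, "yield"],
                alternative = "greater"))
  structure(list(
    treated = data.frame(run = seq_len(n_runs), duration = durations,
                         yield = treated[, "yield"],
                         post_yield = treated[, "post"]),
    control = data.frame(run = seq_len(n_runs), yield = control[, "yield"],
                         post_yield = control[, "post"]),
    mode = mode, start_day = start_day,
    correlation = cor_test, location_test = loc_test,
    median_treated = median(treated[, "yield"]),
    median_control = median(control[, "yield"])),
    class = "release_experiment")
}

#' @export
print.release_experiment <- function(x, ...) {
  cat(sprintf("<release_experiment> %s from day %d, %d runs/arm\n",
              x$mode, x$start_day, nrow(x$treated)))
  cat(sprintf("  median yield treated %.4g vs control %.4g (Mann-Whitney p = %.3g)\n",
              x$median_treated, x$median_control, x$location_test$p.value))
  cat(sprintf("  duration-yield Spearman rho = %.3f (p = %.3g)\n",
              x$correlation$estimate, x$correlation$p.value))
  invisible(x)
}

#' Scan semiochemical start days for the optimal application time
#'
#' For each start day, runs treated stochastic simulations (duration drawn
#' per run, fixed dosage) and computes the average daily tea yield after
#' application: the crop integral from the start day to the end of the year
#' divided by the days remaining.  Returns the per-start-day median of this
#' metric and the start day maximizing it.
#'
#' @inheritParams run_release_experiment
#' @param start_days vector of candidate start days.
#' @param n_runs runs per start day.
#' @return list of class `start_scan`: `summary` (data.frame start_day,
#'   median_post_yield), `best_start`, and the per-run `detail`.
#' @export
optimal_start_scan <- function(p, temps, start_days = seq(30, 130, 10),
                               n_runs = 200,
                               mode = c("attractant", "repellent"),
                               master_seed = 1L, tau = 0.05,
                               duration_mean = 60, duration_sd = 20,
                               dosage = 720,
                               efficacy = efficacy_params(lam0 = p$lam),
                               noise_scale = p$thermal$variation_cv) {
  mode <- match.arg(mode)
  detail <- vector("list", length(start_days))
  med <- numeric(length(start_days))
  for (k in seq_along(start_days)) {
    ex <- run_release_experiment(p, temps, start_days[k], n_runs = n_runs,
                                 mode = mode,
                                 master_seed = master_seed + k - 1L,
                                 tau = tau, duration_mean = duration_mean,
                                 duration_sd = duration_sd, dosage = dosage,
                                 efficacy = efficacy,
                                 noise_scale = noise_scale)
    med[k] <- median(ex$treated$post_yield)
    detail[[k]] <- cbind(start_day = start_days[k], ex$treated)
  }
  structure(list(summary = data.frame(start_day = start_days,
                                      median_post_yield = med),
                 best_start = start_days[which.max(med)],
                 detail = do.call(rbind, detail), mode = mode),
            class = "start_scan")
}

#' @export
print.start_scan <- function(x, ...) {
  cat(sprintf("<start_scan> %s mode, %d start days\n", x$mode,
              nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  cat("best start day:", x$best_start, "\n")
  invisible(x)
}

#' Matched-seed comparison of parasitoid and predator biocontrol
#'
#' Runs two ensembles with identical per-run seeds and run-level thermal
#' factors, one with the egg-parasitoid model and one with the predator
#' variant, and summarizes tea yield (full-year crop integral), the annual
#' maximum of the pest complex (P + N), and the egg integral per run.
#'
#' @inheritParams run_ensemble
#' @return list of class `enemy_comparison` with per-run data.frame and the
#'   medians per model.
#' @export
compare_enemy_models <- function(p, temps, n_runs = 200, tau = 0.05,
                                 master_seed = 1L,
                                 noise_scale = p$thermal$variation_cv) {
  stats_of <- function(variant) {
    ens <- run_ensemble(p, temps, n_runs, tau = tau,
                        master_seed = master_seed,
                        noise_scale = noise_scale, variant = variant)
    n_days <- dim(ens$states)[1] - 1
    t(vapply(seq_len(n_runs), function(i) {
      tr <- ensemble_run(ens, i)
      c(yield = .year_yield(tr),
        max_pest = max(tr$P + tr$N),
        egg_integral = trapz(tr$time, tr$E))
    }, numeric(3)))
  }
  par_stats <- stats_of("parasitoid")
  pred_stats <- stats_of("predator")
  df <- data.frame(run = seq_len(n_runs),
                   yield_parasitoid = par_stats[, "yield"],
                   yield_predator = pred_stats[, "yield"],
                   max_pest_parasitoid = par_stats[, "max_pest"],
                   max_pest_predator = pred_stats[, "max_pest"],
                   egg_parasitoid = par_stats[, "egg_integral"],
                   egg_predator = pred_stats[, "egg_integral"])
  structure(list(per_run = df,
                 medians = vapply(df[-1], median, numeric(1))),
            class = "enemy_comparison")
}

#' @export
print.enemy_comparison <- function(x, ...) {
  cat("<enemy_comparison> medians over", nrow(x$per_run), "matched runs\n")
  print(round(x$medians, 3))
  invisible(x)
}
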