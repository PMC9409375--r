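#' Model parameter set
#'
#' All rate constants of the tritrophic tea crop (C) - leafhopper (adults P,
#' eggs E, nymphs N) - natural enemy (W) system, plus the nested thermal
#' constants.  Crop growth is logistic with harvest; adults and nymphs feed
#' on the crop through a Holling type II response; enemies parasitize eggs
#' through a second Holling type II response and are recruited both by
#' parasitism and by attraction to herbivore-induced plant volatiles
#' (the `lam` term, proportional to the feeding flux).
#'
#' Two reference parameterizations (presets) are provided; both respect the
#' field anchors (`lam = 0.3`; `r` inside the scanned range 4-12 with
#' default 8; `a2` inside 0.4-2 with default 0.8; `h < r`):
#'
#' * `"cycle"` (the default): calibrated so that the autonomous system sits
#'   on a stable limit cycle, with the cycle shrinking as the parasitism
#'   rate `a2` increases (a supercritical oscillation collapse inside the
#'   0.4-2 range) and growing with the crop growth rate `r`.  This is the
#'   parameterization for limit-cycle, bifurcation and sensitivity
#'   analyses.  Its enemy pool turns over quickly (`delta` about 0.7/day,
#'   enemies respond to the current pest density) and its insect rates
#'   describe a fast-turnover reference pest.
#' * `"seasonal"`: calibrated for temperature-forced simulations, producing
#'   two annual leafhopper outbreaks (late spring and autumn) separated by
#'   a mid-summer egg trough under the Anqing-like climate.  Its enemy
#'   pool accumulates and decays slowly (`delta` about 0.08/day), which is
#'   what lets the enemies overshoot after the spring outbreak and release
#'   the pest in late summer.  Populations are scaled up (`K = 30000`) so
#'   that demographic noise is moderate and the crop never strays near
#'   extinction in integer-count simulations.
#'
#' A single parameter set cannot do both jobs in this model: the
#' volatile-mediated attraction term ties enemy recruitment to the feeding
#' flux, so slowly decaying enemy pools (needed for the seasonal
#' double outbreak) hold a standing enemy population that damps the
#' autonomous cycle, while fast-decaying pools (needed for the sustained
#' cycle) cannot accumulate enough to arrest the seasonal outbreak.  The
#' methods vignette discusses this trade-off in detail.
#'
#' @param preset `"cycle"` or `"seasonal"` (see Details).
#' @param r intrinsic tea growth rate (per day).
#' @param K environmental carrying capacity (crop units).
#' @param a1 leafhopper feeding rate on the crop (per day).
#' @param a2 parasitism rate on eggs (per day).
#' @param b1 half-saturation of crop feeding (crop units).
#' @param b2 half-saturation of egg parasitism (egg units).
#' @param c1 conversion efficiency from adult feeding to eggs laid.
#' @param c2 conversion efficiency from parasitized eggs to enemies.
#' @param h harvest/death rate of the crop (per day, < `r`).
#' @param mu adult leafhopper death rate (per day).
#' @param delta enemy dispersal rate (per day).
#' @param lam volatile-mediated enemy attraction rate (dimensionless).
#' @param omega1 egg-to-nymph conversion rate (per day).
#' @param omega2 nymph-to-adult conversion rate (per day; nymph and
#'   pre-oviposition stages combined).
#' @param thermal a [thermal_params()] object.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params()
#' traj <- integrate_model(p, t_end = 400)
#' cycle_metrics(traj, transient = 200)
model_params <- function(preset = c("cycle", "seasonal"),
                         r = NULL, K = NULL, a1 = NULL, a2 = NULL,
                         b1 = NULL, b2 = NULL, c1 = NULL, c2 = NULL,
                         h = NULL, mu = NULL, delta = NULL, lam = NULL,
                         omega1 = NULL, omega2 = NULL,
                         thermal = thermal_params()) {
  preset <- match.arg(preset)
  def <- switch(preset,
    cycle = list(r = 8, K = 1000, a1 = 1.34, a2 = 0.8, b1 = 340,
                 b2 = 280, c1 = 1.78, c2 = 0.415, h = 2.46, mu = 0.32,
                 delta = 0.72, lam = 0.3, omega1 = 0.243, omega2 = 0.199),
    seasonal = list(r = 8, K = 30000, a1 = 1.04, a2 = 0.8, b1 = 40200,
                    b2 = 36000, c1 = 2.25, c2 = 0.62, h = 1.31,
                    mu = 1 / stage_duration(thermal$T0, "adult_lifespan",
                                            thermal),
                    delta = 0.08, lam = 0.3,
                    omega1 = 1 / stage_duration(thermal$T0, "egg_duration",
                                                thermal),
                    omega2 = 1 / stage_duration(thermal$T0,
                                                "nymph_preovip_duration",
                                                thermal)))
  given <- list(r = r, K = K, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1,
                c2 = c2, h = h, mu = mu, delta = delta, lam = lam,
                omega1 = omega1, omega2 = omega2)
  for (nm in names(given)) if (!is.null(given[[nm]])) def[[nm]] <- given[[nm]]
  p <- c(def, list(thermal = thermal, preset = preset))
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' Names of the rate parameters of the model
#'
#' The 14 scalar rate/capacity parameters subject to sensitivity analysis.
#' @return Character vector of length 14.
#' @export
rate_param_names <- function() {
  c("r", "K", "a1", "a2", "b1", "b2", "c1", "c2", "h",
    "mu", "delta", "lam", "omega1", "omega2")
}

validate_model_params <- function(p) {
  # a1, a2 and lam may be zero (decoupled-subsystem limits); the rest are
  # strictly positive
  zero_ok <- c("a1", "a2", "lam")
  for (nm in rate_param_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        (v == 0 && !nm %in% zero_ok))
      stop("parameter `", nm, "` must be a single positive finite number")
  }
  if (p$h >= p$r)
    stop("`h` must be smaller than `r` (h >= r collapses the crop)")
  if (!inherits(p$thermal, "thermal_params"))
    stop("`thermal` must be a thermal_params object")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  v <- unlist(x[rate_param_names()])
  cat(paste(sprintf("  %-7s = %g", names(v), v), collapse = "\n"), "\n")
  print(x$thermal)
  invisible(x)
}

#' Update parameters
#'
#' Returns a copy of `p` with the named scalar parameters replaced.
#' @param p a [model_params()] object.
#' @param ... named scalar replacements, e.g. `a2 = 1.5`.
#' @return A validated `model_params` object.
#' @export
set_params <- function(p, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), c(rate_param_names(), "thermal"))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(repl)] <- repl
  validate_model_params(p)
  structure(p, class = "model_params")
}

state_names <- c("C", "P", "W", "E", "N")

#' Default initial state
#'
#' Crop at half its carrying capacity, a small adult pest inoculum (one
#' twentieth of the carrying capacity by default, i.e. overwintering
#' adults), and no enemies, eggs or nymphs.
#'
#' @param p a [model_params()] object.
#' @param P0 initial adult leafhoppers; defaults to `K/20`.
#' @return Named numeric vector `c(C, P, W, E, N)`.
#' @export
default_init <- function(p = model_params(), P0 = NULL) {
  if (is.null(P0)) P0 <- p$K / 20
  c(C = p$K / 2, P = P0, W = 0, E = 0, N = 0)
}

#' Right-hand side of the autonomous tritrophic model
#'
#' Time derivatives of the five populations:
#' \deqn{dC/dt = rC(1 - C/K) - a_1 C (P+N)/(b_1+C) - hC}
#' \deqn{dP/dt = \omega_2 N - \mu P}
#' \deqn{dW/dt = c_2 a_2 E W/(b_2+E) + \lambda a_1 C (P+N)/(b_1+C) - \delta W}
#' \deqn{dE/dt = c_1 a_1 C P/(b_1+C) - \omega_1 E - a_2 E W/(b_2+E)}
#' \deqn{dN/dt = \omega_1 E - \omega_2 N}
#'
#' @param state named numeric vector `c(C, P, W, E, N)`, non-negative.
#' @param p a [model_params()] object.
#' @return Named numeric vector of derivatives.
#' @export
rhs_autonomous <- function(state, p) {
  if (any(state < 0)) stop("state must be non-negative")
  C <- state[["C"]]; P <- state[["P"]]; W <- state[["W"]]
  E <- state[["E"]]; N <- state[["N"]]
  feed <- p$a1 * C * (P + N) / (p$b1 + C)
  par  <- p$a2 * E * W / (p$b2 + E)
  c(C = p$r * C * (1 - C / p$K) - feed - p$h * C,
    P = p$omega2 * N - p$mu * P,
    W = p$c2 * par + p$lam * feed - p$delta * W,
    E = p$c1 * p$a1 * C * P / (p$b1 + C) - p$omega1 * E - par,
    N = p$omega1 * E - p$omega2 * N)
}

#' Right-hand side of the temperature-forced model
#'
#' As [rhs_autonomous()], but with the crop growth rate scaled by the
#' Gaussian temperature factor and the insect rates replaced by their
#' temperature-dependent values: \code{r} becomes \code{r*TF(T)}, \code{mu}
#' becomes \code{mu(T)}, \code{omega1} becomes \code{psi1*omega1(T)}, and
#' \code{omega2} becomes \code{psi2*omega2(T)}.  The threshold
#' indicators gate maturation in both the source and sink terms, so the
#' egg-to-nymph and nymph-to-adult fluxes are conserved between stages.
#'
#' @inheritParams rhs_autonomous
#' @param T temperature (degC).
#' @param rates optional precomputed output of [thermal_rates()]; computed
#'   (noise-free) from `T` when `NULL`.
#' @return Named numeric vector of derivatives.
#' @export
rhs_temperature <- function(state, p, T, rates = NULL) {
  if (any(state < 0)) stop("state must be non-negative")
  if (is.null(rates)) rates <- thermal_rates(T, p$thermal, noise_scale = 0)
  C <- state[["C"]]; P <- state[["P"]]; W <- state[["W"]]
  E <- state[["E"]]; N <- state[["N"]]
  rT <- p$r * temperature_factor(T, p$thermal)
  w1 <- rates$psi1 * rates$omega1
  w2 <- rates$psi2 * rates$omega2
  feed <- p$a1 * C * (P + N) / (p$b1 + C)
  par  <- p$a2 * E * W / (p$b2 + E)
  c(C = rT * C * (1 - C / p$K) - feed - p$h * C,
    P = w2 * N - rates$mu * P,
    W = p$c2 * par + p$lam * feed - p$delta * W,
    E = p$c1 * p$a1 * C * P / (p$b1 + C) - w1 * E - par,
    N = w1 * E - w2 * N)
}

#' Integrate the deterministic model
#'
#' Stiff-capable adaptive integration (deSolve's `lsoda`).  When a
#' temperature series is supplied the forcing is piecewise-constant within
#' each day (the data are daily averages) and the insect rates are the
#' noise-free thermal rates; otherwise the autonomous system is integrated.
#' States are clipped at zero; clipping events are counted in the
#' `clipped` attribute.
#'
#' @param p a [model_params()] object.
#' @param init initial state, default [default_init()].
#' @param t_end end time in days (ignored when `temperature` is given, in
#'   which case the series length sets the horizon).
#' @param temperature optional [temperature_series()].
#' @param dt_out output grid spacing (days).
#' @param rtol,atol solver tolerances.
#' @return A `tri_trajectory`: data.frame with columns `time, C, P, W, E, N`
#'   (and `temperature` when forced).
#' @export
integrate_model <- function(p, init = default_init(p), t_end = 1000,
                            temperature = NULL, dt_out = 0.2,
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(p, "model_params"))
  if (!is.null(temperature)) {
    stopifnot(inherits(temperature, "temperature_series"))
    t_end <- nrow(temperature)
    temps <- temperature$temp_c
  }
  if (t_end <= 0) stop("`t_end` must be > 0")
  y0 <- init[state_names]
  times <- seq(0, t_end, by = dt_out)
  clipped <- 0L
  if (is.null(temperature)) {
    f <- function(t, y, parms) {
      y <- pmax(y, 0)
      list(rhs_autonomous(y, p))
    }
  } else {
    tp <- p$thermal
    f <- function(t, y, parms) {
      y <- pmax(y, 0)
      d <- min(max(floor(t) + 1, 1), length(temps))
      list(rhs_temperature(y, p, temps[d]))
    }
  }
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", max(sol[, "time"], na.rm = TRUE))
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  for (nm in state_names) {
    neg <- out[[nm]] < 0
    if (any(neg)) {
      clipped <- clipped + sum(neg)
      out[[nm]][neg] <- 0
    }
  }
  if (!is.null(temperature))
    out$temperature <- temps[pmin(pmax(floor(out$time) + 1, 1), length(temps))]
  structure(out, class = c("tri_trajectory", "data.frame"), clipped = clipped)
}

#' Export a trajectory to CSV
#' @param traj a `tri_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Limit-cycle metrics of a trajectory
#'
#' After discarding an initial transient: the period is the mean spacing of
#' successive maxima of the crop variable C; the amplitude of each variable
#' is half its max-min range over the last full cycles; the system is
#' declared oscillating when the crop amplitude exceeds `floor_frac` times
#' the mean crop level; the crop integral is the trapezoidal integral of C
#' over the analysis window.
#'
#' @param traj a `tri_trajectory` from [integrate_model()].
#' @param transient days to discard before analysis.
#' @param floor_frac oscillation floor as a fraction of mean C (default 1%).
#' @return A list of class `cycle_metrics` with elements `oscillating`,
#'   `period`, `amplitude` (named vector over C,P,W,E,N), `crop_integral`,
#'   `n_peaks`.
#' @export
cycle_metrics <- function(traj, transient = 0, floor_frac = 0.01) {
  stopifnot(inherits(traj, "tri_trajectory"))
  keep <- traj$time >= transient
  if (sum(keep) < 10)
    stop("trajectory too short after discarding the transient")
  tt <- traj$time[keep]
  Cv <- traj$C[keep]
  pk <- local_maxima(Cv)
  # analysis window: between first and last detected C maxima when >= 2
  if (length(pk) >= 2) {
    win <- seq(pk[1], pk[length(pk)])
    period <- mean(diff(tt[pk]))
  } else {
    win <- seq_along(tt)
    period <- NA_real_
  }
  amp <- vapply(state_names, function(nm) {
    x <- traj[[nm]][keep][win]
    (max(x) - min(x)) / 2
  }, numeric(1))
  meanC <- mean(Cv[win])
  oscillating <- is.finite(period) && amp[["C"]] > floor_frac * max(meanC, .Machine$double.eps)
  # crop integral over the analysis window, evaluated as the mean crop level
  # over whole cycles (the peak-to-peak window) times the window length, so
  # that finite-difference sensitivities are not polluted by the phase of
  # the cycle at the window edges
  ci <- if (length(pk) >= 2)
    trapz(tt[win], Cv[win]) / (tt[win[length(win)]] - tt[win[1]]) *
      (tt[length(tt)] - tt[1])
  else trapz(tt, Cv)
  structure(list(oscillating = oscillating,
                 period = if (oscillating) period else NA_real_,
                 amplitude = amp, crop_integral = ci,
                 n_peaks = length(pk)),
            class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf("<cycle_metrics> oscillating, period %.2f d, C amplitude %.3g\n",
                x$period, x$amplitude[["C"]]))
  else cat("<cycle_metrics> not oscillating\n")
  cat(sprintf("  crop integral %.4g crop*days over analysis window\n",
              x$crop_integral))
  invisible(x)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least two points")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Crop integral (tea yield proxy) over a time window
#'
#' Trapezoidal integral of the crop variable C over `[t_start, t_end]`.
#'
#' @param traj a `tri_trajectory`.
#' @param t_start,t_end window bounds (days), inside the trajectory span.
#' @return Integral in crop x days.
#' @export
crop_integral <- function(traj, t_start = min(traj$time),
                          t_end = max(traj$time)) {
  if (t_end <= t_start) stop("empty integration window")
  if (t_start < min(traj$time) - 1e-9 || t_end > max(traj$time) + 1e-9)
    stop("window outside trajectory")
  keep <- traj$time >= t_start & traj$time <= t_end
  tt <- traj$time[keep]; Cv <- traj$C[keep]
  # add exact endpoints by interpolation if the grid does not include them
  if (length(tt) == 0 || tt[1] > t_start) {
    tt <- c(t_start, tt); Cv <- c(approx(traj$time, traj$C, t_start)$y, Cv)
  }
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end); Cv <- c(Cv, approx(traj$time, traj$C, t_end)$y)
  }
  trapz(tt, Cv)
}

#' Parameter scan for a Hopf bifurcation
#'
#' Integrates the autonomous model at each value of one parameter, extracts
#' [cycle_metrics()], and locates the bifurcation between the last
#' non-oscillating and the first oscillating value (in the direction of
#' onset).  A supercritical Hopf is diagnosed by the square of the crop
#' amplitude growing approximately linearly with the distance from the
#' critical value near onset (linear fit through the oscillating points
#' nearest the transition).
#'
#' @param p baseline [model_params()].
#' @param param_name one of [rate_param_names()].
#' @param values ordered numeric vector of parameter values.
#' @param t_end,transient integration horizon and discarded transient (days).
#' @param n_fit number of near-onset oscillating points in the linearity fit.
#' @param ... passed to [cycle_metrics()].
#' @return A list of class `hopf_scan` with per-value `metrics`, `amplitude`
#'   and `oscillating` vectors, `critical_value` (NA when no transition is
#'   inside the range), `supercritical` flag and `r_squared` of the
#'   amplitude-squared fit.
#' @export
hopf_scan <- function(p, param_name, values, t_end = 3000, transient = 1500,
                      n_fit = 5, ...) {
  stopifnot(param_name %in% rate_param_names())
  if (is.unsorted(values) && is.unsorted(rev(values)))
    stop("`values` must be ordered")
  metrics <- lapply(values, function(v) {
    pv <- p
    pv[[param_name]] <- v
    validate_model_params(pv)
    traj <- integrate_model(pv, t_end = t_end)
    cycle_metrics(traj, transient = transient, ...)
  })
  osc <- vapply(metrics, `[[`, logical(1), "oscillating")
  amp <- vapply(metrics, function(m) m$amplitude[["C"]], numeric(1))
  critical <- NA_real_
  supercritical <- NA
  r2 <- NA_real_
  tr <- which(diff(osc) != 0)
  if (length(tr)) {
    i <- tr[1]  # transition between values[i] and values[i+1]
    critical <- mean(values[c(i, i + 1)])
    # oscillating points nearest the transition
    osc_idx <- which(osc)
    ord <- osc_idx[order(abs(values[osc_idx] - critical))]
    use <- sort(head(ord, n_fit))
    if (length(use) >= 3) {
      x <- abs(values[use] - critical)
      fit <- lm(amp[use]^2 ~ x)
      r2 <- summary(fit)$r.squared
      supercritical <- coef(fit)[["x"]] > 0 && r2 > 0.9
    }
  }
  structure(list(param = param_name, values = values, metrics = metrics,
                 amplitude = amp, oscillating = osc,
                 critical_value = critical, supercritical = supercritical,
                 r_squared = r2),
            class = "hopf_scan")
}

#' @export
print.hopf_scan <- function(x, ...) {
  cat(sprintf("<hopf_scan> %s over [%g, %g]: %d/%d oscillating\n",
              x$param, min(x$values), max(x$values),
              sum(x$oscillating), length(x$values)))
  if (is.finite(x$critical_value))
    cat(sprintf("  bifurcation near %s = %.4g; supercritical: %s (R^2 = %.3f)\n",
                x$param, x$critical_value, x$supercritical, x$r_squared))
  else cat("  no oscillation transition found in range\n")
  invisible(x)
}
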