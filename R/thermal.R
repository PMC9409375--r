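#' Thermal parameter set
#'
#' Bundles every temperature-response constant of the model: the Gaussian
#' crop-growth optimum, the developmental threshold temperatures of the egg
#' and nymph (plus pre-oviposition) stages, the base temperature used for
#' effective accumulated temperature (EAT), and the Arrhenius coefficients
#' mapping temperature to mean stage durations.
#'
#' Stage durations follow the Arrhenius form `a * exp(-b * T)` (days), so the
#' corresponding first-order rate is the reciprocal duration.  The shipped
#' coefficients are a reference calibration: egg development lasts about 10
#' days near 24 degC and doubles near 15 degC; the combined nymph plus
#' pre-oviposition stage lasts about 13 days near 24 degC (ten to twelve
#' nymphal days plus a short pre-oviposition period) with the same
#' relative temperature response; mean adult lifespan is about 20 days near
#' 24 degC, lengthening strongly in the cold (about seven weeks near
#' 15 degC and several months at winter temperatures, consistent with
#' adult overwintering).  The five nymphal instars are not resolved.
#'
#' @param T0 optimal tea-growth temperature (degC).
#' @param beta Gaussian width of the crop growth response (degC, > 0).
#' @param Ttheta1 egg developmental threshold temperature (degC).
#' @param Ttheta2 nymph developmental threshold temperature (degC).
#' @param B base temperature for effective accumulated temperature (degC).
#' @param arrhenius named list with elements `egg_duration`,
#'   `nymph_preovip_duration` and `adult_lifespan`, each a numeric vector
#'   `c(a = days, b = per_degC)` with `a > 0`, `b >= 0`.
#' @param variation_cv relative dispersion of the run-level multiplicative
#'   noise applied to the adult death and stage-transition rates
#'   (dimensionless, >= 0).
#'
#' @return An object of class `thermal_params`.
#' @export
#' @examples
#' tp <- thermal_params()
#' temperature_factor(23, tp)   # 1 at the optimum
#' stage_duration(20, "egg_duration", tp)
thermal_params <- function(T0 = 23, beta = 20, Ttheta1 = 11, Ttheta2 = 8,
                           B = 7.8,
                           arrhenius = list(
                             egg_duration           = c(a = 63.52, b = 0.07702),
                             nymph_preovip_duration = c(a = 82.58, b = 0.07702),
                             adult_lifespan         = c(a = 220.0, b = 0.10000)),
                           variation_cv = 0.10) {
  stopifnot(is.numeric(T0), length(T0) == 1L, is.finite(T0))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive finite number")
  if (!is.numeric(variation_cv) || variation_cv < 0)
    stop("`variation_cv` must be >= 0")
  needed <- c("egg_duration", "nymph_preovip_duration", "adult_lifespan")
  if (!is.list(arrhenius) || !all(needed %in% names(arrhenius)))
    stop("`arrhenius` must contain coefficients for: ",
         paste(needed, collapse = ", "))
  for (nm in needed) {
    co <- arrhenius[[nm]]
    if (!is.numeric(co) || !all(c("a", "b") %in% names(co)))
      stop("arrhenius$", nm, " must be c(a = , b = )")
    if (co[["a"]] <= 0) stop("arrhenius$", nm, ": `a` must be > 0")
    if (co[["b"]] < 0) stop("arrhenius$", nm, ": `b` must be >= 0")
  }
  structure(list(T0 = T0, beta = beta, Ttheta1 = Ttheta1, Ttheta2 = Ttheta2,
                 B = B, arrhenius = arrhenius[needed],
                 variation_cv = variation_cv),
            class = "thermal_params")
}

#' @export
print.thermal_params <- function(x, ...) {
  cat("<thermal_params>\n")
  cat(sprintf("  T0 = %g degC, beta = %g degC\n", x$T0, x$beta))
  cat(sprintf("  thresholds: egg %g degC, nymph %g degC; EAT base B = %g degC\n",
              x$Ttheta1, x$Ttheta2, x$B))
  for (nm in names(x$arrhenius))
    cat(sprintf("  %s: %g * exp(-%g T) days\n", nm,
                x$arrhenius[[nm]][["a"]], x$arrhenius[[nm]][["b"]]))
  cat(sprintf("  variation_cv = %g\n", x$variation_cv))
  invisible(x)
}

#' Temperature factor for crop growth
#'
#' Gaussian response `exp(-((T - T0)/beta)^2)`: equals 1 at the thermal
#' optimum `T0` and decays symmetrically away from it.
#'
#' @param T temperature (degC); vectorized.
#' @param tp a [thermal_params()] object.
#' @return Dimensionless factor in (0, 1].
#' @export
temperature_factor <- function(T, tp = thermal_params()) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("`T` must be finite numeric")
  exp(-((T - tp$T0) / tp$beta)^2)
}

#' Temperature-dependent crop growth rate
#'
#' Scales the intrinsic growth rate by the Gaussian temperature factor:
#' `r(T) = r * TF(T)`.
#'
#' @param T temperature (degC).
#' @param r intrinsic growth rate (per day, >= 0).
#' @inheritParams temperature_factor
#' @return Growth rate per day, never exceeding `r`.
#' @export
growth_rate_at <- function(T, r, tp = thermal_params()) {
  if (!is.numeric(r) || any(r < 0)) stop("`r` must be >= 0")
  r * temperature_factor(T, tp)
}

#' Mean stage duration at a given temperature
#'
#' Arrhenius relation `a * exp(-b * T)` for the mean duration (days) of a
#' developmental stage; non-increasing in temperature for `b > 0`.
#'
#' @param T temperature (degC); vectorized.
#' @param stage one of `"egg_duration"`, `"nymph_preovip_duration"`,
#'   `"adult_lifespan"`.
#' @inheritParams temperature_factor
#' @return Duration in days (strictly positive).
#' @export
stage_duration <- function(T, stage, tp = thermal_params()) {
  if (!stage %in% names(tp$arrhenius))
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(names(tp$arrhenius), collapse = ", "))
  co <- tp$arrhenius[[stage]]
  co[["a"]] * exp(-co[["b"]] * T)
}

#' Convert between a mean duration and a first-order rate
#'
#' Reciprocal relation between the mean lifetime/duration of a stage and its
#' exponential decay/conversion rate.  The function is an involution:
#' applying it twice returns the input.
#'
#' @param tau duration in days (or a rate per day), strictly positive.
#' @return The reciprocal (per day, or days).
#' @export
rate_from_duration <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop("`tau` must be finite and > 0")
  1 / tau
}

#' Developmental threshold indicator
#'
#' Step function gating stage transitions: development proceeds (1) when the
#' temperature is at or above the threshold, and is frozen (0) below it.
#' The boundary is included.
#'
#' @param T temperature (degC); vectorized.
#' @param threshold developmental threshold temperature (degC).
#' @return 0 or 1 (numeric, vectorized over `T`).
#' @export
stage_indicator <- function(T, threshold) {
  as.numeric(T >= threshold)
}

#' Draw run-level thermal noise factors
#'
#' One multiplicative factor per rate (adult death `mu`, egg-to-nymph
#' `omega1`, nymph-to-adult `omega2`), drawn from a normal distribution with
#' mean 1 and standard deviation `noise_scale`, truncated to \[0.5, 1.5\]
#' (resampled), so factors are strictly positive.  Each stochastic run draws
#' its factors once and keeps them for the whole run, modelling run-level
#' trait heterogeneity.
#'
#' @param noise_scale relative dispersion (>= 0); 0 returns exact ones.
#' @param n number of independent factor triplets.
#' @return An `n x 3` matrix with columns `mu`, `omega1`, `omega2`.
#' @export
draw_thermal_factors <- function(noise_scale = 0.10, n = 1L) {
  if (!is.numeric(noise_scale) || noise_scale < 0)
    stop("`noise_scale` must be >= 0")
  m <- matrix(1, nrow = n, ncol = 3,
              dimnames = list(NULL, c("mu", "omega1", "omega2")))
  if (noise_scale > 0) {
    for (j in 1:3) {
      x <- rnorm(n, 1, noise_scale)
      bad <- x < 0.5 | x > 1.5
      while (any(bad)) {
        x[bad] <- rnorm(sum(bad), 1, noise_scale)
        bad <- x < 0.5 | x > 1.5
      }
      m[, j] <- x
    }
  }
  m
}

#' Temperature-dependent stage rates and threshold indicators
#'
#' Evaluates, at temperature `T`, the adult death rate `mu`, the egg-to-nymph
#' conversion rate `omega1` and the (combined nymph + pre-oviposition)
#' nymph-to-adult conversion rate `omega2` as reciprocal Arrhenius durations,
#' each multiplied by an independent mean-1 random factor with relative
#' dispersion `noise_scale` (0 disables the noise), together with the
#' developmental threshold indicators `psi1` (eggs) and `psi2` (nymphs).
#'
#' @param T temperature (degC), scalar.
#' @inheritParams temperature_factor
#' @param noise_scale relative dispersion of the multiplicative factors;
#'   ignored when `factors` is supplied.
#' @param factors optional named numeric vector `c(mu=, omega1=, omega2=)` of
#'   pre-drawn multiplicative factors (used to hold run-level factors fixed
#'   across time steps).
#' @return A list with elements `mu`, `omega1`, `omega2` (per day) and
#'   `psi1`, `psi2` (0/1).
#' @export
thermal_rates <- function(T, tp = thermal_params(), noise_scale = 0,
                          factors = NULL) {
  if (is.null(factors)) {
    factors <- draw_thermal_factors(noise_scale, 1L)[1, ]
  } else {
    if (!all(c("mu", "omega1", "omega2") %in% names(factors)))
      stop("`factors` must be named c(mu=, omega1=, omega2=)")
    if (any(factors <= 0)) stop("`factors` must be positive")
  }
  list(mu     = factors[["mu"]] /
         stage_duration(T, "adult_lifespan", tp),
       omega1 = factors[["omega1"]] /
         stage_duration(T, "egg_duration", tp),
       omega2 = factors[["omega2"]] /
         stage_duration(T, "nymph_preovip_duration", tp),
       psi1   = stage_indicator(T, tp$Ttheta1),
       psi2   = stage_indicator(T, tp$Ttheta2))
}
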