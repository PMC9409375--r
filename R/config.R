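#' Default run configuration
#'
#' The reference configuration: model and thermal parameters, initial
#' state, climate source, stochastic engine settings, and analysis knobs.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  tp <- thermal_params()
  p <- model_params("seasonal")
  structure(list(
    thermal = list(T0 = tp$T0, beta = tp$beta, Ttheta1 = tp$Ttheta1,
                   Ttheta2 = tp$Ttheta2, B = tp$B,
                   arrhenius = lapply(tp$arrhenius, as.list),
                   variation_cv = tp$variation_cv),
    params = p[rate_param_names()],
    init = as.list(default_init(p)),
    climate = list(source = "synthetic", preset = "anqing2020-like",
                   year_length = 366L, mean_c = 17, amplitude_c = 12,
                   peak_day = 205, noise_sd_c = 2, file = NULL,
                   units = "celsius"),
    engine = list(tau = 0.05, n_runs = 500L, master_seed = 1L),
    analysis = list(smooth_window = 7L, min_separation = 60L,
                    prominence_frac = 0.2, season_split = 200L,
                    eat_n = c(10L, 50L, 80L, 100L, 120L))),
    class = "run_config")
}

.merge_checked <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", key, " must be a mapping")
      base[[nm]] <- .merge_checked(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()] (so an empty file
#' yields the full defaults), rejects unknown keys, and validates all
#' parameter invariants by constructing the corresponding objects.
#'
#' @param path path to a YAML configuration file, or `NULL` for defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- .merge_checked(cfg, user)
    class(cfg) <- "run_config"
  }
  config_params(cfg)  # constructs and validates; errors name the key
  cfg
}

#' Write a configuration to YAML
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Model parameters from a configuration
#' @param cfg a `run_config`.
#' @return A [model_params()] object.
#' @export
config_params <- function(cfg) {
  th <- cfg$thermal
  tp <- thermal_params(T0 = th$T0, beta = th$beta, Ttheta1 = th$Ttheta1,
                       Ttheta2 = th$Ttheta2, B = th$B,
                       arrhenius = lapply(th$arrhenius, unlist),
                       variation_cv = th$variation_cv)
  do.call(model_params, c(cfg$params, list(thermal = tp)))
}

#' Initial state from a configuration
#' @param cfg a `run_config`.
#' @return Named numeric state vector.
#' @export
config_init <- function(cfg) {
  init <- unlist(cfg$init)[state_names]
  if (any(is.na(init)) || any(init < 0))
    stop("config `init` must give non-negative C, P, W, E, N")
  init
}

#' Temperature series from a configuration
#' @param cfg a `run_config`.
#' @param seed seed for the synthetic generator.
#' @return A [temperature_series()].
#' @export
config_climate <- function(cfg, seed = NULL) {
  cl <- cfg$climate
  if (identical(cl$source, "file")) {
    if (is.null(cl$file)) stop("config climate.source is 'file' but no file given")
    read_temperature_csv(cl$file, units = cl$units)
  } else {
    synthetic_temperature(year_length = cl$year_length, mean_c = cl$mean_c,
                          amplitude_c = cl$amplitude_c,
                          peak_day = cl$peak_day,
                          noise_sd_c = cl$noise_sd_c, seed = seed)
  }
}
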