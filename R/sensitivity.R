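#' Oscillation features of the model at a parameter set
#'
#' Integrates the autonomous system and extracts the three scalar features
#' used by the sensitivity analysis: the oscillation period, the crop
#' amplitude, and the crop integral (tea yield proxy) over the analysis
#' window.
#'
#' @param p a [model_params()] object.
#' @param t_end,transient,dt_out integration settings shared by all
#'   sensitivity evaluations.
#' @return list with `period`, `amplitude`, `integral`, `oscillating`.
#' @export
cycle_features <- function(p, t_end = 2500, transient = 1200, dt_out = 0.5) {
  traj <- integrate_model(p, t_end = t_end, dt_out = dt_out)
  m <- cycle_metrics(traj, transient = transient)
  list(period = m$period, amplitude = m$amplitude[["C"]],
       integral = m$crop_integral, oscillating = m$oscillating)
}

#' Local sensitivity coefficient of one feature to one parameter
#'
#' Forward finite difference with a +1% (default) parameter perturbation:
#' `S = ((I_p - I_d)/I_d) / rel_step`, both features computed with
#' identical solver settings.  For the `period` and `amplitude` features
#' the unperturbed system must oscillate.
#'
#' @param p a [model_params()] object.
#' @param param_name one of [rate_param_names()].
#' @param feature `"period"`, `"amplitude"` or `"integral"`.
#' @param rel_step relative perturbation (default 0.01 = +1%).
#' @param default_features optional precomputed [cycle_features()] of `p`
#'   (reused by [sensitivity_table()]).
#' @param ... passed to [cycle_features()].
#' @return list of class `sensitivity_result` with `parameter`, `feature`,
#'   `S`.
#' @export
local_sensitivity <- function(p, param_name, feature = c("period",
                                                         "amplitude",
                                                         "integral"),
                              rel_step = 0.01, default_features = NULL,
                              ...) {
  feature <- match.arg(feature)
  stopifnot(param_name %in% rate_param_names())
  if (is.null(default_features)) default_features <- cycle_features(p, ...)
  if (feature %in% c("period", "amplitude") && !default_features$oscillating)
    stop("system does not oscillate at the default parameters; ",
         feature, " sensitivity undefined")
  pv <- p
  pv[[param_name]] <- p[[param_name]] * (1 + rel_step)
  fp <- cycle_features(pv, ...)
  Id <- default_features[[feature]]
  Ip <- fp[[feature]]
  if (feature == "period" && (is.na(Ip) || is.na(Id)))
    stop("period undefined in perturbed or default system")
  structure(list(parameter = param_name, feature = feature,
                 S = ((Ip - Id) / Id) / rel_step),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("S(%s, %s) = %.4f\n", x$feature, x$parameter, x$S))
  invisible(x)
}

#' Full local sensitivity table
#'
#' Sensitivity of period, crop amplitude, and crop integral to each of the
#' 14 rate parameters (42 coefficients), sharing one default evaluation
#' and one perturbed integration per parameter.
#'
#' @inheritParams local_sensitivity
#' @param features features to include.
#' @return data.frame with columns `parameter`, `feature`, `S`.
#' @export
sensitivity_table <- function(p, rel_step = 0.01,
                              features = c("period", "amplitude",
                                           "integral"), ...) {
  fd <- cycle_features(p, ...)
  if (!fd$oscillating)
    stop("system does not oscillate at the default parameters")
  rows <- list()
  for (pn in rate_param_names()) {
    pv <- p
    pv[[pn]] <- p[[pn]] * (1 + rel_step)
    fp <- cycle_features(pv, ...)
    for (ft in features) {
      rows[[length(rows) + 1]] <-
        data.frame(parameter = pn, feature = ft,
                   S = ((fp[[ft]] - fd[[ft]]) / fd[[ft]]) / rel_step)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a sensitivity table to CSV
#' @param tab data.frame from [sensitivity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
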