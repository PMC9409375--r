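#' Centered moving average with shrinking edge windows
#' @noRd
.moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Topographic prominence of local maxima
#' @noRd
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    lmin <- x[i]; j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) { lmin <- min(lmin, x[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(x[1:i])
    rmin <- x[i]; j <- i + 1L
    while (j <= length(x) && x[j] <= x[i]) { rmin <- min(rmin, x[j]); j <- j + 1L }
    if (j > length(x)) rmin <- min(x[i:length(x)])
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

# daily series of a trajectory variable on integer days 1..n
.daily_series <- function(traj, what) {
  days <- seq_len(floor(max(traj$time)))
  x <- if (identical(what, "PN")) traj$P + traj$N else traj[[what]]
  approx(traj$time, x, xout = days)$y
}

#' Detect the annual leafhopper outbreaks in a trajectory
#'
#' Operates on the 7-day centered moving average of the pest complex
#' (adults + nymphs).  Local maxima qualify as outbreaks when their
#' topographic prominence is at least `prominence_frac` of the smoothed
#' series maximum; qualifying peaks closer together than `min_separation`
#' days are pruned keeping the higher one.  The first outbreak is the
#' highest qualifying peak on or before `season_split`, the second the
#' highest after it; a missing peak is reported as `NA`, not an error.
#'
#' @param traj a `tri_trajectory` covering a full year.
#' @param smooth_window moving-average window (days).
#' @param min_separation minimum distance between peaks (days).
#' @param prominence_frac prominence threshold as a fraction of the series
#'   maximum.
#' @param season_split day of year separating the two outbreak seasons.
#' @return list with `first_peak_day` and `second_peak_day` (day of year or
#'   `NA`).
#' @export
detect_outbreaks <- function(traj, smooth_window = 7, min_separation = 60,
                             prominence_frac = 0.2, season_split = 200) {
  x <- .moving_average(.daily_series(traj, "PN"), smooth_window)
  n <- length(x)
  if (n < 30) stop("trajectory shorter than a month of days")
  cand <- local_maxima(x)
  res <- list(first_peak_day = NA_integer_, second_peak_day = NA_integer_)
  if (!length(cand) || max(x) <= 0) return(res)
  prom <- .peak_prominence(x, cand)
  cand <- cand[prom >= prominence_frac * max(x)]
  if (!length(cand)) return(res)
  # prune by separation, keeping higher peaks
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_separation))
      keep <- c(keep, i)
  }
  early <- keep[keep <= season_split]
  late <- keep[keep > season_split]
  if (length(early)) res$first_peak_day <- as.integer(early[which.max(x[early])])
  if (length(late)) res$second_peak_day <- as.integer(late[which.max(x[late])])
  res
}

#' Locate the mid-season egg trough
#'
#' Argmin of the 7-day smoothed egg series strictly between the two
#' outbreak days; ties resolve to the earliest day.
#'
#' @inheritParams detect_outbreaks
#' @param first_peak_day,second_peak_day outbreak days from
#'   [detect_outbreaks()]; both must be present.
#' @return Day of year of the egg trough.
#' @export
detect_egg_trough <- function(traj, first_peak_day, second_peak_day,
                              smooth_window = 7) {
  if (is.na(first_peak_day) || is.na(second_peak_day))
    stop("both outbreak days must be present to locate the egg trough")
  e <- .moving_average(.daily_series(traj, "E"), smooth_window)
  days <- seq_len(length(e))
  interior <- days > first_peak_day & days < second_peak_day
  if (!any(interior)) stop("no interior days between the outbreak peaks")
  di <- days[interior]
  di[which.min(e[interior])]
}

#' Outbreak and trough days for every run of an ensemble
#'
#' @param ensemble a `tri_ensemble` from [run_ensemble()].
#' @param ... passed to [detect_outbreaks()].
#' @return data.frame with columns `run`, `first`, `second`, `trough`
#'   (days of year; `NA` when absent).
#' @export
ensemble_outbreaks <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "tri_ensemble"))
  n_runs <- dim(ensemble$states)[3]
  out <- data.frame(run = seq_len(n_runs), first = NA_integer_,
                    second = NA_integer_, trough = NA_integer_)
  for (i in seq_len(n_runs)) {
    tr <- ensemble_run(ensemble, i)
    pk <- detect_outbreaks(tr, ...)
    out$first[i] <- pk$first_peak_day
    out$second[i] <- pk$second_peak_day
    if (!is.na(pk$first_peak_day) && !is.na(pk$second_peak_day))
      out$trough[i] <- detect_egg_trough(tr, pk$first_peak_day,
                                         pk$second_peak_day)
  }
  out
}

#' Distribution of an event day across an ensemble
#'
#' Median, 2.5-97.5 percentile interval, and a Gaussian kernel density
#' estimate (Silverman's bandwidth) of day-of-year event times.
#'
#' @param days numeric vector of event days (NAs dropped).
#' @param min_n minimum number of events required (default 100).
#' @return list with `n`, `median`, `ci` (length-2 vector) and `kde`
#'   (a [stats::density] object).
#' @export
event_distribution <- function(days, min_n = 100) {
  days <- days[!is.na(days)]
  if (length(days) < min_n)
    stop("only ", length(days), " events present; need >= ", min_n)
  list(n = length(days),
       median = median(days),
       ci = unname(quantile(days, c(0.025, 0.975))),
       kde = density(days, bw = "nrd0"))
}

#' Daily average effective accumulated temperature
#'
#' Mean of `(T_i - B)` over the `n` days ending at `day`, in degC.  Negative
#' daily terms are not floored.
#'
#' @param temps a [temperature_series()].
#' @param day day of year the record ends on (1-based).
#' @param n record duration in days (>= 1).
#' @param B base temperature (degC), default the EAT base of the default
#'   thermal parameters (7.8 degC).
#' @return Daily average EAT in degC.
#' @export
#' @examples
#' ts <- synthetic_anqing(seed = 1)
#' daily_avg_eat(ts, day = 150, n = 80)
daily_avg_eat <- function(temps, day, n, B = 7.8) {
  stopifnot(inherits(temps, "temperature_series"), n >= 1)
  if (day > nrow(temps)) stop("`day` beyond end of series")
  if (day - n + 1 < 1)
    stop("insufficient temperature history: need ", n, " days ending at day ",
         day)
  mean(temps$temp_c[(day - n + 1):day] - B)
}

#' EAT frequency analysis of outbreak days
#'
#' For every detected outbreak incidence in the ensemble, computes the daily
#' average EAT over each record duration in `n_values`, and tabulates the
#' normalized frequency of outbreak incidences per calendar day.
#' Incidences without enough temperature history for a given `n` are
#' dropped for that `n`.
#'
#' @param events data.frame from [ensemble_outbreaks()].
#' @param temps the [temperature_series()] the ensemble was driven with.
#' @param n_values record durations in days.
#' @param B base temperature (degC).
#' @return list of class `eat_frequency`: per `n`, a list with `eat`
#'   (data.frame day, eat, count, freq over outbreak incidences) and the
#'   record duration.
#' @export
outbreak_eat_frequency <- function(events, temps,
                                   n_values = c(10, 50, 80, 100, 120),
                                   B = 7.8) {
  days <- c(events$first, events$second)
  days <- days[!is.na(days)]
  if (!length(days)) stop("no outbreak incidences in the ensemble")
  out <- lapply(n_values, function(n) {
    usable <- days[days - n + 1 >= 1]
    if (!length(usable)) return(list(n = n, eat = NULL))
    tab <- table(usable)
    d <- as.integer(names(tab))
    eat <- vapply(d, function(dd) daily_avg_eat(temps, dd, n, B), numeric(1))
    list(n = n,
         eat = data.frame(day = d, eat = eat, count = as.integer(tab),
                          freq = as.integer(tab) / sum(tab)))
  })
  names(out) <- paste0("n", n_values)
  structure(out, class = "eat_frequency", B = B)
}

#' Weighted interquartile range of the EAT values for one record duration
#' @param ef an `eat_frequency` object.
#' @param n record duration to extract.
#' @return IQR of the outbreak-day EAT values (incidence-weighted).
#' @export
eat_iqr <- function(ef, n) {
  el <- ef[[paste0("n", n)]]
  if (is.null(el) || is.null(el$eat)) stop("no records for n = ", n)
  x <- rep(el$eat$eat, el$eat$count)
  IQR(x)
}
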