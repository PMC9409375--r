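#' Construct a temperature series object
#'
#' @param dates vector of `Date`s, one per consecutive calendar day.
#' @param temp_c daily average temperatures (degC), same length as `dates`.
#' @return A `temperature_series`: a data.frame with columns `date` and
#'   `temp_c`.
#' @export
temperature_series <- function(dates, temp_c) {
  dates <- as.Date(dates)
  if (length(dates) != length(temp_c))
    stop("`dates` and `temp_c` lengths differ")
  if (length(dates) < 1L) stop("empty temperature series")
  if (any(!is.finite(temp_c))) stop("temperatures must be finite")
  if (any(temp_c < -30 | temp_c > 50))
    stop("temperatures outside plausible range [-30, 50] degC")
  d <- as.integer(diff(dates))
  if (length(d) && any(d != 1L))
    stop("dates must be consecutive calendar days")
  structure(data.frame(date = dates, temp_c = as.numeric(temp_c)),
            class = c("temperature_series", "data.frame"))
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %d days: %s .. %s, %.1f to %.1f degC\n",
              nrow(x), format(x$date[1]), format(x$date[nrow(x)]),
              min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

#' Read a daily temperature CSV
#'
#' Expects a header with columns `date` (ISO dates) and `temperature`.
#' Fahrenheit values (e.g. NOAA GSOD extracts) are converted to Celsius as
#' `(F - 32) * 5/9`.  Gaps of up to 3 consecutive missing days are filled by
#' linear interpolation with a warning; longer gaps are an error.
#'
#' @param path path to the CSV file.
#' @param units `"celsius"` (default) or `"fahrenheit"`.
#' @return A [temperature_series()].
#' @export
read_temperature_csv <- function(path, units = c("celsius", "fahrenheit")) {
  units <- match.arg(units)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "temperature") %in% names(df)))
    stop("CSV must have columns `date` and `temperature`")
  dates <- as.Date(df$date)
  if (any(is.na(dates))) stop("unparseable dates in `date` column")
  o <- order(dates)
  dates <- dates[o]
  temp <- as.numeric(df$temperature)[o]
  if (anyDuplicated(dates)) stop("duplicated dates")
  full <- seq(dates[1], dates[length(dates)], by = "day")
  if (length(full) > length(dates)) {
    gaps <- diff(as.integer(dates)) - 1L
    if (any(gaps > 3L))
      stop("temperature series has a gap of ", max(gaps),
           " days (> 3); refusing to interpolate")
    warning("filling ", length(full) - length(dates),
            " missing day(s) by linear interpolation")
    temp <- approx(as.numeric(dates), temp, xout = as.numeric(full))$y
    dates <- full
  }
  if (units == "fahrenheit") temp <- (temp - 32) * 5 / 9
  temperature_series(dates, temp)
}

#' Synthetic annual temperature series
#'
#' Generates one year of daily average temperatures as a cosine annual cycle
#' plus Gaussian day-to-day noise, smoothed with a 3-day circular moving
#' average to mimic weather autocorrelation:
#' `T(d) = mean_c + amplitude_c * cos(2*pi*(d - peak_day)/year_length) + eps`.
#'
#' @param year_length 365 or 366 days.
#' @param mean_c annual mean temperature (degC).
#' @param amplitude_c seasonal half-range (degC, >= 0).
#' @param peak_day day of year of the summer maximum.
#' @param noise_sd_c standard deviation of daily noise (degC, >= 0).
#' @param seed optional integer seed for reproducibility.
#' @param start_date first calendar day (defaults to 2020-01-01, a leap year,
#'   when `year_length` is 366, else 2021-01-01).
#' @return A [temperature_series()].
#' @export
#' @examples
#' ts <- synthetic_temperature(seed = 1)
#' range(ts$temp_c)
synthetic_temperature <- function(year_length = 366, mean_c = 17,
                                  amplitude_c = 12, peak_day = 205,
                                  noise_sd_c = 2, seed = NULL,
                                  start_date = NULL) {
  if (!year_length %in% c(365L, 366L)) stop("`year_length` must be 365 or 366")
  if (amplitude_c < 0) stop("`amplitude_c` must be >= 0")
  if (noise_sd_c < 0) stop("`noise_sd_c` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- seq_len(year_length)
  temp <- mean_c + amplitude_c * cos(2 * pi * (d - peak_day) / year_length)
  if (noise_sd_c > 0) temp <- temp + rnorm(year_length, 0, noise_sd_c)
  # 3-day circular moving average keeps the annual mean exact
  temp <- as.numeric(stats::filter(temp, rep(1 / 3, 3), sides = 2,
                                   circular = TRUE))
  if (is.null(start_date))
    start_date <- if (year_length == 366L) as.Date("2020-01-01")
                  else as.Date("2021-01-01")
  temperature_series(seq(as.Date(start_date), by = "day",
                         length.out = year_length),
                     pmin(50, pmax(-30, temp)))
}

#' Anqing-like humid-subtropical climate preset
#'
#' One-year synthetic series calibrated to the climatology of Anqing
#' (Anhui, China): annual mean about 17 degC, seasonal amplitude about
#' 12 degC, summer peak in late July (day 205), daily noise SD 2 degC.
#' Winter means sit below the 8 degC nymph threshold, summer means above
#' 27 degC, and the spring warm-up between the developmental thresholds and
#' the crop optimum spans more than two months — the structure the annual
#' two-outbreak leafhopper phenology depends on.
#'
#' @param seed integer seed.
#' @param year_length 365 or 366 (default 366, a leap year).
#' @return A [temperature_series()].
#' @export
synthetic_anqing <- function(seed = NULL, year_length = 366) {
  synthetic_temperature(year_length = year_length, mean_c = 17,
                        amplitude_c = 12, peak_day = 205, noise_sd_c = 2,
                        seed = seed)
}

#' Write a temperature series to CSV
#'
#' @param ts a [temperature_series()].
#' @param path output path; columns `date,temperature` (degC).
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(ts, path) {
  stopifnot(inherits(ts, "temperature_series"))
  write.csv(data.frame(date = format(ts$date), temperature = ts$temp_c),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
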