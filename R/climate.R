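# Daily temperature input: CSV reader for observed series and a synthetic
# climatology generator for an Upper-Midwest growing season.

#' Climatology generator parameters
#'
#' A sinusoidal annual cycle with AR(1) daily weather noise, parameterised to
#' resemble the Upper Midwest (cold March, ~23 C July).
#'
#' @param annual_mean annual mean temperature (degrees C).
#' @param amplitude seasonal half-range (degrees C, >= 0).
#' @param peak_doy day of year of the warm peak (default July 20).
#' @param noise_sd standard deviation of daily deviations (degrees C, >= 0).
#' @param ar1 lag-1 autocorrelation of the daily noise (|ar1| < 1).
#' @return An object of class \code{climatology_params}.
#' @export
climatology_params <- function(annual_mean = 8.0, amplitude = 16.0,
                               peak_doy = 201L, noise_sd = 3.0, ar1 = 0.6) {
  stopifnot(is.numeric(annual_mean),
            is.numeric(amplitude), amplitude >= 0,
            is.numeric(peak_doy), peak_doy >= 1, peak_doy <= 366,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(ar1), abs(ar1) < 1)
  structure(list(annual_mean = annual_mean, amplitude = amplitude,
                 peak_doy = as.integer(peak_doy), noise_sd = noise_sd,
                 ar1 = ar1),
            class = "climatology_params")
}

.validate_series <- function(d) {
  if (!all(c("date", "tmean") %in% names(d)))
    stop("temperature series needs columns date, tmean", call. = FALSE)
  if (nrow(d) < 1L) stop("empty temperature series", call. = FALSE)
  dd <- diff(as.integer(d$date))
  if (any(dd != 1L)) {
    bad <- which(dd != 1L)[1]
    stop(sprintf(
      "temperature series must advance by exactly one day; violation after row %d (%s -> %s)",
      bad, d$date[bad], d$date[bad + 1L]), call. = FALSE)
  }
  class(d) <- c("temperature_series", "data.frame")
  d
}

#' Read a daily temperature series from CSV
#'
#' Accepts two dialects: \code{date,tmean} (ISO dates, degrees C) or
#' \code{date,tmin,tmax}, in which case \code{tmean = (tmin + tmax) / 2}.
#' Dates must be contiguous and strictly increasing by one day.
#'
#' @param path path to the CSV file.
#' @return A \code{temperature_series}: a data frame with \code{date}
#'   (Date) and \code{tmean} (numeric).
#' @export
read_temperature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(d))
    stop("temperature CSV must have a 'date' column", call. = FALSE)
  dates <- as.Date(d$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("unparseable date at row %d: %s", bad, d$date[bad]),
         call. = FALSE)
  }
  if ("tmean" %in% names(d)) {
    tmean <- suppressWarnings(as.numeric(d$tmean))
  } else if (all(c("tmin", "tmax") %in% names(d))) {
    tmin <- suppressWarnings(as.numeric(d$tmin))
    tmax <- suppressWarnings(as.numeric(d$tmax))
    tmean <- (tmin + tmax) / 2
  } else {
    stop("temperature CSV must have 'tmean' or both 'tmin' and 'tmax'",
         call. = FALSE)
  }
  if (any(is.na(tmean))) {
    bad <- which(is.na(tmean))[1]
    stop(sprintf("unparseable temperature value at row %d", bad),
         call. = FALSE)
  }
  .validate_series(data.frame(date = dates, tmean = tmean))
}

#' Generate a synthetic daily temperature season
#'
#' Daily mean temperature is a sinusoid
#' \code{annual_mean + amplitude * cos(2*pi*(doy - peak_doy)/365)} plus an
#' AR(1) noise process; reproducible under a fixed seed.
#'
#' @param params a [climatology_params()] object.
#' @param start,end first and last date (Date or ISO string), start < end.
#' @param seed integer RNG seed.
#' @return A \code{temperature_series} covering \code{start..end}.
#' @examples
#' s <- synthesize_season(seed = 1)
#' mean(s$tmean[months(s$date) == "July"])
#' @export
synthesize_season <- function(params = climatology_params(),
                              start = "2021-03-01", end = "2021-09-01",
                              seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop("start must precede end", call. = FALSE)
  dates <- seq(start, end, by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  base <- params$annual_mean +
    params$amplitude * cos(2 * pi * (doy - params$peak_doy) / 365)
  n <- length(dates)
  noise <- numeric(n)
  if (params$noise_sd > 0) {
    set.seed(as.integer(seed))
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1^2)
    eps <- stats::rnorm(n, 0, innov_sd)
    noise[1] <- stats::rnorm(1, 0, params$noise_sd)
    for (i in seq_len(n - 1L)) noise[i + 1L] <- params$ar1 * noise[i] + eps[i + 1L]
  }
  .validate_series(data.frame(date = dates, tmean = base + noise))
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Daily temperature series: %s to %s (%d days), mean %.1f C\n",
              x$date[1], x$date[nrow(x)], nrow(x), mean(x$tmean)))
  invisible(x)
}
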