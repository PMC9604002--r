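#' Daily degree-days above a threshold
#'
#' Degree-days accumulated on one day with the average method:
#' `max(0, (t_min + t_max)/2 - ltt)`. Days whose mean temperature falls below
#' the threshold contribute zero (never negative) heat. For a
#' constant-temperature day (`t_min == t_max == T`) this reduces to
#' `T - ltt`.
#'
#' @param t_min,t_max Daily minimum and maximum temperature (degrees C);
#'   vectors are accepted, recycled elementwise.
#' @param ltt Lower temperature threshold (degrees C).
#' @return Degree-days (non-negative), same length as the inputs.
#' @examples
#' daily_degree_days(24, 24, 14.4)  # 9.6
#' daily_degree_days(10, 14, 14.4)  # 0, clamped
#' @export
daily_degree_days <- function(t_min, t_max, ltt) {
  if (any(t_min > t_max)) stop("t_min > t_max", call. = FALSE)
  pmax(0, (t_min + t_max) / 2 - ltt)
}

#' Forecast emergence by degree-day accumulation
#'
#' Accumulates [daily_degree_days()] over a temperature series from
#' `start_date` (inclusive) and predicts stage completion on the first day the
#' running sum reaches the thermal requirement. Accumulation is at whole-day
#' granularity with ceiling semantics: emergence falls on the day the sum
#' first crosses `trd`, never interpolated within a day.
#'
#' @param series A `temperature_series` (see [temperature_series()]).
#' @param start_date Date accumulation starts (e.g. the oviposition or
#'   egg-attachment date); must lie within the series.
#' @param ltt Lower temperature threshold (degrees C).
#' @param trd Thermal requirement (degree-days); must be positive.
#' @return Object of class `emergence_forecast`: `start_date`,
#'   `predicted_date`, `duration_days`, the per-day `cumulative_dd` trace
#'   (named by date), `ltt` and `trd`.
#' @examples
#' s <- temperature_series(seq(as.Date("2021-06-01"), by = 1, length.out = 40),
#'                         t_min = 24)
#' forecast_emergence(s, as.Date("2021-06-01"), ltt = 14.4, trd = 285.3)
#' @export
forecast_emergence <- function(series, start_date, ltt, trd) {
  validate_temperature_series(series)
  start_date <- as.Date(start_date)
  if (!is.finite(trd) || trd <= 0) stop("trd must be positive", call. = FALSE)
  dates <- as.Date(series$date)
  idx <- which(dates >= start_date)
  if (length(idx) == 0L || dates[idx[1L]] != start_date) {
    stop(sprintf("start_date %s is not in the temperature series",
                 format(start_date)), call. = FALSE)
  }
  dd <- daily_degree_days(series$t_min[idx], series$t_max[idx], ltt)
  cum <- cumsum(dd)
  names(cum) <- format(dates[idx])
  # tiny tolerance so a requirement met exactly in real arithmetic is not
  # pushed a day late by binary representation error
  hit <- which(cum >= trd - 1e-9)
  if (length(hit) == 0L) {
    stop(sprintf(
      paste0("insufficient thermal accumulation: series ends %.1f ",
             "degree-days short of the %.1f required"),
      trd - cum[length(cum)], trd), call. = FALSE)
  }
  k <- unname(hit[1L])
  structure(list(start_date = start_date,
                 predicted_date = dates[idx[k]],
                 duration_days = k,
                 cumulative_dd = cum[seq_len(k)],
                 ltt = ltt, trd = trd),
            class = "emergence_forecast")
}

#' Chain per-stage forecasts across a stage sequence
#'
#' Runs [forecast_emergence()] for each stage model in order; each stage
#' starts the day after the previous one completes. Residual degree-days
#' accumulated within a stage's final day are discarded rather than carried
#' over, a conservative bias of at most one day per stage boundary that
#' matches a 24-h observation cadence.
#'
#' @param series A `temperature_series`.
#' @param start_date Date the first stage starts.
#' @param models List of `stage_rate_model` objects in developmental order;
#'   each must carry an `ltt` and a `trd_mean`.
#' @return Data frame with one row per stage: `stage`, `start_date`,
#'   `completion_date`, `duration_days`.
#' @export
forecast_stagewise <- function(series, start_date, models) {
  if (length(models) == 0L) stop("no stage models supplied", call. = FALSE)
  start <- as.Date(start_date)
  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (!inherits(m, "stage_rate_model") || is.na(m$trd_mean)) {
      stop("each model must be a stage_rate_model with a thermal requirement",
           call. = FALSE)
    }
    fc <- forecast_emergence(series, start, m$ltt, m$trd_mean)
    rows[[i]] <- data.frame(stage = m$stage, start_date = start,
                            completion_date = fc$predicted_date,
                            duration_days = fc$duration_days)
    start <- fc$predicted_date + 1L
  }
  do.call(rbind, rows)
}

#' Deviation of observed emergence from a forecast
#'
#' Scores a predicted emergence date against one or more observed emergence
#' dates. The sign convention is positive when the observation is later than
#' the prediction: a deviation of `+2` means adults appeared two days after
#' the forecast date.
#'
#' @param predicted Predicted date.
#' @param observed_dates Non-empty vector of observed emergence dates.
#' @return List with `deviation_min` and `deviation_max`, signed whole days.
#' @examples
#' forecast_deviation(as.Date("2021-09-22"),
#'                    as.Date(c("2021-09-24", "2021-09-25", "2021-09-26")))
#' @export
forecast_deviation <- function(predicted, observed_dates) {
  observed_dates <- as.Date(observed_dates)
  if (length(observed_dates) == 0L) {
    stop("observed_dates must be non-empty", call. = FALSE)
  }
  dev <- as.integer(observed_dates - as.Date(predicted))
  list(deviation_min = min(dev), deviation_max = max(dev))
}

#' Back-calculate the oviposition date from a peak-emergence date
#'
#' Reverse application of the degree-day accumulation: starting from an
#' observed adult-emergence (e.g. peak trap-catch) date, degree-days are
#' summed backwards through the series until the thermal requirement is met;
#' the day reaching it is the estimated oviposition date. Useful for placing
#' the egg-laying window of a migratory population from trap records.
#'
#' @param series A `temperature_series`.
#' @param peak_date Observed emergence date (within the series).
#' @param ltt Lower temperature threshold (degrees C).
#' @param trd Thermal requirement (degree-days).
#' @return Estimated oviposition `Date`.
#' @export
backcast_oviposition <- function(series, peak_date, ltt, trd) {
  validate_temperature_series(series)
  peak_date <- as.Date(peak_date)
  dates <- as.Date(series$date)
  idx <- which(dates <= peak_date)
  if (length(idx) == 0L || dates[idx[length(idx)]] != peak_date) {
    stop(sprintf("peak_date %s is not in the temperature series",
                 format(peak_date)), call. = FALSE)
  }
  dd <- daily_degree_days(series$t_min[idx], series$t_max[idx], ltt)
  cum <- rev(cumsum(rev(dd)))  # accumulation backwards from peak_date
  hit <- which(cum >= trd - 1e-9)
  if (length(hit) == 0L) {
    stop(sprintf(
      paste0("insufficient thermal accumulation: series start is %.1f ",
             "degree-days short of the %.1f required"),
      trd - cum[1L], trd), call. = FALSE)
  }
  dates[idx[hit[length(hit)]]]
}

#' @export
print.emergence_forecast <- function(x, ...) {
  cat("Degree-day emergence forecast\n")
  cat(sprintf("  start: %s   predicted: %s   (%d days)\n",
              format(x$start_date), format(x$predicted_date),
              x$duration_days))
  cat(sprintf("  threshold %.1f C, requirement %.1f degree-days, ",
              x$ltt, x$trd))
  cat(sprintf("accumulated %.1f\n", x$cumulative_dd[length(x$cumulative_dd)]))
  invisible(x)
}
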