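#' Valid life-stage labels
#'
#' The closed set of life-stage labels used throughout the package: the egg
#' stage, the six larval instars (`L1`--`L6`), the pupal stage, and the
#' composite `egg_to_adult` period. The pseudo-stage `"larvae"` (sum of the
#' six instars per individual) is accepted by the fitting functions but is
#' never stored as an observation label.
#'
#' @return Character vector of the nine valid stage labels, in
#'   developmental order.
#' @export
development_stages <- function() {
  c("egg", "L1", "L2", "L3", "L4", "L5", "L6", "pupa", "egg_to_adult")
}

stop_row <- function(row, msg) {
  # row is the data row index; +1 converts to the file line (header = line 1)
  stop(sprintf("row %d (file line %d): %s", row, row + 1L, msg), call. = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a development-observation table
#'
#' Checks one-row-per-observation development data against the domain
#' invariants: stage labels drawn from [development_stages()], finite
#' temperatures, and durations of at least one day (observations are made at
#' 24-h intervals, so sub-day durations cannot occur).
#'
#' @param df Data frame with columns `individual_id`, `stage`, `temperature`,
#'   `duration`.
#' @return The validated data frame, invisibly, with `stage` as character.
#' @export
validate_development <- function(df) {
  require_columns(df, c("individual_id", "stage", "temperature", "duration"),
                  "development")
  df$stage <- as.character(df$stage)
  for (i in seq_len(nrow(df))) {
    if (!df$stage[i] %in% development_stages()) {
      stop_row(i, sprintf(
        "unknown stage label '%s'; valid labels are: %s",
        df$stage[i], paste(development_stages(), collapse = ", ")))
    }
    if (!is.finite(df$temperature[i])) {
      stop_row(i, "temperature must be a finite number (degrees C)")
    }
    if (!is.finite(df$duration[i]) || df$duration[i] < 1) {
      stop_row(i, sprintf(
        "duration must be >= 1 day (24-h observation cadence), got %s",
        format(df$duration[i])))
    }
  }
  invisible(df)
}

#' Read a development-observation table
#'
#' Reads a long-format CSV of individual stage durations: one row per
#' (individual, stage) with the rearing temperature and the observed
#' duration in days. Column order is free but the header must name
#' `individual_id`, `stage`, `temperature`, `duration`.
#'
#' @param path Path to a CSV file.
#' @return Data frame of validated development observations.
#' @seealso [write_development()], [validate_development()]
#' @export
read_development <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_development(df)
  df$stage <- as.character(df$stage)
  df
}

#' Write a development-observation table
#'
#' @param df Development observations (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_development <- function(df, path) {
  validate_development(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a daily temperature series
#'
#' A temperature series is a gap-free daily record of minimum and maximum air
#' temperature. Constant-temperature (incubator) series are encoded with
#' `t_min == t_max`.
#'
#' @param date Vector of dates (`Date` or ISO-8601 strings).
#' @param t_min,t_max Daily minimum and maximum temperature in degrees C. If
#'   `t_max` is missing the series is treated as constant (`t_max = t_min`).
#' @return Data frame of class `temperature_series` with columns `date`,
#'   `t_min`, `t_max`.
#' @export
temperature_series <- function(date, t_min, t_max = t_min) {
  date <- as.Date(date)
  df <- data.frame(date = date, t_min = as.numeric(t_min),
                   t_max = as.numeric(t_max))
  validate_temperature_series(df)
  class(df) <- c("temperature_series", "data.frame")
  df
}

#' Validate a temperature series
#'
#' Enforces strictly increasing dates at whole-day steps with no gaps or
#' duplicates, and `t_min <= t_max` on every day. Errors name the offending
#' date.
#'
#' @param df Data frame with columns `date`, `t_min`, `t_max`.
#' @return The data frame, invisibly.
#' @export
validate_temperature_series <- function(df) {
  require_columns(df, c("date", "t_min", "t_max"), "temperature")
  if (nrow(df) == 0L) stop("temperature series is empty", call. = FALSE)
  if (anyNA(df$date)) stop("temperature series contains unparseable dates",
                           call. = FALSE)
  if (nrow(df) > 1L) {
    step <- diff(as.integer(as.Date(df$date)))
    bad <- which(step != 1L)
    if (length(bad) > 0L) {
      i <- bad[1L]
      if (step[i] <= 0L) {
        stop(sprintf("duplicate or out-of-order date: %s",
                     format(df$date[i + 1L])), call. = FALSE)
      }
      stop(sprintf("missing date(s) between %s and %s",
                   format(df$date[i]), format(df$date[i + 1L])), call. = FALSE)
    }
  }
  bad <- which(df$t_min > df$t_max)
  if (length(bad) > 0L) {
    stop(sprintf("t_min > t_max on %s", format(df$date[bad[1L]])),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a daily temperature series
#'
#' Reads a CSV with columns `date` (ISO-8601), `t_min`, `t_max` and validates
#' it into a gap-free daily series.
#'
#' @param path Path to a CSV file.
#' @return A `temperature_series` data frame.
#' @export
read_temperature_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("date", "t_min", "t_max"), "temperature")
  temperature_series(df$date, df$t_min, df$t_max)
}

#' Write a daily temperature series
#'
#' @param series A `temperature_series` (or conforming data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature_series <- function(series, path) {
  validate_temperature_series(series)
  out <- data.frame(date = format(as.Date(series$date)),
                    t_min = series$t_min, t_max = series$t_max)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a feeding-observation table
#'
#' Feeding observations pair the before/after weight of a leaf offered to a
#' larva with the before/after weight of an untreated control leaf used to
#' estimate evaporative water loss. All weights must be positive, the instar
#' must lie in 1--6, and control leaves may only lose weight.
#'
#' @param df Data frame with columns `individual_id`, `instar`, `temperature`,
#'   `w_before`, `w_after`, `ctrl_before`, `ctrl_after`.
#' @return The data frame, invisibly.
#' @export
validate_feeding <- function(df) {
  require_columns(df, c("individual_id", "instar", "temperature", "w_before",
                        "w_after", "ctrl_before", "ctrl_after"), "feeding")
  for (i in seq_len(nrow(df))) {
    if (!df$instar[i] %in% 1:6) {
      stop_row(i, sprintf("instar must be an integer in 1..6, got %s",
                          format(df$instar[i])))
    }
    w <- c(df$w_before[i], df$w_after[i], df$ctrl_before[i], df$ctrl_after[i])
    if (any(!is.finite(w)) || any(w <= 0)) {
      stop_row(i, "all four weights must be positive")
    }
    if (df$ctrl_after[i] > df$ctrl_before[i]) {
      stop_row(i, "ctrl_after > ctrl_before (control leaves only lose water)")
    }
  }
  invisible(df)
}

#' Read a feeding-observation table
#'
#' @param path Path to a CSV file.
#' @return Data frame of validated feeding observations.
#' @export
read_feeding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_feeding(df)
  df
}

#' Write a feeding-observation table
#'
#' @param df Feeding observations (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feeding <- function(df, path) {
  validate_feeding(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a viability-count table
#'
#' @param df Data frame with columns `temperature`, `replicate`, `n_exposed`,
#'   `n_succeeded`, `endpoint`; `endpoint` is `"hatch"` or
#'   `"larval_survival"`.
#' @return The data frame, invisibly.
#' @export
validate_viability <- function(df) {
  require_columns(df, c("temperature", "replicate", "n_exposed",
                        "n_succeeded", "endpoint"), "viability")
  valid_ep <- c("hatch", "larval_survival")
  for (i in seq_len(nrow(df))) {
    if (!df$endpoint[i] %in% valid_ep) {
      stop_row(i, sprintf("unknown endpoint '%s'; valid endpoints are: %s",
                          df$endpoint[i], paste(valid_ep, collapse = ", ")))
    }
    if (df$n_exposed[i] < 1 || df$n_succeeded[i] < 0 ||
        df$n_succeeded[i] > df$n_exposed[i]) {
      stop_row(i, "counts must satisfy 0 <= n_succeeded <= n_exposed")
    }
  }
  invisible(df)
}

#' Read a viability-count table
#'
#' @param path Path to a CSV file.
#' @return Data frame of validated viability records.
#' @export
read_viability <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_viability(df)
  df
}

#' Write a viability-count table
#'
#' @param df Viability records (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_viability <- function(df, path) {
  validate_viability(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
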