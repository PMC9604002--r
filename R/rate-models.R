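#' Development rate from stage duration
#'
#' In the linear degree-day framework the response regressed on temperature is
#' the development rate, the reciprocal of the stage duration: an individual
#' completing a stage in `d` days develops at `1/d` per day.
#'
#' @param duration Stage duration(s) in days; must be positive.
#' @return Development rate(s) in 1/day.
#' @examples
#' development_rate(2)    # 0.5
#' development_rate(7.1)  # egg stage at 20 C
#' @export
development_rate <- function(duration) {
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("duration must be positive", call. = FALSE)
  }
  1 / duration
}

# Closed-form simple OLS via the normal equations; the degree-day model's
# rate line is fitted directly rather than through a model formula so the
# arithmetic behind the reported coefficients is explicit.
ols_line <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 points to fit a line", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in temperature; cannot fit", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Per-individual durations for a stage, including the composite pseudo-stages:
# "larvae" sums L1..L6 per individual; "egg_to_adult" uses explicit rows when
# present, otherwise the per-individual sum over egg..pupa.
stage_durations <- function(observations, stage) {
  observations <- validate_development(observations)
  if (stage %in% development_stages() &&
      (stage != "egg_to_adult" || any(observations$stage == "egg_to_adult"))) {
    sub <- observations[observations$stage == stage, , drop = FALSE]
    return(data.frame(individual_id = sub$individual_id,
                      temperature = sub$temperature,
                      duration = sub$duration))
  }
  parts <- switch(stage,
    larvae = paste0("L", 1:6),
    egg_to_adult = c("egg", paste0("L", 1:6), "pupa"),
    stop(sprintf("unknown stage '%s'; valid: %s, larvae", stage,
                 paste(development_stages(), collapse = ", ")), call. = FALSE))
  sub <- observations[observations$stage %in% parts, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no observations for stage '%s'", stage), call. = FALSE)
  }
  key <- interaction(sub$individual_id, sub$temperature, drop = TRUE)
  counts <- tapply(sub$stage, key, function(s) length(unique(s)))
  complete <- names(counts)[counts == length(parts)]
  sub <- sub[key %in% complete, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf(
      "no individual has all %d component stages needed for '%s'",
      length(parts), stage), call. = FALSE)
  }
  agg <- stats::aggregate(duration ~ individual_id + temperature, data = sub,
                          FUN = sum)
  agg[order(agg$temperature, agg$individual_id), ]
}

#' Construct a stage rate model from known coefficients
#'
#' Builds a `stage_rate_model` directly from a slope and intercept, e.g. when
#' applying published regression coefficients rather than refitting. The lower
#' temperature threshold is derived as `-intercept/slope`; the thermal
#' requirement fields are left `NA` unless supplied.
#'
#' @param stage Stage label.
#' @param slope Rate increase per degree C (1/(day*C)); must be positive.
#' @param intercept Rate at 0 C (1/day).
#' @param r_squared Optional coefficient of determination.
#' @param trd_mean,trd_sd Optional thermal requirement (degree-days).
#' @param temperatures Temperatures the coefficients were fitted on.
#' @param fit_level `"individual"` or `"group_mean"`.
#' @return Object of class `stage_rate_model`.
#' @export
stage_rate_model <- function(stage, slope, intercept, r_squared = NA_real_,
                             trd_mean = NA_real_, trd_sd = NA_real_,
                             temperatures = c(20, 24, 28, 32),
                             fit_level = "group_mean") {
  if (!is.finite(slope) || slope <= 0) {
    stop("slope must be positive: development accelerates with temperature ",
         "in the linear range", call. = FALSE)
  }
  structure(list(stage = stage, slope = slope, intercept = intercept,
                 r_squared = r_squared, ltt = -intercept / slope,
                 trd_mean = trd_mean, trd_sd = trd_sd,
                 temperatures = sort(unique(temperatures)),
                 fit_level = fit_level),
            class = "stage_rate_model")
}

#' Fit the linear development-rate model for one life stage
#'
#' Regresses development rate (1/duration) on rearing temperature by ordinary
#' least squares over the requested temperature window, then derives the lower
#' temperature threshold (LTT, the x-intercept `-b/a` where the rate line
#' crosses zero) and the thermal requirement in degree-days (TRD) by
#' per-temperature degree-day averaging (see [thermal_requirement()]).
#'
#' Two fit levels are supported. `"individual"` regresses every individual's
#' rate on its rearing temperature; `"group_mean"` first averages the rates
#' within each temperature and fits the per-temperature mean rates (one point
#' per temperature). Published summary tables are reproducible only at the
#' group-mean level; individual-level fits use the full data and are the
#' default when individual observations are available.
#'
#' @param observations Development observations (long format).
#' @param stage Stage label from [development_stages()], or the composite
#'   `"larvae"` (per-individual sum of the six instars).
#' @param temperatures Temperature window used for fitting, in degrees C.
#'   Defaults to 20--32 C; rearing extremes with poor survival are excluded
#'   from the linear range by default.
#' @param fit_level `"individual"` (default) or `"group_mean"`.
#' @return A `stage_rate_model` with slope, intercept, R-squared, LTT,
#'   TRD mean and SD, plus `trd_individual_sd` (SD of per-individual
#'   degree-day totals) when more than one observation per temperature is
#'   available.
#' @examples
#' obs <- data.frame(individual_id = 1:4, stage = "egg",
#'                   temperature = c(20, 24, 28, 32),
#'                   duration = c(7.1, 4.3, 3.2, 2.0))
#' fit_stage_model(obs, "egg", fit_level = "group_mean")
#' @export
fit_stage_model <- function(observations, stage,
                            temperatures = c(20, 24, 28, 32),
                            fit_level = c("individual", "group_mean")) {
  fit_level <- match.arg(fit_level)
  dur <- stage_durations(observations, stage)
  dur <- dur[dur$temperature %in% temperatures, , drop = FALSE]
  temps_present <- sort(unique(dur$temperature))
  if (length(temps_present) < 2L) {
    stop(sprintf(
      "stage '%s': need observations at >= 2 distinct temperatures in the ",
      stage), "fitting window, found ", length(temps_present), call. = FALSE)
  }
  rate <- development_rate(dur$duration)
  if (fit_level == "group_mean") {
    y <- as.numeric(tapply(rate, dur$temperature, mean))
    x <- sort(unique(dur$temperature))
  } else {
    y <- rate
    x <- dur$temperature
  }
  line <- ols_line(x, y)
  if (line$slope <= 0) {
    stop(sprintf("stage '%s': fitted slope is not positive; data are outside ",
                 stage), "the linear range", call. = FALSE)
  }
  ltt <- -line$intercept / line$slope
  trd <- thermal_requirement(observations, stage, ltt,
                             temperatures = temps_present)
  m <- stage_rate_model(stage, line$slope, line$intercept,
                        r_squared = line$r_squared,
                        trd_mean = trd$trd_mean, trd_sd = trd$trd_sd,
                        temperatures = temps_present, fit_level = fit_level)
  m$trd_individual_sd <- trd$individual_sd
  m$n_observations <- nrow(dur)
  m
}

#' Lower temperature threshold of a rate line
#'
#' The lower temperature threshold (LTT) is the temperature at which the
#' fitted development rate extrapolates to zero: the x-intercept `-b/a` of the
#' line `rate = a * T + b`. Below it, no degree-days accumulate.
#'
#' @param model A `stage_rate_model`, or a numeric slope (with `intercept`
#'   given separately).
#' @param intercept Intercept `b`, required when `model` is a numeric slope.
#' @return Threshold temperature in degrees C (full precision; summaries
#'   report it at 0.1 C).
#' @examples
#' lower_threshold(0.0289, -0.4536)  # 15.7 C at 1 d.p.
#' @export
lower_threshold <- function(model, intercept = NULL) {
  if (inherits(model, "stage_rate_model")) {
    a <- model$slope
    b <- model$intercept
  } else {
    a <- model
    b <- intercept
  }
  if (!is.finite(a) || a == 0) {
    stop("slope is zero; lower threshold undefined", call. = FALSE)
  }
  -b / a
}

#' Thermal requirement by per-temperature degree-day averaging
#'
#' Under constant rearing temperature the degree-days accumulated by an
#' individual completing a stage in `d` days at temperature `T` are
#' `d * (T - LTT)`. The thermal requirement (TRD) is estimated by averaging
#' these degree-day totals within each rearing temperature and then taking
#' the mean and SD of the per-temperature group means, one value per
#' temperature. The SD over all individual degree-day totals is also
#' returned (`individual_sd`) when individual data are available; the two
#' dispersions answer different questions and are labelled accordingly.
#'
#' @param observations Development observations.
#' @param stage Stage label (or `"larvae"` composite).
#' @param ltt Lower temperature threshold in degrees C.
#' @param temperatures Temperatures to include; all must exceed `ltt`.
#' @return List with `trd_mean`, `trd_sd` (across per-temperature means),
#'   `per_temperature` (named group means) and `individual_sd`.
#' @examples
#' obs <- data.frame(individual_id = 1:4, stage = "egg_to_adult",
#'                   temperature = c(20, 24, 28, 32),
#'                   duration = c(49.6, 29.5, 21.9, 16.1))
#' thermal_requirement(obs, "egg_to_adult", ltt = 0.0490 / 0.0034)
#' @export
thermal_requirement <- function(observations, stage, ltt,
                                temperatures = c(20, 24, 28, 32)) {
  dur <- stage_durations(observations, stage)
  dur <- dur[dur$temperature %in% temperatures, , drop = FALSE]
  if (nrow(dur) == 0L) {
    stop(sprintf("no observations for stage '%s' in the temperature set",
                 stage), call. = FALSE)
  }
  if (any(dur$temperature <= ltt)) {
    bad <- min(dur$temperature[dur$temperature <= ltt])
    stop(sprintf(
      "temperature %g C is at or below the lower threshold %.1f C; ",
      bad, ltt), "degree-day accumulation is undefined there", call. = FALSE)
  }
  dd <- dur$duration * (dur$temperature - ltt)
  group_means <- tapply(dd, dur$temperature, mean)
  list(trd_mean = mean(group_means),
       trd_sd = if (length(group_means) > 1L) stats::sd(group_means) else 0,
       per_temperature = group_means,
       individual_sd = if (nrow(dur) > length(group_means))
         stats::sd(dd) else NA_real_)
}

#' Fit rate models for several stages
#'
#' Convenience wrapper running [fit_stage_model()] over a set of stages and
#' assembling the regression summary table: slope, intercept, R-squared, LTT
#' and TRD per stage, with the customary reporting precision (coefficients
#' and R-squared at 4 d.p., LTT and TRD at 1 d.p.) alongside the
#' full-precision values.
#'
#' @param observations Development observations.
#' @param stages Character vector of stage labels (may include `"larvae"`).
#' @param temperatures Fitting window in degrees C.
#' @param fit_level `"individual"` or `"group_mean"`.
#' @return Data frame with one row per stage.
#' @export
fit_rate_models <- function(observations,
                            stages = c("egg", paste0("L", 1:6), "larvae",
                                       "pupa", "egg_to_adult"),
                            temperatures = c(20, 24, 28, 32),
                            fit_level = c("individual", "group_mean")) {
  fit_level <- match.arg(fit_level)
  rows <- lapply(stages, function(s) {
    m <- fit_stage_model(observations, s, temperatures, fit_level)
    data.frame(stage = s, slope = m$slope, intercept = m$intercept,
               r_squared = m$r_squared, ltt = m$ltt, trd_mean = m$trd_mean,
               trd_sd = m$trd_sd, fit_level = m$fit_level,
               n = m$n_observations)
  })
  out <- do.call(rbind, rows)
  out$slope_4dp <- round(out$slope, 4)
  out$intercept_4dp <- round(out$intercept, 4)
  out$r_squared_4dp <- round(out$r_squared, 4)
  out$ltt_1dp <- round(out$ltt, 1)
  out$trd_1dp <- round(out$trd_mean, 1)
  out
}

#' @export
print.stage_rate_model <- function(x, ...) {
  cat(sprintf("Linear development-rate model: %s (%s fit)\n",
              x$stage, x$fit_level))
  cat(sprintf("  rate = %.4f * T %+.4f   (R^2 = %s)\n", x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  cat(sprintf("  lower temperature threshold: %.1f C\n", x$ltt))
  if (!is.na(x$trd_mean)) {
    cat(sprintf("  thermal requirement: %.1f +/- %.1f degree-days\n",
                x$trd_mean, ifelse(is.na(x$trd_sd), 0, x$trd_sd)))
  }
  cat(sprintf("  temperatures used: %s C\n",
              paste(x$temperatures, collapse = ", ")))
  invisible(x)
}
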