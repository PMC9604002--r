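# Run expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Per-generator substream offsets: a single user seed fans out so that adding
# or re-running one generator never perturbs another's draws.
substream <- function(seed, generator) {
  offset <- c(development = 101L, weather = 202L, feeding = 303L,
              viability = 404L)[[generator]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the ground truth from which every synthetic input table is drawn.
#' Defaults emulate the reference rearing design: 30 individuals per
#' temperature at 20/24/28/32 C observed at 24-h intervals (so durations are
#' rounded to whole days with a floor of 1), per-stage rate lines and
#' day-scale noise calibrated to the reference tables, triplicate viability
#' cohorts of 100, and per-instar feeding means/SDs of reference magnitude.
#'
#' @param rate_lines Data frame with columns `stage`, `slope`, `intercept`:
#'   the true development-rate line per stage. Default: the reference lines
#'   of [sf_rate_lines()] for egg, L1--L6 and pupa.
#' @param temperatures Rearing temperatures (degrees C); every temperature
#'   must exceed each configured stage's implied lower threshold.
#' @param n_per_temperature Individuals per temperature (default 30).
#' @param duration_noise_sd Named vector of additive day-scale noise SDs per
#'   stage; defaults calibrated to the reference SDs at 24 C (0.7 d for eggs).
#' @param rounding `"nearest_day"` (default; 24-h observation cadence) or
#'   `"none"`.
#' @param hatch_p,survival_p Named vectors (by temperature) of hatch and
#'   first-instar-to-adult survival probabilities.
#' @param n_replicates,n_exposed Viability design (default 3 x 100).
#' @param feeding Data frame with columns `instar`, `temperature`, `mean_g`,
#'   `sd_g`: true intake distribution per cell. Default: the reference
#'   per-instar feeding table.
#' @param leaf_weight_mean,leaf_weight_sd Fresh leaf weight distribution (g).
#' @param control_evaporation_ratio Fraction of leaf weight lost to
#'   evaporation over one weighing interval (default 0.05).
#' @param n_controls Untreated control leaves per (instar, temperature) cell
#'   (default 5), reduced to one mean evaporation ratio.
#' @param measurement_noise_sd Balance noise SD in grams (default 5e-4).
#' @param weather List with `base`, `amplitude`, `period`, `diurnal_range`,
#'   `noise_sd`: sinusoidal seasonal mean temperature (degrees C), its period
#'   in days, the fixed daily max-min spread, and day-to-day noise on the
#'   daily mean.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(rate_lines = NULL,
                         temperatures = c(20, 24, 28, 32),
                         n_per_temperature = 30,
                         duration_noise_sd = c(
                           egg = 0.7, L1 = 0.7, L2 = 0.4, L3 = 0.4, L4 = 0.4,
                           L5 = 0.4, L6 = 0.9, pupa = 0.6, egg_to_adult = 1.4),
                         rounding = c("nearest_day", "none"),
                         hatch_p = c(`16` = 0.60, `20` = 0.65, `24` = 0.840,
                                     `28` = 0.857, `32` = 0.773, `36` = 0.55),
                         survival_p = c(`16` = 0.310, `20` = 0.880,
                                        `24` = 0.973, `28` = 0.990,
                                        `32` = 0.987, `36` = 0.453),
                         n_replicates = 3, n_exposed = 100,
                         feeding = NULL,
                         leaf_weight_mean = 10, leaf_weight_sd = 1,
                         control_evaporation_ratio = 0.05,
                         n_controls = 5,
                         measurement_noise_sd = 5e-4,
                         weather = list(base = 22, amplitude = 8,
                                        period = 365, diurnal_range = 8,
                                        noise_sd = 1),
                         seed = 1L) {
  rounding <- match.arg(rounding)
  if (is.null(rate_lines)) {
    ref <- sf_rate_lines()
    rate_lines <- ref[ref$stage %in% c("egg", paste0("L", 1:6), "pupa"),
                      c("stage", "slope", "intercept")]
  }
  require_columns(rate_lines, c("stage", "slope", "intercept"), "rate_lines")
  if (is.null(feeding)) {
    ref <- sf_feeding_amounts()
    feeding <- ref[ref$instar != "total", ]
    feeding$instar <- as.integer(feeding$instar)
  }
  require_columns(feeding, c("instar", "temperature", "mean_g", "sd_g"),
                  "feeding")
  if (any(hatch_p < 0 | hatch_p > 1) || any(survival_p < 0 | survival_p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_per_temperature < 1) stop("n_per_temperature must be >= 1",
                                  call. = FALSE)
  if (control_evaporation_ratio < 0 || control_evaporation_ratio >= 1) {
    stop("control_evaporation_ratio must lie in [0, 1)", call. = FALSE)
  }
  structure(list(rate_lines = rate_lines, temperatures = temperatures,
                 n_per_temperature = n_per_temperature,
                 duration_noise_sd = duration_noise_sd, rounding = rounding,
                 hatch_p = hatch_p, survival_p = survival_p,
                 n_replicates = n_replicates, n_exposed = n_exposed,
                 feeding = feeding, leaf_weight_mean = leaf_weight_mean,
                 leaf_weight_sd = leaf_weight_sd,
                 control_evaporation_ratio = control_evaporation_ratio,
                 n_controls = n_controls,
                 measurement_noise_sd = measurement_noise_sd,
                 weather = weather, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic development observations
#'
#' Draws one duration per (stage, temperature, individual): the mean duration
#' is the reciprocal of the true rate line, `1/(a*T + b)`, with additive
#' Gaussian noise on the day scale, optionally rounded to the nearest whole
#' day with a floor of one day (the 24-h observation cadence). Individuals
#' keep the same id across stages, so composite periods can be assembled per
#' individual. If the config's rate lines include `egg_to_adult` alongside
#' all component stages, the composite rows are the per-individual stage
#' sums; if `egg_to_adult` is configured alone, it is drawn from its own
#' line.
#'
#' @param config A [synth_config()].
#' @return Validated development data frame (deterministic given
#'   `config$seed`).
#' @export
gen_development <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lines <- config$rate_lines
  components <- c("egg", paste0("L", 1:6), "pupa")
  sum_composite <- "egg_to_adult" %in% lines$stage &&
    all(components %in% lines$stage)
  with_seed(substream(config$seed, "development"), {
    rows <- list()
    for (s in seq_len(nrow(lines))) {
      stage <- lines$stage[s]
      if (stage == "egg_to_adult" && sum_composite) next
      a <- lines$slope[s]
      b <- lines$intercept[s]
      sd_s <- config$duration_noise_sd[[stage]]
      if (is.null(sd_s) || is.na(sd_s)) sd_s <- 0
      for (temp in config$temperatures) {
        rate <- a * temp + b
        if (rate <= 0) {
          stop(sprintf(
            "temperature %g C is at or below stage '%s' lower threshold %.1f C",
            temp, stage, -b / a), call. = FALSE)
        }
        n <- config$n_per_temperature
        dur <- 1 / rate + stats::rnorm(n, 0, sd_s)
        if (config$rounding == "nearest_day") dur <- round(dur)
        dur <- pmax(1, dur)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("T%g_i%02d", temp, seq_len(n)),
          stage = stage, temperature = temp, duration = dur)
      }
    }
    out <- do.call(rbind, rows)
    if (sum_composite) {
      tot <- stats::aggregate(duration ~ individual_id + temperature,
                              data = out, FUN = sum)
      tot$stage <- "egg_to_adult"
      out <- rbind(out, tot[c("individual_id", "stage", "temperature",
                              "duration")])
    }
    rownames(out) <- NULL
    validate_development(out)
    out
  })
}

#' Generate a synthetic daily temperature series
#'
#' Daily mean temperature follows a sinusoid,
#' `base + amplitude * sin(2*pi*t/period)` for day index `t` starting at 0,
#' plus Gaussian day-to-day noise on the mean; `t_min`/`t_max` sit half the
#' diurnal range below/above the (noisy) mean, so the daily spread is exactly
#' `diurnal_range`.
#'
#' @param config A [synth_config()] (uses `config$weather` and `config$seed`).
#' @param start First date of the series.
#' @param n_days Number of days (>= 1).
#' @return A `temperature_series`.
#' @export
gen_weather <- function(config, start, n_days) {
  stopifnot(inherits(config, "synth_config"))
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  w <- config$weather
  with_seed(substream(config$seed, "weather"), {
    t <- seq_len(n_days) - 1
    mid <- w$base + w$amplitude * sin(2 * pi * t / w$period) +
      stats::rnorm(n_days, 0, w$noise_sd)
    temperature_series(seq(as.Date(start), by = 1, length.out = n_days),
                       t_min = mid - w$diurnal_range / 2,
                       t_max = mid + w$diurnal_range / 2)
  })
}

#' Generate synthetic feeding observations
#'
#' For each (instar, temperature, individual): a true intake is drawn from the
#' configured Gaussian clipped at zero; the offered leaf weight is drawn from
#' the leaf-weight distribution; the remaining weight is the leaf weight after
#' control-matched evaporation minus the intake, plus balance noise. Five
#' untreated control leaves per cell share the evaporation ratio and are
#' reduced to one mean ratio (carried on each row as the paired control
#' weights), so with zero noise [corrected_intake()] inverts the construction
#' exactly.
#'
#' @param config A [synth_config()].
#' @return Validated feeding data frame (deterministic given `config$seed`).
#' @export
gen_feeding <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  keep <- config$feeding$temperature %in% config$temperatures
  cells <- config$feeding[keep, , drop = FALSE]
  retain <- 1 - config$control_evaporation_ratio
  with_seed(substream(config$seed, "feeding"), {
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      n <- config$n_per_temperature
      intake <- pmax(0, stats::rnorm(n, cells$mean_g[i], cells$sd_g[i]))
      w_before <- stats::rnorm(n, config$leaf_weight_mean,
                               config$leaf_weight_sd)
      w_after <- w_before * retain - intake +
        stats::rnorm(n, 0, config$measurement_noise_sd)
      cb <- stats::rnorm(config$n_controls, config$leaf_weight_mean,
                         config$leaf_weight_sd)
      ca <- cb * retain + stats::rnorm(config$n_controls, 0,
                                       config$measurement_noise_sd)
      ca <- pmin(ca, cb)  # controls only lose water
      ratio <- evaporation_ratio(cb, ca)
      rows[[i]] <- data.frame(
        individual_id = sprintf("T%g_i%02d", cells$temperature[i],
                                seq_len(n)),
        instar = cells$instar[i], temperature = cells$temperature[i],
        w_before = w_before, w_after = w_after,
        ctrl_before = mean(cb), ctrl_after = mean(cb) * ratio)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_feeding(out)
    out
  })
}

#' Generate synthetic viability counts
#'
#' Binomial draws per replicate for both endpoints (`hatch` and
#' `larval_survival`) at every configured temperature with a configured
#' probability.
#'
#' @param config A [synth_config()].
#' @return Validated viability data frame (deterministic given `config$seed`).
#' @export
gen_viability <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(substream(config$seed, "viability"), {
    rows <- list()
    for (ep in c("hatch", "larval_survival")) {
      p_by_t <- if (ep == "hatch") config$hatch_p else config$survival_p
      for (temp in config$temperatures) {
        p <- p_by_t[[as.character(temp)]]
        if (is.null(p)) next
        rows[[length(rows) + 1L]] <- data.frame(
          temperature = temp, replicate = seq_len(config$n_replicates),
          n_exposed = config$n_exposed,
          n_succeeded = stats::rbinom(config$n_replicates, config$n_exposed,
                                      p),
          endpoint = ep)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_viability(out)
    out
  })
}
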