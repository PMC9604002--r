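# Round half away from zero at `digits` decimals; weighings are reported at
# the milligram (3 d.p.) after rounding from the balance's 4th decimal. The
# epsilon keeps exact half-milligram differences (0.0005 g) on the round-up
# side despite binary representation error.
round_half_up <- function(x, digits = 3) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Mean evaporation ratio from untreated control leaves
#'
#' Reduces one or more untreated control weighings to a single moisture-
#' retention ratio: the mean of the per-leaf `after/before` ratios. Each
#' control leaf gives an independent estimate of evaporative loss, so the
#' ratios are averaged rather than pooling the weights.
#'
#' @param ctrl_before,ctrl_after Control leaf weights (g) before and after the
#'   evaporation period; equal-length vectors.
#' @return Mean retention ratio in (0, 1].
#' @export
evaporation_ratio <- function(ctrl_before, ctrl_after) {
  if (any(ctrl_before <= 0)) stop("ctrl_before must be positive",
                                  call. = FALSE)
  if (any(ctrl_after > ctrl_before)) {
    stop("ctrl_after > ctrl_before: control leaves only lose water",
         call. = FALSE)
  }
  mean(ctrl_after / ctrl_before)
}

#' Evaporation-corrected leaf consumption
#'
#' The raw difference `w_before - w_after` overstates consumption because an
#' excised leaf loses water over the feeding period. The correction scales the
#' pre-feeding weight by the moisture-retention ratio observed on paired
#' untreated control leaves and subtracts the actual remaining weight:
#'
#' `intake = w_before * (ctrl_after / ctrl_before) - w_after`
#'
#' i.e. (what the leaf would have weighed from evaporation alone) minus (what
#' it actually weighed). With no evaporation (`ctrl_after == ctrl_before`) it
#' reduces to the simple difference; with no feeding and control-matched
#' evaporation it is zero. Results are rounded half-up to 3 decimal places,
#' the reporting precision of the analytical balance. Slightly negative values
#' can arise from measurement noise in early instars and are retained, not
#' clipped, to avoid biasing means upward.
#'
#' @param w_before,w_after Treated leaf weight (g) before and after feeding.
#' @param ctrl_before,ctrl_after Paired control leaf weights (g); pass a
#'   pre-averaged ratio via equal vectors or use [evaporation_ratio()]
#'   upstream.
#' @return Corrected intake in grams (3 d.p.), vectorised.
#' @examples
#' corrected_intake(2.000, 1.500, 1.000, 0.900)  # 0.300
#' corrected_intake(1.000, 0.950, 1.000, 0.950)  # 0.000, nothing eaten
#' @export
corrected_intake <- function(w_before, w_after, ctrl_before, ctrl_after) {
  if (any(ctrl_before <= 0)) stop("ctrl_before must be positive",
                                  call. = FALSE)
  round_half_up(w_before * (ctrl_after / ctrl_before) - w_after, 3)
}

#' Summarize leaf feeding per instar and per day
#'
#' Computes, for every (instar, temperature) cell, the mean and SD of the
#' evaporation-corrected intakes, plus a `total` row per temperature built
#' from per-individual sums across instars (individuals present in all six
#' instars). Daily intake divides the mean intake by the mean stage duration
#' at that temperature (total intake by total larval duration for the total
#' row), separating cumulative damage from feeding pressure per day.
#'
#' @param feeding Feeding observations (see [validate_feeding()]).
#' @param durations Data frame of mean stage durations with columns `stage`
#'   (instar labels `L1`--`L6`), `temperature`, and `duration` (mean days);
#'   e.g. per-temperature means of a development table.
#' @return Data frame with columns `instar` (`"1"`..`"6"` or `"total"`),
#'   `temperature`, `n`, `mean_intake`, `sd_intake`, `mean_duration`,
#'   `daily_intake`, and `n_negative` (count of negative corrected intakes,
#'   retained but flagged).
#' @export
summarize_feeding <- function(feeding, durations) {
  validate_feeding(feeding)
  require_columns(durations, c("stage", "temperature", "duration"),
                  "durations")
  feeding$intake <- corrected_intake(feeding$w_before, feeding$w_after,
                                     feeding$ctrl_before, feeding$ctrl_after)
  dur_for <- function(instar, temp) {
    d <- durations$duration[durations$stage == paste0("L", instar) &
                              durations$temperature == temp]
    if (length(d) != 1L) {
      stop(sprintf("missing stage duration for instar %s at %g C",
                   instar, temp), call. = FALSE)
    }
    d
  }
  cells <- unique(feeding[c("instar", "temperature")])
  cells <- cells[order(cells$temperature, cells$instar), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ins <- cells$instar[i]
    tmp <- cells$temperature[i]
    x <- feeding$intake[feeding$instar == ins & feeding$temperature == tmp]
    d <- dur_for(ins, tmp)
    data.frame(instar = as.character(ins), temperature = tmp, n = length(x),
               mean_intake = mean(x),
               sd_intake = if (length(x) > 1L) stats::sd(x) else 0,
               mean_duration = d, daily_intake = mean(x) / d,
               n_negative = sum(x < 0))
  })
  out <- do.call(rbind, rows)
  # total row: per-individual sums over complete 6-instar series
  for (tmp in sort(unique(feeding$temperature))) {
    sub <- feeding[feeding$temperature == tmp, , drop = FALSE]
    n_instars <- tapply(sub$instar, sub$individual_id,
                        function(v) length(unique(v)))
    complete <- names(n_instars)[n_instars == 6L]
    if (length(complete) == 0L) next
    sub <- sub[sub$individual_id %in% complete, , drop = FALSE]
    totals <- tapply(sub$intake, sub$individual_id, sum)
    total_dur <- sum(vapply(1:6, dur_for, numeric(1), temp = tmp))
    out <- rbind(out, data.frame(
      instar = "total", temperature = tmp, n = length(totals),
      mean_intake = mean(totals),
      sd_intake = if (length(totals) > 1L) stats::sd(totals) else 0,
      mean_duration = total_dur, daily_intake = mean(totals) / total_dur,
      n_negative = sum(totals < 0)))
  }
  rownames(out) <- NULL
  out
}
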