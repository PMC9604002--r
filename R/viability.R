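#' Hatch or survival percentage at one temperature
#'
#' Estimates a viability endpoint (egg hatch, or first-instar-to-adult
#' survival) at a rearing temperature as the mean of the per-replicate
#' percentages `100 * n_succeeded / n_exposed`. With equal exposure per
#' replicate (the usual triplicate-of-100 design) this equals the pooled
#' percentage; with unequal exposure the replicate mean is used, treating each
#' replicate as one experimental unit.
#'
#' @param records Viability records (see [validate_viability()]).
#' @param temperature Rearing temperature (degrees C) to estimate.
#' @param endpoint `"hatch"` or `"larval_survival"`.
#' @return List with `mean_pct` (mean percentage across replicates) and
#'   `replicate_pct` (per-replicate percentages). Summaries report the mean
#'   at 0.1 percent.
#' @examples
#' rec <- data.frame(temperature = 28, replicate = 1:3, n_exposed = 100,
#'                   n_succeeded = c(86, 85, 86), endpoint = "hatch")
#' proportion_estimate(rec, 28, "hatch")$mean_pct  # 85.66...
#' @export
proportion_estimate <- function(records, temperature,
                                endpoint = c("hatch", "larval_survival")) {
  endpoint <- match.arg(endpoint)
  validate_viability(records)
  sub <- records[records$temperature == temperature &
                   records$endpoint == endpoint, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no %s records at %g C", endpoint, temperature),
         call. = FALSE)
  }
  pct <- 100 * sub$n_succeeded / sub$n_exposed
  list(mean_pct = mean(pct), replicate_pct = pct)
}

#' Viability summary across temperatures and endpoints
#'
#' Runs [proportion_estimate()] for every (temperature, endpoint) combination
#' present in the records.
#'
#' @param records Viability records.
#' @return Data frame with `temperature`, `endpoint`, `n_replicates`,
#'   `mean_pct` (and `mean_pct_1dp` at the customary 0.1 percent precision).
#' @export
summarize_viability <- function(records) {
  validate_viability(records)
  combos <- unique(records[c("temperature", "endpoint")])
  combos <- combos[order(combos$endpoint, combos$temperature), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    est <- proportion_estimate(records, combos$temperature[i],
                               combos$endpoint[i])
    data.frame(temperature = combos$temperature[i],
               endpoint = combos$endpoint[i],
               n_replicates = length(est$replicate_pct),
               mean_pct = est$mean_pct,
               mean_pct_1dp = round(est$mean_pct, 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
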