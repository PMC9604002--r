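# Shared fixture builders; all fixtures are constructed in code.

# Long-format development observations from per-(stage, temperature) means,
# one observation per cell (the group-mean fitting route on printed means).
obs_from_means <- function(means, stages = unique(means$stage)) {
  sub <- means[means$stage %in% stages, ]
  data.frame(individual_id = paste0("m", seq_len(nrow(sub))),
             stage = sub$stage, temperature = sub$temperature,
             duration = sub$mean_days)
}

# Reference means restricted to the linear fitting window.
ref_means_window <- function(temps = c(20, 24, 28, 32)) {
  m <- sf_development_times()
  m[m$temperature %in% temps, ]
}

# Constant-temperature daily series of n days.
const_series <- function(temp, n, start = as.Date("2021-06-01")) {
  temperature_series(seq(start, by = 1, length.out = n), t_min = temp)
}

# Brute-force OLS: sum of squared residuals minimised over a grid of
# (slope, intercept) pairs centred on `centre`; returns the grid argmin and
# the grid resolution. Independent of the closed-form normal equations.
grid_ols <- function(x, y, centre, half_width = c(0.005, 0.1), n_grid = 81) {
  slopes <- seq(centre[1] - half_width[1], centre[1] + half_width[1],
                length.out = n_grid)
  intercepts <- seq(centre[2] - half_width[2], centre[2] + half_width[2],
                    length.out = n_grid)
  ss <- outer(slopes, intercepts,
              Vectorize(function(a, b) sum((y - (a * x + b))^2)))
  k <- arrayInd(which.min(ss), dim(ss))
  list(slope = slopes[k[1]], intercept = intercepts[k[2]],
       res = c(diff(slopes)[1], diff(intercepts)[1]),
       min_ss = min(ss))
}
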