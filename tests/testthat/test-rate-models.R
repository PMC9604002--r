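test_that("development rate is the reciprocal duration", {
  expect_equal(development_rate(2), 0.5)
  expect_equal(development_rate(1), 1)
  # reference egg mean at 20 C
  expect_equal(development_rate(7.1), 0.1408451, tolerance = 1e-6)
  expect_error(development_rate(0), "positive")
  expect_error(development_rate(-3), "positive")
})

test_that("two points are fitted exactly", {
  obs <- data.frame(individual_id = 1:2, stage = "egg",
                    temperature = c(20, 30), duration = c(10, 5))
  m <- fit_stage_model(obs, "egg", temperatures = c(20, 30))
  expect_equal(m$slope, 0.01)
  expect_equal(m$intercept, -0.1)
  expect_equal(m$r_squared, 1)
  expect_equal(m$ltt, 10)
})

test_that("group-mean fit on reference egg means recovers the published slope", {
  obs <- obs_from_means(ref_means_window(), "egg")
  m <- fit_stage_model(obs, "egg", fit_level = "group_mean")
  expect_equal(m$slope, 0.0289, tolerance = 0.0005 / 0.0289)
  expect_equal(round(m$ltt, 1), 15.8)  # refit LTT; printed-coefficient LTT is 15.7
  expect_gt(m$r_squared, 0.95)
})

test_that("closed-form OLS agrees with lm() and a brute-force grid minimiser", {
  set.seed(42)
  for (n in c(4, 17, 50)) {
    x <- runif(n, 18, 34)
    y <- 0.03 * x - 0.45 + rnorm(n, 0, 0.02)
    obs <- data.frame(individual_id = seq_len(n), stage = "pupa",
                      temperature = x, duration = 1 / pmax(y, 0.01))
    m <- fit_stage_model(obs, "pupa", temperatures = unique(x))
    ref <- stats::lm(I(1 / obs$duration) ~ x)
    expect_equal(m$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(m$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
    g <- grid_ols(x, 1 / obs$duration, centre = c(m$slope, m$intercept))
    expect_lt(abs(g$slope - m$slope), g$res[1])
    expect_lt(abs(g$intercept - m$intercept), g$res[2])
    ss_fit <- sum((1 / obs$duration - (m$slope * x + m$intercept))^2)
    expect_lte(ss_fit, g$min_ss + 1e-12)
  }
})

test_that("lower threshold is -intercept/slope and matches published values", {
  ref <- sf_rate_lines()
  for (i in seq_len(nrow(ref))) {
    expect_equal(round(lower_threshold(ref$slope[i], ref$intercept[i]), 1),
                 ref$ltt[i])
  }
  expect_equal(lower_threshold(0.1, 0), 0)
  expect_error(lower_threshold(0, -0.4), "slope is zero")
  m <- stage_rate_model("egg", 0.0289, -0.4536)
  expect_equal(lower_threshold(m), -(-0.4536) / 0.0289)
  # the fitted line evaluates to exactly zero rate at the threshold
  expect_lt(abs(m$slope * m$ltt + m$intercept), 1e-12)
})

test_that("thermal requirement averages per-temperature degree-day means", {
  # single observation: duration 10 d at 10 C above threshold -> 100 DD
  one <- data.frame(individual_id = "a", stage = "egg", temperature = 24,
                    duration = 10)
  tr <- thermal_requirement(one, "egg", ltt = 14, temperatures = 24)
  expect_equal(tr$trd_mean, 100)
  expect_equal(tr$trd_sd, 0)
  # reference egg-to-adult totals with the published-coefficient LTT
  tot <- obs_from_means(ref_means_window(), "egg_to_adult")
  ltt <- lower_threshold(0.0034, -0.0490)
  tr2 <- thermal_requirement(tot, "egg_to_adult", ltt)
  expect_lt(abs(tr2$trd_mean - 285.3), 0.3)
  expect_error(thermal_requirement(tot, "egg_to_adult", ltt = 21),
               "at or below the lower threshold")
})

test_that("noise-free data on a line are recovered to machine precision", {
  a <- 0.03
  b <- -0.45
  temps <- c(20, 24, 28, 32)
  cfg <- synth_config(rate_lines = data.frame(stage = "egg", slope = a,
                                              intercept = b),
                      temperatures = temps, n_per_temperature = 5,
                      duration_noise_sd = c(egg = 0), rounding = "none",
                      seed = 3)
  obs <- gen_development(cfg)
  for (level in c("individual", "group_mean")) {
    m <- fit_stage_model(obs, "egg", temps, fit_level = level)
    expect_equal(m$slope, a, tolerance = 1e-9)
    expect_equal(m$intercept, b, tolerance = 1e-9)
    expect_equal(m$r_squared, 1, tolerance = 1e-9)
    expect_equal(m$ltt, -b / a, tolerance = 1e-9)
    expect_equal(m$trd_mean, 1 / a, tolerance = 1e-9)
    expect_equal(m$trd_sd, 0, tolerance = 1e-9)
  }
  # predicted duration 1/(aT+b) strictly decreases above the threshold
  grid_t <- seq(-b / a + 0.5, 40, by = 0.5)
  expect_true(all(diff(1 / (a * grid_t + b)) < 0))
})

test_that("individual-level fit recovers generating parameters within 3 SE", {
  a <- 0.03
  b <- -0.45
  cfg <- synth_config(rate_lines = data.frame(stage = "pupa", slope = a,
                                              intercept = b),
                      n_per_temperature = 30,
                      duration_noise_sd = c(pupa = 0.3), rounding = "none",
                      seed = 17)
  obs <- gen_development(cfg)  # 120 individuals over 4 temperatures
  expect_equal(nrow(obs), 120)
  m <- fit_stage_model(obs, "pupa", fit_level = "individual")
  ref <- stats::lm(I(1 / duration) ~ temperature, data = obs)
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_lt(abs(m$slope - a), 3 * se["temperature"])
  expect_lt(abs(m$intercept - b), 3 * se["(Intercept)"])
})

test_that("degenerate fitting inputs raise errors", {
  one_t <- data.frame(individual_id = 1:3, stage = "egg", temperature = 24,
                      duration = c(4, 5, 4))
  expect_error(fit_stage_model(one_t, "egg"), "2 distinct temperatures")
  expect_error(fit_stage_model(one_t, "moth"), "unknown stage")
})

test_that("composite larvae stage sums the six instars per individual", {
  means <- ref_means_window()
  # two synthetic individuals per temperature carrying all instars
  rows <- list()
  for (temp in c(20, 24, 28, 32)) {
    for (id in c("a", "b")) {
      sub <- means[means$temperature == temp &
                     means$stage %in% paste0("L", 1:6), ]
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = paste0(id, temp), stage = sub$stage,
        temperature = temp, duration = sub$mean_days)
    }
  }
  obs <- do.call(rbind, rows)
  m <- fit_stage_model(obs, "larvae", fit_level = "group_mean")
  # published composite-larvae coefficients: 0.0070x - 0.0964; rounding of
  # the tabulated instar means limits agreement to ~5% on the slope
  expect_equal(m$slope, 0.0070, tolerance = 0.05)
  expect_lt(abs(m$ltt - 13.8), 0.5)
  # an individual missing an instar is excluded from the composite
  obs2 <- obs[!(obs$individual_id == "a20" & obs$stage == "L3"), ]
  d <- phenodd:::stage_durations(obs2, "larvae")
  expect_false("a20" %in% d$individual_id)
})

test_that("fit_rate_models assembles the regression summary table", {
  obs <- obs_from_means(ref_means_window())
  tab <- fit_rate_models(obs, stages = c("egg", "pupa", "egg_to_adult"),
                         fit_level = "group_mean")
  expect_equal(tab$stage, c("egg", "pupa", "egg_to_adult"))
  expect_true(all(tab$slope > 0))
  expect_equal(tab$slope_4dp, round(tab$slope, 4))
  expect_equal(tab$ltt_1dp, round(-tab$intercept / tab$slope, 1))
})
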