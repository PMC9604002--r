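test_that("daily degree-days use the min/max average, clamped at zero", {
  expect_equal(daily_degree_days(24, 24, 14.4), 9.6)
  expect_equal(daily_degree_days(10, 18.8, 14.4), 0)  # mean == threshold
  expect_equal(daily_degree_days(5, 10, 14.4), 0)     # below, not negative
  expect_equal(daily_degree_days(18, 26, 14.4), 7.6)  # diurnal series
  expect_error(daily_degree_days(26, 18, 14.4), "t_min > t_max")
})

test_that("constant-temperature forecast matches observed rearing duration", {
  ltt <- lower_threshold(0.0034, -0.0490)
  tot <- obs_from_means(ref_means_window(), "egg_to_adult")
  trd <- thermal_requirement(tot, "egg_to_adult", ltt)$trd_mean
  s <- const_series(24, 60)
  fc <- forecast_emergence(s, s$date[1], ltt, trd)
  expect_lt(abs(fc$duration_days - 29.5), 1)  # observed 29.5 d at 24 C
  expect_equal(fc$predicted_date, s$date[fc$duration_days])
  expect_true(all(diff(fc$cumulative_dd) >= 0))
})

test_that("forecast edge cases: one-day completion and cold series", {
  s <- const_series(24.4, 10)
  fc <- forecast_emergence(s, s$date[1], ltt = 14.4, trd = 10)
  expect_equal(fc$duration_days, 1)  # T = ltt + trd completes in one day
  cold <- const_series(12, 30)
  expect_error(forecast_emergence(cold, cold$date[1], 14.4, 50),
               "insufficient thermal accumulation.*50.0")
  short <- const_series(24, 5)
  err <- expect_error(forecast_emergence(short, short$date[1], 14.4, 285.3),
                      "insufficient thermal accumulation")
  expect_match(conditionMessage(err), "237.3")  # shortfall is reported
  expect_error(forecast_emergence(short, as.Date("2020-01-01"), 14.4, 10),
               "not in the temperature series")
})

test_that("forecast equals the closed form ceil(trd/(T-ltt)) on a grid", {
  for (temp in c(18, 22, 26, 30, 34)) {
    for (ltt in c(10, 12.4, 14.4, 15.7)) {
      for (trd in c(17.3, 34.3, 113.4, 285.3)) {
        s <- const_series(temp, 400)
        expected <- ceiling(trd / (temp - ltt))
        fc <- forecast_emergence(s, s$date[1], ltt, trd)
        expect_equal(fc$duration_days, expected)
      }
    }
  }
})

test_that("forecast is translation-invariant and monotone", {
  cfg <- synth_config(weather = list(base = 24, amplitude = 4, period = 120,
                                     diurnal_range = 8, noise_sd = 1),
                      seed = 5)
  s <- gen_weather(cfg, "2021-08-01", 90)
  fc <- forecast_emergence(s, s$date[10], ltt = 14.4, trd = 150)
  # shift all dates by 17 days: prediction shifts by exactly 17 days
  s_shift <- temperature_series(s$date + 17, s$t_min, s$t_max)
  fc_shift <- forecast_emergence(s_shift, s$date[10] + 17, 14.4, 150)
  expect_equal(as.integer(fc_shift$predicted_date - fc$predicted_date), 17)
  # raising any single day's temperatures never delays the prediction
  for (k in c(12, 20, 35)) {
    warm <- s
    warm$t_min[k] <- warm$t_min[k] + 5
    warm$t_max[k] <- warm$t_max[k] + 5
    fc_w <- forecast_emergence(warm, s$date[10], 14.4, 150)
    expect_lte(as.numeric(fc_w$predicted_date), as.numeric(fc$predicted_date))
  }
  # larger requirement never yields an earlier prediction
  fc_big <- forecast_emergence(s, s$date[10], 14.4, 180)
  expect_gte(as.numeric(fc_big$predicted_date), as.numeric(fc$predicted_date))
})

test_that("stagewise chaining reproduces per-stage durations at 28 C", {
  means <- ref_means_window()
  ref <- sf_rate_lines()
  stages <- c("egg", paste0("L", 1:6), "pupa")
  models <- lapply(stages, function(st) {
    r <- ref[ref$stage == st, ]
    ltt <- lower_threshold(r$slope, r$intercept)
    trd <- thermal_requirement(obs_from_means(means, st), st, ltt)$trd_mean
    stage_rate_model(st, r$slope, r$intercept, trd_mean = trd)
  })
  s <- const_series(28, 120)
  chain <- forecast_stagewise(s, s$date[1], models)
  expect_equal(chain$stage, stages)
  obs28 <- means[means$temperature == 28 & means$stage %in% stages, ]
  for (i in seq_along(stages)) {
    expect_lt(abs(chain$duration_days[i] -
                    obs28$mean_days[obs28$stage == stages[i]]), 1)
  }
  # stage starts chain day-after-completion
  expect_equal(chain$start_date[-1], chain$completion_date[-nrow(chain)] + 1)
  # single-stage list reduces to forecast_emergence
  solo <- forecast_stagewise(s, s$date[1], models[1])
  fc <- forecast_emergence(s, s$date[1], models[[1]]$ltt,
                           models[[1]]$trd_mean)
  expect_equal(solo$completion_date, fc$predicted_date)
  # chained total is at most 1 day per boundary longer than the composite
  comp <- ref[ref$stage == "egg_to_adult", ]
  ltt_c <- lower_threshold(comp$slope, comp$intercept)
  trd_c <- thermal_requirement(obs_from_means(means, "egg_to_adult"),
                               "egg_to_adult", ltt_c)$trd_mean
  fc_c <- forecast_emergence(s, s$date[1], ltt_c, trd_c)
  total_chained <- sum(chain$duration_days)
  expect_gte(total_chained, fc_c$duration_days - length(models))
})

test_that("forecast deviation reproduces the field-validation scores", {
  ecl <- sf_observed_eclosion()
  expected <- list(Cheongju = c(2, 4), Boeun = c(-1, 1), Taean = c(4, 6))
  for (loc in names(expected)) {
    sub <- ecl[ecl$location == loc, ]
    dev <- forecast_deviation(sub$predicted_date[1], sub$observed_date)
    expect_equal(dev$deviation_min, expected[[loc]][1])
    expect_equal(dev$deviation_max, expected[[loc]][2])
  }
  same <- forecast_deviation(as.Date("2021-09-22"), as.Date("2021-09-22"))
  expect_equal(c(same$deviation_min, same$deviation_max), c(0, 0))
  expect_error(forecast_deviation(as.Date("2021-09-22"), as.Date(character())),
               "non-empty")
})

test_that("oviposition back-calculation inverts the forward forecast", {
  cfg <- synth_config(weather = list(base = 23, amplitude = 3, period = 200,
                                     diurnal_range = 6, noise_sd = 0.5),
                      seed = 9)
  s <- gen_weather(cfg, "2021-08-01", 80)
  fc <- forecast_emergence(s, s$date[5], ltt = 14.4, trd = 285.3)
  back <- backcast_oviposition(s, fc$predicted_date, 14.4, 285.3)
  # inverting from the predicted emergence recovers the start to <= 1 day
  expect_lte(abs(as.integer(back - s$date[5])), 1)
  expect_error(backcast_oviposition(s, s$date[3], 14.4, 285.3),
               "insufficient thermal accumulation")
})
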