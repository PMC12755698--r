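test_that("zero-noise DGP reproduces the seasonal curve and constant PM exactly", {
  dgp <- exposure_dgp(temp_sd = 0, pm_log_sd = 0, n_areas = 2,
                      date_start = "2010-06-01", date_end = "2010-07-31")
  ex <- simulate_exposures(dgp, seed = 1)
  expect_equal(ex$tmax, seasonal_mean_temp(as.POSIXlt(ex$date)$yday + 1, dgp))
  expect_equal(ex$pm25, rep(exp(dgp$pm_log_mean), nrow(ex)))
})

test_that("exposure generation is reproducible, ordered and positive", {
  dgp <- exposure_dgp(n_areas = 3, date_start = "2010-01-01",
                      date_end = "2010-03-01")
  a <- simulate_exposures(dgp, seed = 9)
  b <- simulate_exposures(dgp, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulate_exposures(dgp, seed = 10)))
  expect_identical(a, dplyr::arrange(a, area_id, date))
  expect_true(all(a$pm25 > 0))
  # one record per (area, date), contiguous dates
  expect_equal(nrow(dplyr::distinct(a, area_id, date)), nrow(a))
  gaps <- a |> dplyr::group_by(area_id) |>
    dplyr::summarise(ok = all(diff(as.integer(date)) == 1))
  expect_true(all(gaps$ok))
})

test_that("temperature-PM correlation tracks the configured value", {
  # 50 areas x 20 warm seasons, zero configured correlation
  dgp0 <- exposure_dgp(temp_pm_corr = 0, n_areas = 50,
                       date_start = "1997-01-01", date_end = "2016-12-31")
  ex <- simulate_exposures(dgp0, seed = 4)
  warm <- ex[(as.POSIXlt(ex$date)$mon + 1) %in% 6:9, ]
  dev <- warm$tmax - seasonal_mean_temp(as.POSIXlt(warm$date)$yday + 1, dgp0)
  expect_lt(abs(cor(dev, log(warm$pm25))), 0.02)

  # positive default correlation is recovered
  dgp3 <- exposure_dgp(n_areas = 20, date_start = "2008-01-01",
                       date_end = "2012-12-31")
  ex3 <- simulate_exposures(dgp3, seed = 5)
  dev3 <- ex3$tmax - seasonal_mean_temp(as.POSIXlt(ex3$date)$yday + 1, dgp3)
  expect_equal(cor(dev3, log(ex3$pm25)), 0.3, tolerance = 0.02)
})

test_that("default DGP reproduces the warm-season exposure moments it emulates", {
  # >= 1e5 warm-season area-days
  dgp <- exposure_dgp(n_areas = 100)
  ex <- simulate_exposures(dgp, seed = 2)
  w <- add_exposure_windows(ex)
  warm <- w[(as.POSIXlt(w$date)$mon + 1) %in% 6:9, ]
  expect_gte(nrow(warm), 1e5)
  expect_equal(mean(warm$tmax), 29.2, tolerance = 0.2)
  expect_equal(sd(warm$tmax), 5.0, tolerance = 0.2)
  # 3-day PM2.5, trimmed at its own 95th percentile
  pm3 <- warm$pm25_w[!is.na(warm$pm25_w)]
  keep <- pm3[pm3 <= trim_threshold(pm3, 0.95)]
  expect_equal(mean(keep), 9.4, tolerance = 0.2)
  expect_equal(sd(keep), 3.7, tolerance = 0.2)
})

test_that("degenerate and invalid DGP configurations are rejected or empty", {
  expect_error(exposure_dgp(n_areas = 0), class = "heatpm_invalid_config")
  expect_error(exposure_dgp(date_start = "2010-02-01",
                            date_end = "2010-01-01"),
               class = "heatpm_invalid_config")
  expect_error(exposure_dgp(ar_coef = 1), class = "heatpm_invalid_config")
  expect_error(exposure_dgp(temp_pm_corr = 1),
               class = "heatpm_invalid_config")
  ex <- simulate_exposures(exposure_dgp(n_areas = 2,
                                        date_start = "2010-06-01",
                                        date_end = "2010-07-31"), seed = 1)
  ev <- simulate_events(ex, hazard_dgp(alpha = -50), 500, seed = 1)
  expect_equal(nrow(ev), 0)
})

test_that("null-hazard event rate matches the configured daily probability", {
  ex <- simulate_exposures(exposure_dgp(n_areas = 5,
                                        date_start = "2010-06-01",
                                        date_end = "2010-09-30"), seed = 3)
  hz <- hazard_dgp(alpha = qlogis(0.001), beta_T = 0, beta_P = 0,
                   beta_TP = 0)
  n_persons <- 20000
  ev <- simulate_events(ex, hz, n_persons, seed = 4)
  # person-days at risk: up to (and including) the first event; the first
  # two days of each series lack PM window coverage and carry no hazard
  n_days <- length(unique(ex$date)) - 2
  days_at_risk <- rep(n_days, n_persons)
  idx <- match(ev$admission_date,
               sort(unique(ex$date))[-(1:2)]) # day index among valid days
  days_at_risk[ev$person_id] <- idx
  rate <- nrow(ev) / sum(days_at_risk)
  se <- sqrt(0.001 * 0.999 / sum(days_at_risk))
  expect_lt(abs(rate - 0.001), 3 * se)
})

test_that("temperature slope reproduces the implied event frequency ratio", {
  ex <- simulate_exposures(exposure_dgp(n_areas = 20,
                                        date_start = "2010-06-01",
                                        date_end = "2010-09-30"), seed = 6)
  hz <- hazard_dgp(alpha = qlogis(1e-4) - 0.05 * 30, beta_T = 0.05,
                   beta_P = 0, beta_TP = 0)
  n_persons <- 300000
  ev <- simulate_events(ex, hz, n_persons, seed = 7)
  w <- add_exposure_windows(ex)
  w <- w[!is.na(w$pm25_w), ]
  per_area <- n_persons / length(unique(ex$area_id))
  in_bin <- function(x, c) abs(x - c) <= 0.5
  joined <- dplyr::inner_join(ev, w, by = c("area_id",
                                            "admission_date" = "date"))
  n35 <- sum(in_bin(joined$tmax_w, 35))
  n25 <- sum(in_bin(joined$tmax_w, 25))
  d35 <- sum(in_bin(w$tmax_w, 35)) * per_area
  d25 <- sum(in_bin(w$tmax_w, 25)) * per_area
  log_ratio <- log((n35 / d35) / (n25 / d25))
  se <- sqrt(1 / n35 + 1 / n25)
  expect_lt(abs(log_ratio - 0.5), 3 * se)
})

test_that("only first events are emitted, reproducibly, with dx flags", {
  ex <- simulate_exposures(exposure_dgp(n_areas = 5,
                                        date_start = "2010-06-01",
                                        date_end = "2010-09-30"), seed = 8)
  hz <- hazard_dgp(alpha = qlogis(0.05), beta_T = 0, beta_P = 0,
                   beta_TP = 0) # high rate: repeat events would be likely
  ev <- simulate_events(ex, hz, 2000, seed = 9)
  expect_gt(nrow(ev), 1000)
  expect_equal(anyDuplicated(ev$person_id), 0)
  expect_identical(ev, simulate_events(ex, hz, 2000, seed = 9))
  expect_type(ev$primary_dx, "logical")
  expect_equal(mean(ev$primary_dx), 0.532, tolerance = 0.05)
})

test_that("a hazard violating the rare-outcome assumption warns", {
  ex <- simulate_exposures(exposure_dgp(n_areas = 2,
                                        date_start = "2010-06-01",
                                        date_end = "2010-07-31"), seed = 1)
  expect_warning(
    simulate_events(ex, hazard_dgp(alpha = qlogis(0.7), beta_T = 0,
                                   beta_P = 0, beta_TP = 0), 10, seed = 1),
    class = "heatpm_rare_outcome_violated")
})

test_that("true_effects matches the closed form and ignores the baseline", {
  ct <- contrast_spec(t0 = 29.6, t1 = 36.9, p0 = 8.9, p1 = 16.1)
  null <- true_effects(hazard_dgp(beta_T = 0, beta_P = 0, beta_TP = 0), ct)
  expect_equal(unlist(null), c(or10 = 1, or01 = 1, or11 = 1, reri = 0))

  # worked closed form: OR11 = exp(0.01*7.3 + 0.002*7.2) = exp(0.0874)
  h <- hazard_dgp(beta_T = 0.01, beta_P = 0.002, beta_TP = 0)
  te <- true_effects(h, ct)
  expect_equal(te$or11, exp(0.0874), tolerance = 1e-12)
  expect_equal(te$reri, exp(0.0874) - exp(0.073) - exp(0.0144) + 1,
               tolerance = 1e-12)

  # alpha invariance and positive-interaction monotonicity
  for (a in c(-9, -3, 0, 2)) {
    h2 <- hazard_dgp(alpha = a, beta_T = 0.01, beta_P = 0.002,
                     beta_TP = 0)
    expect_equal(true_effects(h2, ct), te)
  }
  for (b in c(1e-4, 1e-3, 5e-3)) {
    h3 <- hazard_dgp(beta_T = 0, beta_P = 0, beta_TP = b)
    expect_gt(true_effects(h3, ct)$reri, 0)
  }
})
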