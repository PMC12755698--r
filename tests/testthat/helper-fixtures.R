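# deterministic small exposure series (no RNG): 2 areas, smooth wiggles
toy_exposures <- function(start = "2010-06-01", days = 40, areas = 1:2) {
  dates <- seq(as.Date(start), by = "day", length.out = days)
  tidyr::expand_grid(area_id = areas, date = dates) |>
    dplyr::mutate(
      tmax = 25 + 5 * sin(as.integer(.data$date) / 5) + .data$area_id,
      pm25 = 8 + 3 * cos(as.integer(.data$date) / 7) + 0.5 * .data$area_id
    )
}

# matched strata drawn directly from the conditional model: within each
# stratum the case row is sampled with probability softmax(eta), so the
# conditional-logistic likelihood is exactly correct by construction
sim_strata <- function(n_sets, beta = c(0.05, 0.02, 0.003), m = 5,
                       seed = 1) {
  set.seed(seed)
  n <- n_sets * m
  t <- rnorm(n, 30, 4)
  p <- exp(rnorm(n, log(9), 0.5))
  eta <- beta[1] * t + beta[2] * p + beta[3] * t * p
  set_id <- rep(seq_len(n_sets), each = m)
  is_case <- integer(n)
  for (s in seq_len(n_sets)) {
    i <- which(set_id == s)
    w <- exp(eta[i] - max(eta[i]))
    is_case[i[sample.int(m, 1, prob = w)]] <- 1L
  }
  tibble::tibble(set_id = set_id, is_case = is_case, tmax_w = t, pm25_w = p)
}

linear_model <- function() {
  model_spec(temp = spline_spec(1), pm = spline_spec(1))
}

# small end-to-end analysis table: one warm season, 20 areas
small_analysis <- function(seed = 301, n_persons = 1300,
                           hazard = hazard_dgp(alpha = qlogis(0.0015)),
                           trim_quantile = 0.95) {
  dgp <- exposure_dgp(n_areas = 20, date_start = "2010-05-25",
                      date_end = "2010-09-30")
  ex <- simulate_exposures(dgp, seed = seed)
  ev <- simulate_events(ex, hazard, n_persons, seed = seed + 1)
  suppressMessages(
    trim_extreme_pm(build_matched_sets(select_cases(ev), ex), trim_quantile)
  )
}

# reference conditional-logit fit via survival::clogit on a cc_design
clogit_reference <- function(design) {
  library(survival) # clogit() expands to an unqualified coxph() call
  df <- data.frame(y = as.integer(design$is_case), g = design$set_id,
                   design$X, check.names = TRUE)
  xn <- setdiff(names(df), c("y", "g"))
  fml <- stats::as.formula(paste("y ~", paste(xn, collapse = " + "),
                                 "+ strata(g)"))
  fit <- survival::clogit(fml, data = df,
                          control = survival::coxph.control(
                            eps = 1e-11, toler.chol = 1e-13,
                            iter.max = 50))
  stats::coef(fit)
}

# draw-level OR via the exported surface evaluator (test-side oracle path)
or_draws_via_surface <- function(fit, t1, p1, t0, p0) {
  lo <- log_odds_surface(fit, c(t1, t0), c(p1, p0),
                         warn_extrapolation = FALSE)
  drop(exp(lo[1, ] - lo[2, ]))
}
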