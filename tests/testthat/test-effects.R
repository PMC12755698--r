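make_linear_fit <- function(beta = c(0.05, 0.02, 0.003), n_sets = 40,
                            seed = 61) {
  an <- sim_strata(n_sets, beta = beta, seed = seed)
  d <- build_design(an, linear_model())
  manual_draws(d, beta)
}

test_that("odds ratios match the closed form on a known coefficient vector", {
  fit <- make_linear_fit()
  ct <- contrast_spec(t0 = 29.6, t1 = 36.9, p0 = 8.9, p1 = 16.1)
  # identity contrast
  id <- odds_ratio(fit, ct$t0, ct$p0, ct$t0, ct$p0)
  expect_equal(id$estimate, 1)
  expect_equal(id$conf.low, 1)
  expect_equal(id$conf.high, 1)
  # null coefficients
  null <- manual_draws(fit$design, c(0, 0, 0))
  expect_equal(odds_ratio(null, ct$t1, ct$p1, ct$t0, ct$p0)$estimate, 1)
  # closed form
  or <- odds_ratio(fit, ct$t1, ct$p1, ct$t0, ct$p0)
  lo <- function(t, p) 0.05 * t + 0.02 * p + 0.003 * t * p
  expect_equal(or$estimate, exp(lo(36.9, 16.1) - lo(29.6, 8.9)),
               tolerance = 1e-12)
})

test_that("per-draw log odds are antisymmetric and transitive", {
  an <- sim_strata(40, seed = 63)
  d <- build_design(an, model_spec())
  set.seed(64)
  fit <- manual_draws(d, matrix(rnorm(9 * 25, sd = 0.1), 25, 9))
  pts <- list(c(28, 8), c(33, 12), c(37, 16))
  lo <- function(a, b) {
    log(or_draws_via_surface(fit, a[1], a[2], b[1], b[2]))
  }
  ab <- lo(pts[[1]], pts[[2]])
  ba <- lo(pts[[2]], pts[[1]])
  bc <- lo(pts[[2]], pts[[3]])
  ac <- lo(pts[[1]], pts[[3]])
  expect_equal(ab, -ba, tolerance = 1e-12)
  expect_equal(ac, ab + bc, tolerance = 1e-12)
})

test_that("RERI summaries satisfy the defining identity and match truth", {
  # plug-in arithmetic on published-scale ORs
  expect_equal(round(reri_plugin(1.09, 1.05, 1.01), 2), 0.03)
  # null model: RERI exactly zero with a zero-width interval
  fit0 <- manual_draws(make_linear_fit()$design, c(0, 0, 0))
  er0 <- estimate_reri(fit0, contrast_spec(29, 36, 9, 16))
  expect_equal(er0$estimate[er0$quantity == "reri"], 0)
  expect_equal(er0$conf.low[er0$quantity == "reri"], 0)
  # linear DGP coefficients as a single draw reproduce true_effects
  beta <- c(0.05, 0.02, 0.003)
  fit <- make_linear_fit(beta)
  ct <- contrast_spec(29.6, 36.9, 8.9, 16.1)
  er <- estimate_reri(fit, ct)
  te <- true_effects(hazard_dgp(alpha = -7, beta_T = beta[1],
                                beta_P = beta[2], beta_TP = beta[3]), ct)
  expect_equal(er$estimate[er$quantity == "or_temp"], te$or10,
               tolerance = 1e-12)
  expect_equal(er$estimate[er$quantity == "or_pm"], te$or01,
               tolerance = 1e-12)
  expect_equal(er$estimate[er$quantity == "or_joint"], te$or11,
               tolerance = 1e-12)
  expect_equal(er$estimate[er$quantity == "reri"], te$reri,
               tolerance = 1e-12)
  expect_equal(er$estimate[er$quantity == "reri_plugin"], te$reri,
               tolerance = 1e-12)
})

test_that("the RERI identity holds for every draw of a posterior sample", {
  an <- sim_strata(40, seed = 67)
  d <- build_design(an, model_spec())
  set.seed(68)
  # moderate coefficients (ORs near 1) so the identity is testable at
  # floating-point precision
  dr <- cbind(matrix(rnorm(8 * 50, sd = 0.1), 50, 8),
              rnorm(50, sd = 0.002))
  fit <- manual_draws(d, dr)
  ct <- contrast_spec(28, 35, 8, 15)
  or11 <- or_draws_via_surface(fit, ct$t1, ct$p1, ct$t0, ct$p0)
  or10 <- or_draws_via_surface(fit, ct$t1, ct$p0, ct$t0, ct$p0)
  or01 <- or_draws_via_surface(fit, ct$t0, ct$p1, ct$t0, ct$p0)
  reri <- or11 - or10 - or01 + 1
  expect_equal(reri + or10 + or01 - or11, rep(1, 50), tolerance = 1e-12)
  # summary path agrees with the draw-level computation
  er <- estimate_reri(fit, ct)
  expect_equal(er$estimate[er$quantity == "reri"], mean(reri))
  expect_equal(er$conf.low[er$quantity == "reri"],
               unname(quantile(reri, 0.025)))
})

test_that("multiplicative interaction is the exponentiated product coefficient", {
  d <- make_linear_fit()$design
  expect_equal(
    multiplicative_interaction(manual_draws(d, c(0.1, 0.1, 0)))$estimate, 1)
  expect_equal(
    multiplicative_interaction(manual_draws(d, c(0, 0, log(2))))$estimate, 2)
  # quantile oracle on a spread of draws
  set.seed(69)
  dr <- cbind(rnorm(200), rnorm(200), rnorm(200, sd = 0.01))
  mi <- multiplicative_interaction(manual_draws(d, dr))
  expect_equal(mi$estimate, mean(exp(dr[, 3])))
  expect_equal(mi$conf.low, unname(quantile(exp(dr[, 3]), 0.025)))
  expect_equal(mi$conf.high, unname(quantile(exp(dr[, 3]), 0.975)))
  # undefined for the tensor model
  an <- sim_strata(40, seed = 70)
  dt <- build_design(an, model_spec(interaction = "tensor_product"))
  expect_error(
    multiplicative_interaction(manual_draws(dt, rep(0, ncol(dt$X)))),
    class = "heatpm_unsupported_model")
})

test_that("the OR grid equals cellwise odds ratios with a unit reference cell", {
  fit <- make_linear_fit()
  ct <- contrast_spec(30, 36, 9, 15)
  g <- or_grid(fit, ct, t_grid = c(28, 30, 34), p_grid = c(7, 9, 13))
  expect_equal(g$or[g$tmax == 30 & g$pm25 == 9], 1) # reference cell
  for (i in seq_len(nrow(g))) {
    cell <- odds_ratio(fit, g$tmax[i], g$pm25[i], ct$t0, ct$p0)
    expect_equal(g$or[i], cell$estimate, tolerance = 1e-12)
  }
  # null draws give an all-ones grid
  g0 <- or_grid(manual_draws(fit$design, c(0, 0, 0)), ct,
                t_grid = c(28, 32), p_grid = c(8, 12))
  expect_equal(g0$or, rep(1, 4))
})

test_that("OR curves pass through 1 at the reference exposure", {
  fit <- make_linear_fit()
  ct <- contrast_spec(30, 36, 9, 15)
  cv <- or_curve(fit, "temp", ct, grid = c(25, 30, 35))
  expect_equal(cv$estimate[cv$level == 30], 1)
  expect_s3_class(autoplot(cv), "ggplot")
  gg <- or_grid(fit, ct, t_grid = c(28, 32), p_grid = c(8, 12))
  expect_s3_class(autoplot(gg), "ggplot")
})

test_that("default contrasts are case-day medians and 95th percentiles", {
  an <- sim_strata(80, seed = 73)
  ct <- default_contrast(an)
  cs <- an[an$is_case == 1, ]
  expect_equal(ct$t0, unname(quantile(cs$tmax_w, 0.5)))
  expect_equal(ct$t1, unname(quantile(cs$tmax_w, 0.95)))
  expect_equal(ct$p0, unname(quantile(cs$pm25_w, 0.5)))
  expect_equal(ct$p1, unname(quantile(cs$pm25_w, 0.95)))
})
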