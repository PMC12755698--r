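#' Exposure contrast specification
#'
#' Reference `(t0, p0)` and comparison `(t1, p1)` exposure levels for odds
#' ratios and the RERI.  The conventional choice is the case-day median for
#' the reference and the case-day 95th percentile for the comparison; see
#' [default_contrast()].
#'
#' @param t0,t1 Reference and comparison temperature (degC).
#' @param p0,p1 Reference and comparison windowed PM2.5 (ug/m3).
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(t0, t1, p0, p1) {
  stopifnot(is.numeric(t0), is.numeric(t1), is.numeric(p0), is.numeric(p1))
  structure(list(t0 = t0, t1 = t1, p0 = p0, p1 = p1),
            class = "contrast_spec")
}

#' Default contrast: case-day median vs 95th percentile
#'
#' @param analysis Analysis tibble with `is_case`, `tmax_w`, `pm25_w`
#'   (the trimmed analysis sample).
#' @param probs Reference and comparison quantiles (default `c(0.5, 0.95)`).
#' @return A [contrast_spec()] computed from case days only.
#' @export
default_contrast <- function(analysis, probs = c(0.5, 0.95)) {
  stopifnot_cols(analysis, c("is_case", "tmax_w", "pm25_w"), "`analysis`")
  cs <- analysis[analysis$is_case == 1L, ]
  if (!nrow(cs)) abort("No case days in `analysis`.",
                       class = "heatpm_invalid_input")
  tq <- quantile(cs$tmax_w, probs, names = FALSE, type = 7)
  pq <- quantile(cs$pm25_w, probs, names = FALSE, type = 7)
  contrast_spec(t0 = tq[1], t1 = tq[2], p0 = pq[1], p1 = pq[2])
}

draws_of <- function(fit) {
  if (!inherits(fit, "cc_draws")) {
    abort("`fit` must be a cc_clogit_bayes / cc_draws object.",
          class = "heatpm_invalid_input")
  }
  fit$draws
}

#' Per-draw log-odds surface
#'
#' Evaluates the fitted model's basis at `(t, p)` and dots it with every
#' posterior draw, giving the log-odds relative to the model's implicit
#' baseline (which cancels in all contrasts).
#'
#' @param fit A `cc_clogit_bayes` or [manual_draws()] object.
#' @param t,p Exposure vectors of equal length.
#' @param warn_extrapolation Warn outside the boundary knots.
#' @return Matrix of dimension `length(t)` by `n_draws`.
#' @export
log_odds_surface <- function(fit, t, p, warn_extrapolation = TRUE) {
  draws <- draws_of(fit)
  rows <- design_rows(fit$design, t, p, warn_extrapolation)
  if (!identical(colnames(rows), colnames(draws))) {
    abort("Draw labels do not match the design columns.",
          class = "heatpm_invalid_input")
  }
  rows %*% t(draws)
}

# per-draw ORs of (t1,p1) vs (t0,p0); rows index the contrast points
or_draws <- function(fit, t1, p1, t0, p0, warn_extrapolation = FALSE) {
  n <- length(t1)
  lo <- log_odds_surface(fit, c(t1, rep(t0, length.out = n)),
                         c(p1, rep(p0, length.out = n)),
                         warn_extrapolation)
  exp(lo[seq_len(n), , drop = FALSE] -
        lo[n + seq_len(n), , drop = FALSE])
}

summarise_draws_vec <- function(x, quantity) {
  q <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  tibble(quantity = quantity, estimate = mean(x),
         conf.low = q[1], conf.high = q[2], n_draws = length(x))
}

#' Posterior odds ratio for an exposure contrast
#'
#' Per draw, `OR = exp(log-odds(t1, p1) - log-odds(t0, p0))`; summarized as
#' the posterior mean with an equal-tailed 95% credible interval.
#'
#' @param fit A `cc_clogit_bayes` or [manual_draws()] object.
#' @param t1,p1 Comparison exposure levels.
#' @param t0,p0 Reference exposure levels.
#' @param quantity Label for the output row.
#' @return A one-row tibble: `quantity`, `estimate`, `conf.low`,
#'   `conf.high`, `n_draws`.
#' @export
odds_ratio <- function(fit, t1, p1, t0, p0, quantity = "or") {
  or <- drop(or_draws(fit, t1, p1, t0, p0))
  summarise_draws_vec(or, quantity)
}

#' Plug-in RERI from three odds ratios
#'
#' `RERI = OR11 - OR10 - OR01 + 1`: the additive-scale excess of the joint
#' effect over the sum of the two lone effects, on the odds-ratio scale
#' (which approximates the risk-ratio RERI when the outcome is rare).
#'
#' @param or11 OR of the joint contrast.
#' @param or10 OR of the temperature-only contrast.
#' @param or01 OR of the PM2.5-only contrast.
#' @return The RERI (positive = super-additive synergy).
#' @examples
#' reri_plugin(1.09, 1.05, 1.01)  # 0.03
#' @export
reri_plugin <- function(or11, or10, or01) {
  or11 - or10 - or01 + 1
}

#' Posterior RERI and contrast odds ratios
#'
#' Per draw, computes the three ORs of the contrast grid referenced to
#' `(t0, p0)` -- temperature alone, PM2.5 alone, joint -- and
#' `RERI = OR11 - OR10 - OR01 + 1`.  Each is summarized as posterior mean
#' with equal-tailed 95% credible interval.  The plug-in variant (RERI of
#' the posterior-mean ORs) is reported alongside, labeled `reri_plugin`,
#' with no interval.
#'
#' @param fit A `cc_clogit_bayes` or [manual_draws()] object.
#' @param contrast A [contrast_spec()].
#' @return Tibble with rows `or_temp` (OR10), `or_pm` (OR01), `or_joint`
#'   (OR11), `reri`, `reri_plugin`.
#' @export
estimate_reri <- function(fit, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  or <- or_draws(fit,
                 t1 = c(contrast$t1, contrast$t0, contrast$t1),
                 p1 = c(contrast$p0, contrast$p1, contrast$p1),
                 t0 = contrast$t0, p0 = contrast$p0)
  reri <- or[3, ] - or[1, ] - or[2, ] + 1
  out <- bind_rows(
    summarise_draws_vec(or[1, ], "or_temp"),
    summarise_draws_vec(or[2, ], "or_pm"),
    summarise_draws_vec(or[3, ], "or_joint"),
    summarise_draws_vec(reri, "reri")
  )
  plug <- reri_plugin(out$estimate[out$quantity == "or_joint"],
                      out$estimate[out$quantity == "or_temp"],
                      out$estimate[out$quantity == "or_pm"])
  bind_rows(out, tibble(quantity = "reri_plugin", estimate = plug,
                        conf.low = NA_real_, conf.high = NA_real_,
                        n_draws = ncol(or)))
}

#' Multiplicative interaction odds ratio
#'
#' The exponentiated linear product-term coefficient: the multiplicative
#' interaction OR per 1 degC * ug/m3, summarized over draws.  Only defined
#' for the `linear_product` model.
#'
#' @param fit A `cc_clogit_bayes` or [manual_draws()] object.
#' @return A one-row tibble as [odds_ratio()].
#' @export
multiplicative_interaction <- function(fit) {
  draws <- draws_of(fit)
  if (fit$design$frozen$interaction != "linear_product") {
    abort("The multiplicative interaction OR is defined only for the linear-product model.",
          class = "heatpm_unsupported_model")
  }
  or <- exp(draws[, "tmax_x_pm25"])
  summarise_draws_vec(or, "or_interaction")
}

#' Exposure-response odds-ratio curve
#'
#' Posterior OR of each grid exposure level versus the reference, holding
#' the other exposure at its reference level.
#'
#' @param fit A `cc_clogit_bayes` or [manual_draws()] object.
#' @param exposure `"temp"` or `"pm"`.
#' @param grid Exposure levels; default 50 points across the boundary knots.
#' @param contrast A [contrast_spec()] giving the reference levels.
#' @return Tibble of class `cc_or_curve`: `exposure`, `level`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
or_curve <- function(fit, exposure = c("temp", "pm"), contrast,
                     grid = NULL) {
  exposure <- match.arg(exposure)
  stopifnot(inherits(contrast, "contrast_spec"))
  frozen <- fit$design$frozen
  if (is.null(grid)) {
    b <- if (exposure == "temp") frozen$temp$boundary else frozen$pm$boundary
    grid <- seq(b[1], b[2], length.out = 50)
  }
  if (exposure == "temp") {
    or <- or_draws(fit, t1 = grid, p1 = rep(contrast$p0, length(grid)),
                   t0 = contrast$t0, p0 = contrast$p0)
  } else {
    or <- or_draws(fit, t1 = rep(contrast$t0, length(grid)), p1 = grid,
                   t0 = contrast$t0, p0 = contrast$p0)
  }
  q <- apply(or, 1, quantile, c(0.025, 0.975), names = FALSE)
  out <- tibble(exposure = exposure, level = grid,
                estimate = rowMeans(or),
                conf.low = q[1, ], conf.high = q[2, ])
  class(out) <- c("cc_or_curve", class(out))
  attr(out, "reference") <- if (exposure == "temp") contrast$t0 else contrast$p0
  out
}

#' Posterior-mean odds-ratio grid over joint exposures
#'
#' For every `(t, p)` cell, the posterior-mean OR versus the reference cell
#' `(t0, p0)`; the reference cell itself is exactly 1.
#'
#' @param fit A `cc_clogit_bayes` or [manual_draws()] object.
#' @param t_grid,p_grid Exposure grids; default 25 points across the
#'   boundary knots.
#' @param contrast A [contrast_spec()] giving the reference `(t0, p0)`.
#' @return Tibble of class `cc_or_grid`: `tmax`, `pm25`, `or`.
#' @export
or_grid <- function(fit, contrast, t_grid = NULL, p_grid = NULL) {
  stopifnot(inherits(contrast, "contrast_spec"))
  frozen <- fit$design$frozen
  t_grid <- t_grid %||%
    seq(frozen$temp$boundary[1], frozen$temp$boundary[2], length.out = 25)
  p_grid <- p_grid %||%
    seq(frozen$pm$boundary[1], frozen$pm$boundary[2], length.out = 25)
  cells <- tidyr::expand_grid(tmax = t_grid, pm25 = p_grid)
  or <- or_draws(fit, t1 = cells$tmax, p1 = cells$pm25,
                 t0 = contrast$t0, p0 = contrast$p0)
  out <- mutate(cells, or = rowMeans(or))
  class(out) <- c("cc_or_grid", class(out))
  attr(out, "reference") <- c(t0 = contrast$t0, p0 = contrast$p0)
  out
}
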