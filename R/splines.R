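#' Natural cubic spline specification
#'
#' Describes one exposure's basis.  With `df = 1` the basis is the raw
#' (linear) exposure column -- the natural-spline space with no interior
#' knots is exactly the linear functions, and the raw column keeps
#' coefficients directly interpretable.  With `df > 1`, `df - 1` interior
#' knots are placed at equally spaced quantiles of the *case-day* exposure
#' values and boundary knots at the min/max of all analysis values, unless
#' given explicitly.
#'
#' @param df Basis dimension (default 4).
#' @param knots Optional interior knot locations (exposure units).
#' @param boundary Optional length-2 boundary knots.
#' @return A list of class `spline_spec`.
#' @export
spline_spec <- function(df = 4, knots = NULL, boundary = NULL) {
  df <- as.integer(df)
  if (df < 1) abort("`df` must be >= 1.", class = "heatpm_invalid_config")
  if (!is.null(knots) && length(knots) != df - 1) {
    abort("`knots` must have length `df - 1`.",
          class = "heatpm_invalid_config")
  }
  if (!is.null(boundary) &&
      (length(boundary) != 2 || boundary[1] >= boundary[2])) {
    abort("`boundary` must be c(min, max) with min < max.",
          class = "heatpm_invalid_config")
  }
  structure(list(df = df, knots = knots, boundary = boundary),
            class = "spline_spec")
}

#' Exposure-response model specification
#'
#' The primary model is `NCS(T) + NCS(P) + T*P`: a natural cubic spline per
#' exposure plus a single linear interaction column in raw units
#' (degC * ug/m3).  The sensitivity model replaces the product column with a
#' tensor-product block of `tensor_df[1] * tensor_df[2]` pairwise products
#' of marginal natural-spline bases, allowing a nonlinear interaction
#' surface.  No intercept column is ever included: it is absorbed by the
#' matched-set conditioning.
#'
#' @param temp,pm [spline_spec()] for each exposure.
#' @param interaction `"linear_product"` (primary) or `"tensor_product"`.
#' @param tensor_df Length-2 marginal basis dimensions for the tensor block.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(temp = spline_spec(), pm = spline_spec(),
                       interaction = c("linear_product", "tensor_product"),
                       tensor_df = c(4, 4)) {
  interaction <- match.arg(interaction)
  stopifnot(inherits(temp, "spline_spec"), inherits(pm, "spline_spec"))
  if (length(tensor_df) != 2 || any(tensor_df < 1)) {
    abort("`tensor_df` must be two dimensions >= 1.",
          class = "heatpm_invalid_config")
  }
  structure(list(temp = temp, pm = pm, interaction = interaction,
                 tensor_df = as.integer(tensor_df)),
            class = "model_spec")
}

# freeze a spline_spec against data: fill in knots/boundary
freeze_spline <- function(spec, x_case, x_all) {
  df <- spec$df
  if (df == 1) {
    return(list(df = 1L, knots = numeric(), boundary = range(x_all)))
  }
  boundary <- spec$boundary %||% range(x_all)
  knots <- spec$knots %||%
    quantile(x_case, probs = seq_len(df - 1) / df, names = FALSE, type = 7)
  if (any(knots <= boundary[1]) || any(knots >= boundary[2])) {
    abort("Interior knots must lie strictly inside the boundary knots.",
          class = "heatpm_invalid_config")
  }
  list(df = df, knots = as.numeric(knots), boundary = as.numeric(boundary))
}

#' Evaluate a natural cubic spline basis
#'
#' Rows are observations, columns the `df` basis functions.  The represented
#' function space contains all linear functions, and the basis is linear
#' beyond the boundary knots (values outside them are extrapolated linearly,
#' with a warning).
#'
#' @param x Numeric vector of exposure values.
#' @param spec A [spline_spec()], or a frozen spec with `knots` and
#'   `boundary` filled in.  An unfrozen spec is frozen against `x` itself.
#' @param warn_extrapolation Warn when `x` falls outside the boundary knots.
#' @return Matrix of dimension `length(x)` by `df`.
#' @export
natural_cubic_basis <- function(x, spec = spline_spec(),
                                warn_extrapolation = TRUE) {
  if (is.null(spec$boundary) || (spec$df > 1 && is.null(spec$knots))) {
    spec <- freeze_spline(spec, x_case = x, x_all = x)
  }
  if (warn_extrapolation &&
      any(x < spec$boundary[1] | x > spec$boundary[2])) {
    warn("Values outside the boundary knots; extrapolating linearly.",
         class = "heatpm_extrapolation")
  }
  if (spec$df == 1) {
    return(matrix(as.numeric(x), ncol = 1))
  }
  unclass(splines::ns(x, knots = spec$knots,
                      Boundary.knots = spec$boundary))
}

block_labels <- function(prefix, frozen) {
  if (frozen$df == 1) paste0(prefix, "_lin")
  else paste0(prefix, "_ns", seq_len(frozen$df))
}

# basis blocks at arbitrary (t, p) given a frozen model
eval_design_rows <- function(frozen, t, p, warn_extrapolation = FALSE) {
  bt <- natural_cubic_basis(t, frozen$temp, warn_extrapolation)
  bp <- natural_cubic_basis(p, frozen$pm, warn_extrapolation)
  if (frozen$interaction == "linear_product") {
    inter <- matrix(t * p, ncol = 1)
    colnames(inter) <- "tmax_x_pm25"
  } else {
    tt <- natural_cubic_basis(t, frozen$tensor_temp, warn_extrapolation)
    tp <- natural_cubic_basis(p, frozen$tensor_pm, warn_extrapolation)
    inter <- matrix(0, length(t), ncol(tt) * ncol(tp))
    k <- 0
    for (i in seq_len(ncol(tt))) {
      for (j in seq_len(ncol(tp))) {
        k <- k + 1
        inter[, k] <- tt[, i] * tp[, j]
      }
    }
    colnames(inter) <- paste0("te_", rep(seq_len(ncol(tt)),
                                         each = ncol(tp)),
                              "_", rep(seq_len(ncol(tp)), ncol(tt)))
  }
  colnames(bt) <- block_labels("tmax", frozen$temp)
  colnames(bp) <- block_labels("pm25", frozen$pm)
  cbind(bt, bp, inter)
}

#' Build the conditional-logistic design from an analysis table
#'
#' Freezes the spline specification against the data (interior knots from
#' case-day exposure quantiles, boundary knots from the range of all
#' analysis values), evaluates the basis blocks, and packages everything
#' needed for fitting: the design matrix, stratum structure, and the frozen
#' knots for reproducible evaluation at new exposure values.
#'
#' @param analysis Long-format analysis tibble (from [build_matched_sets()],
#'   usually after [trim_extreme_pm()]).
#' @param model A [model_spec()].
#' @return An object of class `cc_design`: list with `X` (design matrix,
#'   labeled columns), `set_id`, `is_case`, `groups` (row indices per
#'   stratum), `frozen` (knot locations), `n_sets`.
#' @export
build_design <- function(analysis, model = model_spec()) {
  stopifnot(inherits(model, "model_spec"))
  stopifnot_cols(analysis,
                 c("set_id", "is_case", "tmax_w", "pm25_w"), "`analysis`")
  if (!nrow(analysis)) {
    abort("Empty analysis table.", class = "heatpm_invalid_input")
  }
  t <- analysis$tmax_w
  p <- analysis$pm25_w
  if (sd(t) == 0 || sd(p) == 0) {
    abort("Constant exposure column: design is degenerate.",
          class = "heatpm_degenerate_design")
  }
  case <- analysis$is_case == 1L
  one_case <- tapply(case, analysis$set_id, sum)
  if (any(one_case != 1L)) {
    abort("Every matched set must contain exactly one case row.",
          class = "heatpm_invalid_input")
  }

  frozen <- list(
    temp = freeze_spline(model$temp, t[case], t),
    pm = freeze_spline(model$pm, p[case], p),
    interaction = model$interaction
  )
  if (model$interaction == "tensor_product") {
    frozen$tensor_temp <- freeze_spline(spline_spec(model$tensor_df[1]),
                                        t[case], t)
    frozen$tensor_pm <- freeze_spline(spline_spec(model$tensor_df[2]),
                                      p[case], p)
  }
  X <- eval_design_rows(frozen, t, p)
  set_levels <- unique(analysis$set_id)
  groups <- split(seq_len(nrow(X)),
                  factor(analysis$set_id, levels = set_levels))
  structure(
    list(X = X, set_id = analysis$set_id, is_case = case,
         groups = groups,
         group_id = match(analysis$set_id, set_levels),
         frozen = frozen, model = model, n_sets = length(groups),
         tmax_w = t, pm25_w = p),
    class = "cc_design"
  )
}

#' Evaluate design rows at new exposure values
#'
#' Uses the knots frozen into a fitted design, so effect summaries are
#' computed on exactly the basis the model was fitted with.
#'
#' @param design A `cc_design` from [build_design()].
#' @param t,p Vectors of temperature (degC) and windowed PM2.5 (ug/m3).
#' @param warn_extrapolation Warn when values fall outside the boundary
#'   knots (default TRUE).
#' @return Matrix with `length(t)` rows and one column per coefficient.
#' @export
design_rows <- function(design, t, p, warn_extrapolation = TRUE) {
  stopifnot(inherits(design, "cc_design"))
  if (length(t) != length(p)) abort("`t` and `p` must have equal length.")
  eval_design_rows(design$frozen, t, p, warn_extrapolation)
}

#' @export
print.cc_design <- function(x, ...) {
  cat("<cc_design> ", x$n_sets, " matched sets, ", nrow(x$X), " person-days, ",
      ncol(x$X), " coefficients (", x$frozen$interaction, ")\n", sep = "")
  invisible(x)
}
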