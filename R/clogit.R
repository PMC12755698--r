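#' Conditional log-likelihood of a single matched set
#'
#' The standard matched-set conditional form: with linear predictors
#' `eta = x %*% beta`, the log-probability that the observed case row is the
#' case among the rows of its stratum, `eta[case_index] - logsumexp(eta)`.
#' Always negative; stratum-constant columns cancel exactly, which is the
#' self-matching confounding-control property of the design.
#'
#' @param beta Coefficient vector.
#' @param x Design-matrix rows of the stratum (case and referents).
#' @param case_index Row index of the case.
#' @return The stratum log-likelihood, in `(-Inf, 0)`.
#' @examples
#' x <- cbind(c(1, 2, 3))
#' stratum_loglik(c(0.5), x, 1)
#' @export
stratum_loglik <- function(beta, x, case_index) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(beta))) {
    abort("Design rows and coefficients must be finite.",
          class = "heatpm_invalid_input")
  }
  if (case_index < 1 || case_index > nrow(x)) {
    abort("`case_index` out of range.", class = "heatpm_invalid_input")
  }
  eta <- drop(x %*% beta)
  eta[case_index] - logsumexp(eta)
}

# log-likelihood, gradient and observed information over all strata.
# X rows are grouped by gid (1..G); case is the logical case-row indicator.
cc_ll_parts <- function(beta, X, case, groups, gid, order = 2L) {
  eta <- drop(X %*% beta)
  M <- vapply(groups, function(i) max(eta[i]), numeric(1))
  e <- exp(eta - M[gid])
  S <- drop(rowsum(e, gid))
  ll <- sum(eta[case]) - sum(M + log(S))
  if (order < 1L) return(list(ll = ll))
  p <- e / S[gid]
  grad <- colSums(X[case, , drop = FALSE]) - drop(crossprod(X, p))
  if (order < 2L) return(list(ll = ll, grad = grad))
  Xp <- X * p
  mu <- rowsum(Xp, gid)
  info <- crossprod(X, Xp) - crossprod(mu)
  list(ll = ll, grad = grad, info = info)
}

#' Total conditional log-likelihood of a design
#'
#' @param beta Coefficient vector (raw scale, matching `colnames(design$X)`).
#' @param design A `cc_design` from [build_design()].
#' @return Sum of [stratum_loglik()] over all matched sets.
#' @export
clogit_loglik <- function(beta, design) {
  stopifnot(inherits(design, "cc_design"))
  cc_ll_parts(beta, design$X, design$is_case, design$groups,
              design$group_id, order = 0L)$ll
}

# Newton maximizer of the (optionally ridge-penalized) conditional
# log-likelihood in a column-scaled space.  tau is the per-column prior
# precision in the scaled space (0 = flat).
newton_clogit <- function(Xs, case, groups, gid, tau, tol_grad = 1e-9,
                          max_iter = 100) {
  d <- ncol(Xs)
  beta <- numeric(d)
  lp_of <- function(b, parts) parts$ll - 0.5 * sum(tau * b^2)
  parts <- cc_ll_parts(beta, Xs, case, groups, gid)
  ev <- eigen(parts$info + diag(tau, d), symmetric = TRUE,
              only.values = TRUE)$values
  if (max(ev) <= 0 || min(ev) < max(ev) * 1e-10) {
    abort(paste("The conditional likelihood is flat or rank-deficient in",
                "at least one direction (non-identifiable design)."),
          class = "heatpm_nonidentifiable")
  }
  lp <- lp_of(beta, parts)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    g <- parts$grad - tau * beta
    if (sqrt(sum(g^2)) < tol_grad) { converged <- TRUE; break }
    if (iter > max_iter) break
    H <- parts$info + diag(tau, d)
    step <- solve(H, g)
    h <- 1
    repeat {
      cand <- beta + h * step
      cand_parts <- cc_ll_parts(cand, Xs, case, groups, gid)
      cand_lp <- lp_of(cand, cand_parts)
      if (is.finite(cand_lp) && cand_lp >= lp - 1e-12) break
      h <- h / 2
      if (h < 1e-12) {
        abort("Newton step failed to improve the log-likelihood.",
              class = "heatpm_no_convergence")
      }
    }
    beta <- cand; parts <- cand_parts; lp <- cand_lp
    if (sqrt(sum(beta^2)) > 1e4) {
      abort(paste("Coefficients diverging: the conditional likelihood",
                  "appears unbounded (separation)."),
            class = "heatpm_separation")
    }
  }
  if (!converged) {
    abort(sprintf(
      "Newton did not reach gradient norm %.0e in %d iterations (%.2e).",
      tol_grad, max_iter, sqrt(sum((parts$grad - tau * beta)^2))),
      class = "heatpm_no_convergence")
  }
  # a likelihood at its supremum (every case probability ~1) means the
  # strata are separated and the unpenalized MLE does not exist
  if (all(tau == 0) && parts$ll > -1e-6 * length(groups)) {
    abort(paste("Perfect separation: every stratum assigns its case",
                "probability ~1 and the likelihood is unbounded."),
          class = "heatpm_separation")
  }
  list(beta = beta, parts = parts, lp = lp, iterations = iter,
       grad_norm = sqrt(sum((parts$grad - tau * beta)^2)))
}

#' Maximum-likelihood conditional logistic fit
#'
#' Newton-Raphson maximizer of the matched-set conditional log-likelihood
#' with step-halving (the log-likelihood is concave, so steps never decrease
#' it), analytic gradient and observed information, and internal column
#' scaling for conditioning.  Separation is reported as an explicit error
#' rather than silent divergence; a flat (non-identifiable) likelihood is
#' reported too.
#'
#' @param design A `cc_design` from [build_design()].
#' @param tol_grad Convergence tolerance on the L2 norm of the raw-scale
#'   score (default 1e-9).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cc_clogit`: coefficients, `vcov` (inverse
#'   observed information), `loglik`, `null_loglik`, counts, and the design.
#' @export
fit_clogit <- function(design, tol_grad = 1e-9, max_iter = 100) {
  stopifnot(inherits(design, "cc_design"))
  X <- design$X
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  Xs <- sweep(X, 2, s, "/")
  # raw-scale gradient = scaled gradient * s, so tighten the scaled
  # tolerance by the largest scale factor
  fit <- newton_clogit(Xs, design$is_case, design$groups, design$group_id,
                       tau = rep(0, ncol(X)),
                       tol_grad = tol_grad / max(1, max(s)),
                       max_iter = max_iter)
  beta <- fit$beta / s
  raw_grad <- cc_ll_parts(beta, X, design$is_case, design$groups,
                          design$group_id, order = 1L)$grad
  Vs <- solve(fit$parts$info)
  V <- Vs / tcrossprod(s)
  labels <- colnames(X)
  dimnames(V) <- list(labels, labels)
  structure(
    list(coefficients = setNames(beta, labels), vcov = V,
         loglik = fit$parts$ll,
         null_loglik = -sum(log(lengths(design$groups))),
         n_sets = design$n_sets, n_obs = nrow(X),
         iterations = fit$iterations,
         grad_norm = sqrt(sum(raw_grad^2)),
         design = design),
    class = "cc_clogit"
  )
}

# multivariate-t proposal utilities in the scaled space
mvt_propose <- function(mode, U, scale, df) {
  d <- length(mode)
  z <- rnorm(d)
  w <- rchisq(1, df)
  mode + scale * drop(crossprod(U, z)) * sqrt(df / w)
}
mvt_logq <- function(x, mode, U, scale, df) {
  y <- (x - mode) / scale
  w <- backsolve(U, y, transpose = TRUE)
  -0.5 * (df + length(x)) * log1p(sum(w^2) / df)
}

#' Bayesian conditional logistic fit
#'
#' Samples the posterior over the design coefficients: independent
#' `Normal(0, prior_sd^2)` priors (or flat with `prior_sd = Inf`) times the
#' matched-set conditional likelihood.  Sampling is by independence
#' Metropolis-Hastings with a multivariate-t proposal centred at the
#' posterior mode with covariance from the inverse curvature (Laplace
#' approximation) -- the posterior is log-concave, so this proposal tracks
#' it closely and acceptance rates are high.  Convergence is gated on
#' split-Rhat and bulk effective sample size; a fit failing the gate is
#' rejected with a diagnostic report.
#'
#' @param design A `cc_design` from [build_design()].
#' @param prior_sd Prior SD per coefficient on the raw scale (default 5;
#'   `Inf` for a flat prior).
#' @param chains Number of chains (default 4).
#' @param warmup,iter Discarded and retained draws per chain (default
#'   1000 each).
#' @param seed Integer seed; fits are reproducible given `(design, config,
#'   seed)`.
#' @param proposal_scale Multiplier on the Laplace covariance (default 1.05).
#' @param proposal_df Degrees of freedom of the t proposal (default 20).
#' @param rhat_max,ess_min Acceptance gates (defaults 1.01 and 400).
#' @param on_fail What to do when a gate fails: `"error"` (default),
#'   `"warn"`, or `"ignore"`.
#' @return Object of class `cc_clogit_bayes` (also `cc_draws`): `draws`
#'   (post-warmup draws, all chains stacked, labeled columns),
#'   `diagnostics` (per-coefficient split-Rhat, bulk ESS, MCSE),
#'   `accept_rate`, `mode`, and the design.
#' @export
fit_clogit_bayes <- function(design, prior_sd = 5, chains = 4,
                             warmup = 1000, iter = 1000, seed = 1,
                             proposal_scale = 1.05, proposal_df = 20,
                             rhat_max = 1.01, ess_min = 400,
                             on_fail = c("error", "warn", "ignore")) {
  stopifnot(inherits(design, "cc_design"))
  on_fail <- match.arg(on_fail)
  if (prior_sd <= 0) abort("`prior_sd` must be positive (Inf = flat).")
  if (iter < 1 || chains < 1) abort("Need at least one chain and one draw.")
  set.seed(as.integer(seed))

  X <- design$X
  d <- ncol(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  Xs <- sweep(X, 2, s, "/")
  tau <- if (is.finite(prior_sd)) 1 / (prior_sd * s)^2 else rep(0, d)

  mode_fit <- newton_clogit(Xs, design$is_case, design$groups,
                            design$group_id, tau = tau)
  mode <- mode_fit$beta
  V <- solve(mode_fit$parts$info + diag(tau, d))
  U <- chol(V)

  lp_of <- function(b) {
    cc_ll_parts(b, Xs, design$is_case, design$groups, design$group_id,
                order = 0L)$ll - 0.5 * sum(tau * b^2)
  }

  n_keep <- iter
  chain_draws <- vector("list", chains)
  accepts <- 0L
  for (ch in seq_len(chains)) {
    cur <- mvt_propose(mode, U, proposal_scale, proposal_df)
    lp_cur <- lp_of(cur)
    lq_cur <- mvt_logq(cur, mode, U, proposal_scale, proposal_df)
    keep <- matrix(NA_real_, n_keep, d)
    for (i in seq_len(warmup + n_keep)) {
      prop <- mvt_propose(mode, U, proposal_scale, proposal_df)
      lp_prop <- lp_of(prop)
      lq_prop <- mvt_logq(prop, mode, U, proposal_scale, proposal_df)
      logr <- (lp_prop - lp_cur) + (lq_cur - lq_prop)
      if (is.finite(logr) && log(runif(1)) < logr) {
        cur <- prop; lp_cur <- lp_prop; lq_cur <- lq_prop
        if (i > warmup) accepts <- accepts + 1L
      }
      if (i > warmup) keep[i - warmup, ] <- cur
    }
    chain_draws[[ch]] <- sweep(keep, 2, s, "/") # back to raw scale
  }
  labels <- colnames(X)
  diagnostics <- mcmc_diagnostics(chain_draws, labels)
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- labels

  ok <- all(diagnostics$rhat < rhat_max, na.rm = TRUE) &&
    all(diagnostics$ess_bulk > ess_min, na.rm = TRUE)
  if (!ok) {
    msg <- sprintf(
      "MCMC convergence gate failed (max Rhat %.4f, min bulk ESS %.0f; gates: Rhat < %.3f, ESS > %.0f).",
      max(diagnostics$rhat, na.rm = TRUE),
      min(diagnostics$ess_bulk, na.rm = TRUE), rhat_max, ess_min)
    if (on_fail == "error") {
      abort(msg, class = "heatpm_mcmc_not_converged",
            diagnostics = diagnostics)
    } else if (on_fail == "warn") {
      warn(msg, class = "heatpm_mcmc_not_converged")
    }
  }

  structure(
    list(draws = draws, chains = chains, iter = iter, warmup = warmup,
         accept_rate = accepts / (chains * n_keep),
         diagnostics = diagnostics,
         mode = setNames(mode / s, labels),
         prior_sd = prior_sd, seed = seed, converged = ok,
         design = design),
    class = c("cc_clogit_bayes", "cc_draws")
  )
}

#' Wrap fixed coefficient vectors as draws
#'
#' Utility for closed-form checks and plug-in evaluation: treats one or more
#' known coefficient vectors as a posterior sample so that every effect
#' summary can be applied to them.
#'
#' @param design A `cc_design`.
#' @param beta A coefficient vector or matrix of rows of coefficients.
#' @return Object of class `cc_draws`.
#' @export
manual_draws <- function(design, beta) {
  stopifnot(inherits(design, "cc_design"))
  beta <- if (is.matrix(beta)) beta else matrix(beta, nrow = 1)
  if (ncol(beta) != ncol(design$X)) {
    abort("Coefficient length must match the design.",
          class = "heatpm_invalid_input")
  }
  colnames(beta) <- colnames(design$X)
  structure(list(draws = beta, design = design), class = "cc_draws")
}

# split-Rhat and bulk ESS (Geyer initial monotone sequence) per coefficient
mcmc_diagnostics <- function(chain_draws, labels) {
  halves <- list()
  for (m in chain_draws) {
    n <- nrow(m)
    h <- floor(n / 2)
    if (h < 2) { halves <- c(halves, list(m)); next }
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(n - h + 1):n, , drop = FALSE]))
  }
  d <- ncol(chain_draws[[1]])
  rhat <- ess <- mcse <- numeric(d)
  n <- nrow(halves[[1]])
  m2 <- length(halves)
  for (j in seq_len(d)) {
    xs <- lapply(halves, function(h) h[, j])
    mk <- vapply(xs, mean, numeric(1))
    s2k <- vapply(xs, var, numeric(1))
    W <- mean(s2k)
    B <- if (m2 > 1) n * var(mk) else 0
    varplus <- (n - 1) / n * W + B / n
    if (!is.finite(W) || W <= 0 || varplus <= 0) {
      rhat[j] <- 1; ess[j] <- n * m2; mcse[j] <- 0
      next
    }
    rhat[j] <- sqrt(varplus / W)
    acov <- vapply(xs, function(x) {
      drop(acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf)
    }, numeric(n))
    rho <- 1 - (W - rowMeans(acov)[-1]) / varplus
    # Geyer: pair sums, truncate at first negative, enforce monotone
    npair <- floor((length(rho) - 1) / 2)
    tau <- 1
    prev <- Inf
    k <- 0
    while (k <= npair) {
      p <- if (k == 0) 1 + rho[1] else rho[2 * k] + rho[2 * k + 1]
      if (!is.finite(p) || p <= 0) break
      p <- min(p, prev)
      tau <- tau + 2 * p
      prev <- p
      k <- k + 1
    }
    tau <- tau - 1 # rho_0 counted inside the first pair
    ess[j] <- min(m2 * n, m2 * n / max(tau, 1e-12))
    mcse[j] <- sd(unlist(xs)) / sqrt(ess[j])
  }
  tibble(term = labels, rhat = rhat, ess_bulk = ess, mcse = mcse)
}

#' @export
print.cc_clogit <- function(x, ...) {
  cat("<cc_clogit> conditional logistic MLE:", x$n_sets, "matched sets,",
      x$n_obs, "person-days\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
print.cc_clogit_bayes <- function(x, ...) {
  cat("<cc_clogit_bayes> ", x$chains, " chains x ", x$iter,
      " draws (warmup ", x$warmup, "), acceptance ",
      sprintf("%.2f", x$accept_rate), ", prior sd ", x$prior_sd, "\n",
      sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname fit_clogit
#' @param x A fitted `cc_clogit` object.
#' @param ... Unused.
#' @method tidy cc_clogit
#' @export
tidy.cc_clogit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- unname(x$coefficients)
  tibble(term = names(x$coefficients), estimate = est, std.error = se,
         statistic = est / se,
         p.value = 2 * pnorm(-abs(est / se)))
}

#' @rdname fit_clogit
#' @method glance cc_clogit
#' @export
glance.cc_clogit <- function(x, ...) {
  tibble(logLik = x$loglik, null_logLik = x$null_loglik,
         n_sets = x$n_sets, n_obs = x$n_obs,
         n_coef = length(x$coefficients), iterations = x$iterations)
}

#' @rdname fit_clogit_bayes
#' @param x A fitted `cc_clogit_bayes` object.
#' @param ... Unused.
#' @method tidy cc_clogit_bayes
#' @export
tidy.cc_clogit_bayes <- function(x, ...) {
  q <- apply(x$draws, 2, quantile, c(0.025, 0.975), names = FALSE)
  tibble(term = colnames(x$draws),
         estimate = colMeans(x$draws),
         std.error = apply(x$draws, 2, sd),
         conf.low = q[1, ], conf.high = q[2, ],
         rhat = x$diagnostics$rhat,
         ess_bulk = x$diagnostics$ess_bulk)
}

#' @rdname fit_clogit_bayes
#' @method glance cc_clogit_bayes
#' @export
glance.cc_clogit_bayes <- function(x, ...) {
  tibble(n_draws = nrow(x$draws), chains = x$chains,
         accept_rate = x$accept_rate,
         max_rhat = max(x$diagnostics$rhat),
         min_ess_bulk = min(x$diagnostics$ess_bulk),
         converged = x$converged, prior_sd = x$prior_sd)
}
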