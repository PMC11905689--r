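#' Pool posterior draws across imputations (mixture pooling)
#'
#' For each imputation the chains are concatenated into one draw set; the
#' `K` draw sets are then pooled into one mixture. Reported per parameter:
#' mixture mean, SD and 2.5/97.5% quantiles, the per-imputation means, and
#' the within/between-imputation variance decomposition. The mixture mean
#' equals the mean of the per-imputation means by construction.
#'
#' @param fits list of `jmsens_fit` objects (one per imputation) or of draw
#'   matrices with identical named columns.
#' @return an object of class `jmsens_pooled`: `summary` data frame
#'   (`parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `within`, `between`),
#'   `per_imputation_means` (K x p), `K`.
#' @export
pool_draws <- function(fits) {
  mats <- lapply(fits, function(f)
    if (inherits(f, "jmsens_fit")) draw_matrix(f) else as.matrix(f))
  nm <- colnames(mats[[1]])
  for (m in mats)
    if (!identical(colnames(m), nm))
      stop("imputations have mismatched parameter sets")
  K <- length(mats)
  pooled <- do.call(rbind, mats)
  per_mean <- do.call(rbind, lapply(mats, colMeans))
  per_var <- do.call(rbind, lapply(mats, function(m) apply(m, 2, stats::var)))
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975))
  sm <- data.frame(parameter = nm,
                   mean = colMeans(pooled),
                   sd = apply(pooled, 2, stats::sd),
                   q2.5 = qs[1, ], q97.5 = qs[2, ],
                   within = colMeans(per_var),
                   between = if (K > 1) apply(per_mean, 2, stats::var)
                             else rep(0, length(nm)),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = sm, per_imputation_means = per_mean, K = K),
            class = "jmsens_pooled")
}

#' @export
print.jmsens_pooled <- function(x, ...) {
  cat("Pooled posterior over", x$K, "imputation(s)\n")
  sm <- x$summary
  sm[, -1] <- round(sm[, -1], 4)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' Rubin's rules for point estimates and variances
#'
#' Classic multiple-imputation combination: the pooled estimate is the mean
#' of the per-imputation estimates; the total variance is the mean
#' within-imputation variance plus `(1 + 1/K)` times the between-imputation
#' variance; the interval uses a t reference with the standard
#' degrees-of-freedom formula
#' \eqn{\nu = (K-1)(1 + \bar W / ((1+1/K) B))^2}.
#'
#' @param estimates per-imputation point estimates: length-K vector or
#'   K x p matrix.
#' @param variances matching per-imputation variances.
#' @param level confidence level.
#' @return data frame with `estimate`, `within`, `between`, `total`, `se`,
#'   `df`, `lower`, `upper` (one row per parameter).
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  est <- as.matrix(estimates); var_ <- as.matrix(variances)
  if (ncol(est) == 1L && !is.matrix(estimates)) {
    est <- matrix(estimates, ncol = 1); var_ <- matrix(variances, ncol = 1)
  }
  stopifnot(identical(dim(est), dim(var_)))
  K <- nrow(est)
  if (K < 2L) {
    warning("K = 1: between-imputation variance set to 0")
    B <- rep(0, ncol(est))
  } else B <- apply(est, 2, stats::var)
  Q <- colMeans(est)
  W <- colMeans(var_)
  Tv <- W + (1 + 1 / K) * B
  df <- ifelse(B > 0, (K - 1) * (1 + W / ((1 + 1 / K) * B))^2, Inf)
  a <- 1 - (1 - level) / 2
  tq <- stats::qt(a, df)
  tq[is.infinite(df)] <- stats::qnorm(a)
  data.frame(parameter = colnames(est) %||% paste0("par", seq_along(Q)),
             estimate = Q, within = W, between = B, total = Tv,
             se = sqrt(Tv), df = df,
             lower = Q - tq * sqrt(Tv), upper = Q + tq * sqrt(Tv),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative efficiency loss of finite multiple imputation
#'
#' The efficiency of K imputations relative to infinitely many is
#' \eqn{(1 + \gamma/K)^{-1}}, where \eqn{\gamma} is the fraction of missing
#' information; the loss is returned in percent:
#' `100 * (1 - (1 + gamma/K)^(-1))`. With 19% missing information and K = 5
#' the loss is about 4%.
#'
#' @param gamma fraction of missing information, in `[0, 1]`.
#' @param K number of imputations (>= 1).
#' @return percent efficiency loss.
#' @export
relative_efficiency_loss <- function(gamma, K) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]")
  if (any(K < 1)) stop("K must be >= 1")
  100 * (1 - 1 / (1 + gamma / K))
}

#' Run the full delta-adjustment sensitivity analysis
#'
#' Orchestrates the four workflow steps: (A) fit the substantive joint model
#' to the observed data (the MAR baseline); (B) fit the pattern-mixture
#' imputation model once; (C) for each delta scenario impute `K` completed
#' data sets and refit the substantive model on each; (D) pool per scenario
#' and tabulate side by side. Every stage is seeded: scenario s selects
#' imputation draws with seed `seed + 100 * s` and imputation k is refitted
#' with seed `seed + 100 * s + k`, so the whole run is reproducible and
#' scenarios share identical observed data and imputation-model draws while
#' their draw selections stay independent.
#'
#' @param dataset a prepared, pattern-labelled `jmsens_data`.
#' @param substantive a [joint_model_spec()].
#' @param imputation an [imputation_model_spec()].
#' @param scenarios list of `delta_spec` objects.
#' @param K imputations per scenario.
#' @param control [mcmc_control()] for the MAR and imputation fits.
#' @param refit_control [mcmc_control()] for the per-imputation refits
#'   (defaults to `control`).
#' @param keep_fits keep the per-imputation `jmsens_fit` objects (memory
#'   heavy; needed for scenario-wise dynamic prediction).
#' @return an object of class `jmsens_sens`: `mar` (the MAR fit),
#'   `imputation_fit`, `scenarios` (per scenario: `label`, `delta`,
#'   `pooled`, `rubin`, optionally `fits`), and `table` from
#'   [comparison_table()].
#' @export
run_sensitivity <- function(dataset, substantive = joint_model_spec(),
                            imputation = imputation_model_spec(substantive),
                            scenarios = list(delta_constant(0),
                                             delta_threshold(-1, 60),
                                             delta_cubic()),
                            K = 5L, control = mcmc_control(),
                            refit_control = control, keep_fits = FALSE) {
  message("stage A: substantive fit on observed data (MAR)")
  mar <- fit_joint_model(dataset, substantive, control)
  message("stage B: pattern-mixture imputation model fit")
  imp_fit <- fit_imputation_model(dataset, imputation, control)
  res <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    de <- scenarios[[s]]
    message("stage C: scenario ", de$label)
    sseed <- control$seed + 100L * s
    completed <- impute_missing(dataset, imp_fit, de, K = K, seed = sseed)
    fits <- vector("list", K)
    for (k in seq_len(K)) {
      ctl <- refit_control
      ctl$seed <- sseed + k
      fits[[k]] <- fit_joint_model(completed[[k]], substantive, ctl)
    }
    pooled <- pool_draws(fits)
    est <- pooled$per_imputation_means
    vars <- do.call(rbind, lapply(fits, function(f)
      apply(draw_matrix(f), 2, stats::var)))
    res[[s]] <- list(label = de$label, delta = de, pooled = pooled,
                     rubin = rubin_pool(est, vars),
                     fits = if (keep_fits) fits else NULL)
  }
  out <- structure(list(mar = mar, imputation_fit = imp_fit,
                        scenarios = res, K = K),
                   class = "jmsens_sens")
  out$table <- comparison_table(out)
  out
}

#' Side-by-side scenario comparison table
#'
#' One row per substantive-model parameter; one estimate column (posterior
#' mean with 2.5/97.5% quantiles) for the MAR fit and for each delta
#' scenario.
#'
#' @param sens a `jmsens_sens` object.
#' @param digits rounding for display.
#' @return a data frame.
#' @export
comparison_table <- function(sens, digits = 3) {
  fmt <- function(m, lo, hi)
    sprintf("%.*f (%.*f, %.*f)", digits, m, digits, lo, digits, hi)
  mar_m <- draw_matrix(sens$mar)
  qs <- apply(mar_m, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(parameter = colnames(mar_m),
                    MAR = fmt(colMeans(mar_m), qs[1, ], qs[2, ]),
                    stringsAsFactors = FALSE)
  for (sc in sens$scenarios) {
    sm <- sc$pooled$summary
    out[[sc$label]] <- fmt(sm$mean, sm$q2.5, sm$q97.5)
  }
  out
}

#' @export
print.jmsens_sens <- function(x, ...) {
  cat("Delta-adjustment sensitivity analysis (K =", x$K, "imputations)\n")
  cat("scenarios:", paste(vapply(x$scenarios, `[[`, "", "label"),
                          collapse = ", "), "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
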