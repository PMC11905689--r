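#' @export
print.jmsens_fit <- function(x, ...) {
  kind <- if (isTRUE(x$spec$pattern_deviations)) "pattern-mixture imputation"
          else "substantive joint"
  cat("Bayesian", kind, "model fit\n")
  cat("  subjects: ", x$frame$N, ", observed scores: ",
      length(x$frame$y), ", events: ", sum(x$frame$delta), "\n", sep = "")
  cat("  chains: ", length(x$chains), " x ",
      nrow(x$chains[[1]]$params), " kept draws (warmup ",
      x$control$warmup, ", thin ", x$control$thin, ")\n", sep = "")
  co <- coef(x)
  show <- intersect(c("alpha_value", "alpha_slope", "sigma"), names(co))
  cat("  posterior means: ",
      paste(show, "=", round(co[show], 3), collapse = ", "), "\n", sep = "")
  if (length(x$diagnostics$flagged))
    cat("  convergence flags: ",
        paste(x$diagnostics$flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Posterior summary of a fitted joint model
#'
#' @param object a `jmsens_fit`.
#' @param ... unused.
#' @return data frame with posterior mean, SD, 2.5/97.5% quantiles, split
#'   PSRF and effective sample size per parameter.
#' @export
summary.jmsens_fit <- function(object, ...) {
  m <- draw_matrix(object)
  qs <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975))
  dg <- object$diagnostics$summary
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m), sd = apply(m, 2, stats::sd),
                    q2.5 = qs[1, ], q97.5 = qs[2, ],
                    psrf = dg$psrf_split[match(colnames(m), dg$parameter)],
                    ess = dg$ess[match(colnames(m), dg$parameter)],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("jmsens_fit_summary", "data.frame")
  out
}

#' @export
print.jmsens_fit_summary <- function(x, digits = 3, ...) {
  y <- x
  for (cc in intersect(c("mean", "sd", "q2.5", "q97.5", "psrf"), names(y)))
    y[[cc]] <- round(y[[cc]], digits)
  if (!is.null(y$ess)) y$ess <- round(y$ess)
  class(y) <- "data.frame"
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.jmsens_fit <- function(object, ...) colMeans(draw_matrix(object))

#' Longitudinal residuals at the posterior mean
#'
#' Observed score minus the posterior-mean subject-specific trajectory
#' (posterior means of fixed effects and random effects; the mean of a
#' linear function of the draws).
#'
#' @param object a `jmsens_fit`.
#' @param ... unused.
#' @return numeric vector, one residual per observed assessment.
#' @export
residuals.jmsens_fit <- function(object, ...) {
  fr <- object$frame
  beta_hat <- coef(object)[fr$beta_names]
  b_hat <- Reduce(`+`, lapply(object$chains, function(ch)
    apply(ch$re, c(2, 3), mean))) / length(object$chains)
  fr$y - drop(fr$X %*% beta_hat) - b_hat[fr$id, 1] - b_hat[fr$id, 2] * fr$z
}

#' Posterior-predictive replicate scores
#'
#' Draws replicate observed-score vectors at the observed design points,
#' each from a randomly selected posterior draw (trajectory plus fresh
#' measurement noise).
#'
#' @param object a `jmsens_fit`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns, rows matching the observed
#'   scores.
#' @export
simulate.jmsens_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  M <- n_draws_total(object)
  idx <- sample.int(M, nsim, replace = nsim > M)
  out <- vapply(idx, function(j) {
    p <- draw_params(object, j)
    b <- p$random_effects
    mu <- drop(fr$X %*% p$beta) + b[fr$id, 1] + b[fr$id, 2] * fr$z
    mu + stats::rnorm(length(mu), 0, sqrt(p$sigma2))
  }, numeric(length(fr$y)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Trace plots
#'
#' @param x a `jmsens_fit`.
#' @param pars parameters to plot (default: association weights and sigma).
#' @param ... passed to `matplot`.
#' @export
plot.jmsens_fit <- function(x, pars = c("alpha_value", "alpha_slope",
                                        "sigma"), ...) {
  pars <- intersect(pars, x$param_names)
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    tr <- vapply(x$chains, function(ch) ch$params[, p],
                 numeric(nrow(x$chains[[1]]$params)))
    graphics::matplot(tr, type = "l", lty = 1, ylab = p, ...)
  }
  invisible(x)
}
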