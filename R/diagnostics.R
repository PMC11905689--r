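#' MCMC convergence diagnostics
#'
#' Computes, per scalar parameter, the split potential-scale-reduction
#' factor (each chain halved, between/within variance comparison across the
#' resulting sub-chains), the classic non-split PSRF (between whole chains),
#' and an effective sample size from Geyer's initial-positive-sequence
#' autocovariance estimator. Parameters whose split PSRF exceeds `threshold`
#' are flagged. Metropolis acceptance rates are included when the input is a
#' fitted model.
#'
#' @param x a `jmsens_fit`, or a list of draw matrices (one per chain, equal
#'   dimensions, named columns).
#' @param threshold flag parameters with split PSRF above this (default 1.1).
#' @return a list of class `jmsens_diagnostics`: `summary` (data frame with
#'   `parameter`, `psrf_split`, `psrf_basic`, `ess`), `flagged`,
#'   `acceptance` (or `NULL`).
#' @export
convergence_diagnostics <- function(x, threshold = 1.1) {
  if (inherits(x, "jmsens_fit")) {
    chains <- lapply(x$chains, `[[`, "params")
    acceptance <- do.call(rbind, lapply(x$chains, `[[`, "acceptance"))
  } else {
    chains <- x
    acceptance <- NULL
  }
  p <- ncol(chains[[1]])
  nm <- colnames(chains[[1]])
  if (is.null(nm)) nm <- paste0("par", seq_len(p))
  one_chain <- length(chains) == 1L
  if (one_chain)
    warning("single chain: PSRF cannot be computed and is omitted")
  sm <- data.frame(parameter = nm,
                   psrf_split = NA_real_, psrf_basic = NA_real_,
                   ess = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    cols <- lapply(chains, function(m) m[, j])
    if (!one_chain) {
      sm$psrf_split[j] <- psrf(split_halves(cols))
      sm$psrf_basic[j] <- psrf(cols)
    }
    sm$ess[j] <- sum(vapply(cols, ess_geyer, numeric(1)))
  }
  flagged <- if (one_chain) character(0) else
    sm$parameter[!is.na(sm$psrf_split) & sm$psrf_split > threshold]
  structure(list(summary = sm, flagged = flagged, threshold = threshold,
                 acceptance = acceptance),
            class = "jmsens_diagnostics")
}

split_halves <- function(cols) {
  out <- list()
  for (v in cols) {
    n2 <- length(v) %/% 2L
    out <- c(out, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
  }
  out
}

psrf <- function(cols) {
  m <- length(cols)
  n <- min(lengths(cols))
  cols <- lapply(cols, function(v) v[seq_len(n)])
  mu <- vapply(cols, mean, numeric(1))
  W <- mean(vapply(cols, stats::var, numeric(1)))
  B_over_n <- stats::var(mu)
  if (W <= 0) return(1)
  sqrt((n - 1) / n + B_over_n / W)
}

ess_geyer <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(n)
  lag_max <- min(n - 1L, 10L * floor(sqrt(n)))
  ac <- stats::acf(v, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # sum pairs of autocorrelations while positive (Geyer initial positive seq)
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac) - 1L) {
    pair <- ac[k + 1L] + ac[k + 2L]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' @export
print.jmsens_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics (", nrow(x$summary), " parameters)\n", sep = "")
  if (all(is.na(x$summary$psrf_split))) {
    cat("  PSRF omitted (single chain)\n")
  } else {
    cat("  max split PSRF: ",
        round(max(x$summary$psrf_split, na.rm = TRUE), 3), "\n", sep = "")
    if (length(x$flagged))
      cat("  flagged (> ", x$threshold, "): ",
          paste(x$flagged, collapse = ", "), "\n", sep = "")
    else cat("  no parameter above threshold ", x$threshold, "\n", sep = "")
  }
  cat("  min ESS: ", round(min(x$summary$ess)), "\n", sep = "")
  if (!is.null(x$acceptance)) {
    cat("  acceptance rates (per chain):\n")
    print(round(x$acceptance, 3))
  }
  invisible(x)
}
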