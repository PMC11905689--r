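#' Serialize posterior draws and a run manifest
#'
#' Writes the stacked fixed-parameter draws as a labelled CSV (one row per
#' draw, with `chain` and `iteration` columns) and a JSON manifest holding
#' the MCMC configuration, seed, acceptance rates and convergence flags, so
#' a fit is reproducible and auditable from its artifacts.
#'
#' @param fit a `jmsens_fit`.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
write_draws <- function(fit, dir, stem = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dp <- file.path(dir, paste0(stem, "_draws.csv"))
  rows <- lapply(seq_along(fit$chains), function(c) {
    m <- fit$chains[[c]]$params
    data.frame(chain = c, iteration = seq_len(nrow(m)), m,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), dp, row.names = FALSE)
  mp <- file.path(dir, paste0(stem, "_manifest.json"))
  ctl <- fit$control
  manifest <- list(
    package_version = as.character(utils::packageVersion("jmsens")),
    chains = ctl$chains, warmup = ctl$warmup,
    iterations = ctl$iterations, thin = ctl$thin, seed = ctl$seed,
    n_subjects = fit$frame$N, n_events = sum(fit$frame$delta),
    acceptance = lapply(fit$chains, function(ch) as.list(ch$acceptance)),
    max_psrf_split = suppressWarnings(
      max(fit$diagnostics$summary$psrf_split, na.rm = TRUE)),
    flagged = fit$diagnostics$flagged)
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(dp, mp))
}

#' Read draws written by [write_draws()]
#'
#' @param path path to a `_draws.csv` file.
#' @return a list of per-chain draw matrices.
#' @export
read_draws <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  lapply(split(d, d$chain), function(x)
    as.matrix(x[, setdiff(names(x), c("chain", "iteration")), drop = FALSE]))
}

#' Write completed (imputed) datasets
#'
#' Each completed dataset is written as the standard longitudinal table with
#' its `imputed` flag column, plus a small JSON manifest recording the
#' scenario, imputation index, source posterior draw and seed.
#'
#' @param completed list returned by [impute_missing()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_completed <- function(completed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ds in completed) {
    k <- attr(ds, "imputation_index")
    lab <- attr(ds, "scenario_label")
    stem <- sprintf("completed_%s_k%d", gsub("[^A-Za-z0-9_.-]", "_", lab), k)
    lp <- file.path(dir, paste0(stem, "_long.csv"))
    utils::write.csv(ds$longitudinal, lp, row.names = FALSE, na = "")
    mp <- file.path(dir, paste0(stem, "_manifest.json"))
    jsonlite::write_json(list(scenario = lab, imputation = k,
                              source_draw_index = attr(ds,
                                                       "source_draw_index"),
                              seed = attr(ds, "seed")),
                         mp, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, lp, mp)
  }
  invisible(paths)
}
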