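#' Sensitivity (delta) specifications
#'
#' A delta specification describes the assumed additional change in the
#' linear slope of the longitudinal outcome after dropout — the sensitivity
#' parameter of the pattern-mixture imputation model. Three families:
#' \describe{
#'   \item{constant}{the slope changes by `delta` points/year after dropout
#'     for everyone (`delta = 0` recovers the pattern-mixture MAR-type
#'     scenario).}
#'   \item{age_threshold}{subjects dropping out at or before `cutoff_age`
#'     keep their pre-dropout age trend; those dropping out later decline by
#'     an additional `delta` points/year.}
#'   \item{age_varying_cubic}{the additional slope depends on the age at
#'     which the value is imputed:
#'     \eqn{\Delta(age) = -((age - floor)/scale)^{power}} (0 below `floor_age`),
#'     so with the defaults it is 0 at age 25, near zero before 60, and -1
#'     at age 100.}
#' }
#'
#' @param delta additional slope after dropout (score points/year).
#' @param cutoff_age threshold on the dropout age (years).
#' @param floor_age,scale,power parameters of the cubic age-varying delta.
#' @param label scenario label used in reports; a default is derived.
#' @return an object of class `delta_spec`.
#' @export
delta_constant <- function(delta = 0, label = NULL) {
  structure(list(kind = "constant", delta = delta,
                 label = label %||% paste0("delta", format(delta))),
            class = "delta_spec")
}

#' @rdname delta_constant
#' @export
delta_threshold <- function(delta = -1, cutoff_age = 60, label = NULL) {
  structure(list(kind = "age_threshold", delta = delta,
                 cutoff_age = cutoff_age,
                 label = label %||% paste0("delta", format(delta))),
            class = "delta_spec")
}

#' @rdname delta_constant
#' @param eval_at for the cubic kind, whether \eqn{\Delta} is evaluated at
#'   the imputation age (default, so the additional decline steepens with
#'   age) or at the dropout age.
#' @export
delta_cubic <- function(floor_age = 25, scale = 75, power = 3L,
                        eval_at = c("imputation", "dropout"), label = NULL) {
  structure(list(kind = "age_varying_cubic", floor_age = floor_age,
                 scale = scale, power = as.integer(power),
                 eval_at = match.arg(eval_at),
                 label = label %||% "age_varying"),
            class = "delta_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective delta and delta offset
#'
#' `delta_value()` returns the effective additional slope
#' \eqn{\Delta_{eff}} (points/year) for an imputation at age `t` of a
#' subject who dropped out at `dropout_age`; `delta_offset()` returns the
#' resulting offset \eqn{\Delta_{eff} \cdot (t - t_{F})_+} added to the
#' imputed mean. The offset is exactly zero at (and before) the dropout age
#' for every specification, so imputed trajectories are continuous at
#' dropout.
#'
#' @param spec a `delta_spec`.
#' @param t imputation ages (years); vectorized.
#' @param dropout_age dropout ages (years); recycled against `t`.
#' @return numeric vector (points/year for `delta_value`, score points for
#'   `delta_offset`).
#' @export
delta_value <- function(spec, t, dropout_age = t) {
  stopifnot(inherits(spec, "delta_spec"))
  n <- max(length(t), length(dropout_age))
  t <- rep_len(t, n); dropout_age <- rep_len(dropout_age, n)
  switch(spec$kind,
    constant = rep_len(spec$delta, n),
    age_threshold = ifelse(dropout_age > spec$cutoff_age, spec$delta, 0),
    age_varying_cubic = {
      a <- if (spec$eval_at == "imputation") t else dropout_age
      v <- -(pmax(a - spec$floor_age, 0) / spec$scale)^spec$power
      v + 0  # avoid IEEE negative zero at the floor age
    })
}

#' @rdname delta_value
#' @export
delta_offset <- function(spec, t, dropout_age) {
  delta_value(spec, t, dropout_age) * pmax(t - dropout_age, 0)
}

#' Enumerate imputation targets
#'
#' Scheduled-but-unobserved assessments eligible for imputation: strictly
#' after the subject's dropout age, strictly before dementia onset (for
#' events) and before death (for the deceased). Intermittent gaps before
#' dropout are never imputed, nor is anything for completers.
#'
#' @param dataset a pattern-labelled `jmsens_data`.
#' @return data frame with `subject_id`, `wave`, `age`, `dropout_age`.
#' @export
enumerate_targets <- function(dataset) {
  stopifnot(inherits(dataset, "jmsens_data"))
  subj <- dataset$subjects
  drp <- dataset$dropout
  obs <- dataset$longitudinal[dataset$longitudinal$observed, , drop = FALSE]
  waves_by_subj <- split(obs$wave, factor(obs$subject_id,
                                          levels = subj$subject_id))
  out <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    sched <- subj$scheduled_ages[[i]]
    upper <- min(if (subj$event[i]) subj$event_age[i] else Inf,
                 if (!is.na(subj$death_age[i])) subj$death_age[i] else Inf)
    w <- setdiff(seq_along(sched), waves_by_subj[[i]])
    w <- w[sched[w] > drp$dropout_age[i] + 1e-9 &
             sched[w] < upper - 1e-9]
    if (length(w))
      out[[i]] <- data.frame(subject_id = subj$subject_id[i], wave = w,
                             age = sched[w],
                             dropout_age = drp$dropout_age[i])
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject_id = subj$subject_id[0], wave = integer(0),
                      age = numeric(0), dropout_age = numeric(0))
  rownames(out) <- NULL
  out
}

#' Multiply impute post-dropout outcomes under a delta scenario
#'
#' Selects `K` distinct posterior draws (uniformly, without replacement,
#' from the supplied seed) from a fitted pattern-mixture imputation model.
#' For each selected draw and each imputation target the imputed score is
#' the pattern-specific mean at the target age (that draw's fixed effects
#' and that subject's random-effects draw — joint posterior coherence, no
#' re-simulation from N(0, D)), plus the delta offset, plus measurement
#' noise from that draw's error SD, floored at 0. Observed rows are never
#' touched; different scenarios should use different seeds so their draw
#' selections are independent.
#'
#' @param dataset the pattern-labelled `jmsens_data` the model was fitted
#'   to.
#' @param fit a `jmsens_fit` from [fit_imputation_model()].
#' @param delta a `delta_spec`.
#' @param K number of imputations.
#' @param seed integer seed for draw selection and noise.
#' @param cap optional upper bound applied to imputed scores (default none;
#'   only the floor at 0 is always applied).
#' @return a list of `K` completed `jmsens_data` objects; each has an
#'   `imputed` logical column in `longitudinal` and attributes
#'   `imputation_index`, `scenario_label`, `source_draw_index`, `seed`.
#' @export
impute_missing <- function(dataset, fit, delta, K = 5L, seed = 1L,
                           cap = NULL) {
  stopifnot(inherits(fit, "jmsens_fit"), inherits(delta, "delta_spec"))
  M <- n_draws_total(fit)
  if (K > M) stop("K = ", K, " exceeds the ", M, " available draws")
  targets <- enumerate_targets(dataset)
  set.seed(seed)
  idx <- sample.int(M, K)
  spec <- fit$spec
  fr <- fit$frame
  tid <- match(targets$subject_id, dataset$subjects$subject_id)
  Xt <- if (nrow(targets)) {
    beta_design(spec, targets$age, fr$male[tid], fr$edu[tid],
                fr$cohort[tid], FALSE,
                if (spec$pattern_deviations) fr$pattern[tid] else NULL)
  } else NULL
  zt <- targets$age - fr$t_center
  off <- delta_offset(delta, targets$age, targets$dropout_age)

  lapply(seq_len(K), function(k) {
    pk <- draw_params(fit, idx[k])
    ds <- dataset
    ds$longitudinal$imputed <- FALSE
    if (nrow(targets)) {
      b <- pk$random_effects
      mu <- drop(Xt %*% pk$beta) + b[tid, 1L] + b[tid, 2L] * zt + off
      y <- mu + stats::rnorm(nrow(targets), 0, sqrt(pk$sigma2))
      y <- pmax(y, 0)
      if (!is.null(cap)) y <- pmin(y, cap)
      key_l <- paste(ds$longitudinal$subject_id, ds$longitudinal$wave)
      key_t <- paste(targets$subject_id, targets$wave)
      pos <- match(key_t, key_l)
      if (anyNA(pos)) stop("imputation target not present in the ",
                           "longitudinal table")
      ds$longitudinal$score[pos] <- y
      ds$longitudinal$observed[pos] <- TRUE
      ds$longitudinal$imputed[pos] <- TRUE
    }
    attr(ds, "imputation_index") <- k
    attr(ds, "scenario_label") <- delta$label
    attr(ds, "source_draw_index") <- idx[k]
    attr(ds, "seed") <- seed
    ds
  })
}
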