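#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-cohort prospective aging study with scheduled waves
#' about five years apart, bounded memory scores, dropout that may depend on
#' the latent memory level or slope (MNAR), dementia onset observable after
#' dropout (registry follow-up), and death acting as censoring. Defaults
#' give a long/short cohort mix (6-, 3- and 1-wave cohorts) so that all six
#' dropout patterns occur.
#'
#' @param n_subjects number of subjects.
#' @param cohorts list of cohort descriptors: `label`, `entry_age_range`
#'   (years), `n_waves`, `wave_spacing` (years), `enroll_year`, `weight`
#'   (sampling proportion).
#' @param spec a [joint_model_spec()] with *explicit* bases (the true model;
#'   also reusable for fitting).
#' @param true_params a [jm_parameters()] without random effects.
#' @param t_center centering age used by the true trajectory (years).
#' @param dropout_model named coefficients of the per-wave logistic dropout
#'   hazard `plogis(intercept + age * age_j + value * m_ij + slope_re * b1i)`
#'   applied after each non-final wave.
#' @param true_delta true additional slope of the latent trajectory after
#'   dropout (score points/year; 0 means dropout changes nothing, i.e. data
#'   are MAR if `dropout_model` ignores the latent process).
#' @param death_hazard Gompertz parameters `c(rate, shape, anchor_age)`:
#'   hazard `rate * exp(shape * (t - anchor_age))`.
#' @param registry_extra years after the final scheduled wave during which
#'   dementia/death remain observable (the last-evaluation age).
#' @param score_bounds score range, used only when `clip_scores = TRUE`.
#' @param clip_scores clip generated scores into `score_bounds`? Default
#'   `FALSE`: unclipped scores satisfy the Gaussian model exactly, which is
#'   what parameter-recovery validation requires. Set `TRUE` only for
#'   realistic-looking demonstrations.
#' @param horizon administrative age horizon for event simulation.
#' @param seed integer seed.
#' @return a list of class `jmsens_sim_config`.
#' @export
simulation_config <- function(n_subjects = 300L,
                              cohorts = default_cohorts(),
                              spec = NULL, true_params = NULL,
                              t_center = 62,
                              dropout_model = c(intercept = 1.5, age = 0,
                                                value = -0.1, slope_re = 0),
                              true_delta = 0,
                              death_hazard = c(rate = 0.01, shape = 0.09,
                                               anchor_age = 60),
                              registry_extra = 8,
                              score_bounds = c(0, 76), clip_scores = FALSE,
                              horizon = 110, seed = 1L) {
  if (is.null(spec)) spec <- default_true_spec()
  if (is.null(true_params)) true_params <- default_true_params(spec)
  dm <- c(intercept = -20, age = 0, value = 0, slope_re = 0)
  dm[names(dropout_model)] <- dropout_model
  structure(list(n_subjects = as.integer(n_subjects), cohorts = cohorts,
                 spec = spec, true_params = true_params, t_center = t_center,
                 dropout_model = dm, true_delta = true_delta,
                 death_hazard = death_hazard,
                 registry_extra = registry_extra,
                 score_bounds = score_bounds, clip_scores = clip_scores,
                 horizon = horizon, seed = as.integer(seed)),
            class = "jmsens_sim_config")
}

#' @rdname simulation_config
#' @export
default_cohorts <- function() {
  list(list(label = "C6", entry_age_range = c(35, 65), n_waves = 6L,
            wave_spacing = 5, enroll_year = 1990, weight = 0.4),
       list(label = "C3", entry_age_range = c(45, 75), n_waves = 3L,
            wave_spacing = 5, enroll_year = 2000, weight = 0.3),
       list(label = "C1", entry_age_range = c(55, 85), n_waves = 1L,
            wave_spacing = 5, enroll_year = 2008, weight = 0.3))
}

#' @rdname simulation_config
#' @export
default_true_spec <- function() {
  joint_model_spec(
    long_basis = natural_cubic_basis(knots = c(55, 75),
                                     boundary = c(35, 95)),
    baseline_basis = bspline_basis(df = 9, boundary = c(30, 112)),
    lag = 5)
}

#' @rdname simulation_config
#' @export
default_true_params <- function(spec = default_true_spec()) {
  jm_parameters(
    beta = c("(Intercept)" = 33.8, ns1 = -0.08, ns2 = -0.6, ns3 = 0.53,
             male = -2.9, education = 0.8, first = -3.9, first_age = 0.04,
             cohort = 0.1),
    gamma = c(male = -0.5, education = 0.04),
    alpha = c(-0.07, -1.5),
    sigma2 = 16,
    D = matrix(c(49, 0.3 * 7 * 0.25, 0.3 * 7 * 0.25, 0.0625), 2, 2),
    baseline_coefs = rep(-3.3, spec$baseline_basis$df))
}

# latent-trajectory closure: value and slope, with optional post-dropout kink
true_traj <- function(cfg, covs, b, kink_age = Inf) {
  spec <- cfg$spec; tp <- cfg$true_params; tc <- cfg$t_center
  function(t, first = FALSE, deriv = 0L) {
    X <- beta_design(spec, t, covs$male, covs$education, covs$cohort,
                     first, NULL, as.integer(deriv))
    base <- if (deriv == 0L)
      drop(X %*% tp$beta) + b[1] + b[2] * (t - tc)
    else drop(X %*% tp$beta) + b[2]
    if (deriv == 0L) base + cfg$true_delta * pmax(t - kink_age, 0)
    else base + cfg$true_delta * (t > kink_age)
  }
}

# cumulative-hazard inversion: piecewise Gauss-Legendre cumulative integral,
# then root-finding inside the bracketing segment.
invert_hazard <- function(h, entry, horizon, E, n_nodes = 7L) {
  if (horizon <= entry) return(Inf)
  gl <- gl_rule(n_nodes)
  seg <- unique(c(seq(entry, horizon, by = 1), horizon))
  M <- length(seg) - 1L
  half <- diff(seg) / 2; mid <- (seg[-1] + seg[-length(seg)]) / 2
  nodes <- rep(mid, each = n_nodes) + rep(half, each = n_nodes) * gl$x
  wts <- rep(half, each = n_nodes) * gl$w
  hv <- h(nodes)
  Hseg <- rowsum(wts * hv, rep(seq_len(M), each = n_nodes))
  cumH <- c(0, cumsum(Hseg))
  if (cumH[M + 1L] < E) return(Inf)
  k <- findInterval(E, cumH, rightmost.closed = TRUE)
  g2 <- gl_rule(n_nodes)
  f <- function(t) {
    if (t <= seg[k]) return(cumH[k] - E)
    hh <- (t - seg[k]) / 2
    cumH[k] + sum(hh * g2$w * h((t + seg[k]) / 2 + hh * g2$x)) - E
  }
  stats::uniroot(f, c(seg[k], seg[k + 1L]), tol = 1e-8)$root
}

#' Simulate a synthetic cohort with known truth
#'
#' Draws random effects, builds latent trajectories from the true joint
#' model (with an optional post-dropout slope change `true_delta`), decides
#' dropout wave-by-wave via the logistic dropout model, simulates dementia
#' onset by inverting the subject's quadrature-evaluated cumulative hazard,
#' simulates death from a Gompertz hazard, and masks the truth into the raw
#' observed tables (scores after dropout/death missing; event and death ages
#' recorded from registry follow-up even after dropout). Bit-identical output
#' for the same config.
#'
#' @param config a [simulation_config()].
#' @param prep preparation rules applied when assembling the returned
#'   dataset. The default disables the early-onset exclusion so that the
#'   returned dataset satisfies the generating model exactly; pass
#'   `prep_rules()` for the study-like filters.
#' @return a list: `dataset` (prepared, pattern-labelled `jmsens_data`),
#'   `raw_long`/`raw_subj` (the unfiltered delimited-style tables), `truth`
#'   (per-subject random effects, true event/death times, dropout wave, true
#'   scores at every scheduled wave), `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            prep = prep_rules(early_onset_cutoff = 0)) {
  cfg <- config
  set.seed(cfg$seed)
  wts <- vapply(cfg$cohorts, `[[`, numeric(1), "weight")
  ci <- sample.int(length(cfg$cohorts), cfg$n_subjects, replace = TRUE,
                   prob = wts)
  dm <- cfg$dropout_model
  subj_rows <- vector("list", cfg$n_subjects)
  long_rows <- vector("list", cfg$n_subjects)
  truth_rows <- vector("list", cfg$n_subjects)
  score_rows <- vector("list", cfg$n_subjects)
  Dch <- chol(cfg$true_params$D)

  for (i in seq_len(cfg$n_subjects)) {
    co <- cfg$cohorts[[ci[i]]]
    entry <- stats::runif(1, co$entry_age_range[1], co$entry_age_range[2])
    sched <- entry + co$wave_spacing * (seq_len(co$n_waves) - 1L)
    sex <- if (stats::runif(1) < 0.5) "male" else "female"
    education <- round(stats::runif(1, 7, 17))
    birth_year <- round(co$enroll_year - entry)
    covs <- list(male = as.numeric(sex == "male"), education = education,
                 cohort = birth_year - 1937)
    b <- drop(stats::rnorm(2) %*% Dch)

    m0 <- true_traj(cfg, covs, b, kink_age = Inf)
    # wave-by-wave dropout on the latent current value / slope random effect
    drop_wave <- co$n_waves
    for (j in seq_len(max(co$n_waves - 1L, 0L))) {
      eta <- dm["intercept"] + dm["age"] * sched[j] +
        dm["value"] * m0(sched[j]) + dm["slope_re"] * b[2]
      if (stats::runif(1) < stats::plogis(eta)) { drop_wave <- j; break }
    }
    kink <- if (drop_wave < co$n_waves) sched[drop_wave] else Inf
    mfun <- true_traj(cfg, covs, b, kink_age = kink)

    # dementia: invert the cumulative hazard of the true model
    tp <- cfg$true_params
    wlin <- tp$gamma[1] * covs$male + tp$gamma[2] * education
    h <- function(t) {
      lh <- drop(evaluate_basis(cfg$spec$baseline_basis, t, 0L) %*%
                   tp$baseline_coefs) + wlin +
        tp$alpha[1] * mfun(t - cfg$spec$lag) +
        tp$alpha[2] * mfun(t - cfg$spec$lag, deriv = 1L)
      exp(lh)
    }
    Tdem <- invert_hazard(h, entry, cfg$horizon, stats::rexp(1))

    # death: Gompertz, closed-form inversion
    dh <- cfg$death_hazard
    Ed <- stats::rexp(1)
    Tdeath <- dh["anchor_age"] + log(exp(dh["shape"] *
                                           (entry - dh["anchor_age"])) +
                                       dh["shape"] * Ed / dh["rate"]) /
      dh["shape"]
    Tdeath <- unname(Tdeath)

    last_eval <- max(sched) + cfg$registry_extra
    onset_age <- if (Tdem < min(Tdeath, last_eval)) Tdem else NA_real_
    death_age <- if (Tdeath <= last_eval) Tdeath else NA_real_

    mtrue <- mfun(sched, first = c(TRUE, rep(FALSE, co$n_waves - 1L)))
    y <- mtrue + stats::rnorm(co$n_waves, 0, sqrt(tp$sigma2))
    if (cfg$clip_scores)
      y <- pmin(pmax(y, cfg$score_bounds[1]), cfg$score_bounds[2])
    in_study <- seq_len(co$n_waves) <= drop_wave
    alive <- sched < Tdeath
    observed <- in_study & alive
    long_rows[[i]] <- data.frame(
      subject_id = i, age = sched,
      score = ifelse(observed, y, NA_real_),
      wave = seq_len(co$n_waves),
      is_first = seq_len(co$n_waves) == 1L,
      observed = observed)
    subj_rows[[i]] <- data.frame(
      subject_id = i, sex = sex, education = education,
      birth_year = birth_year, cohort_label = co$label,
      scheduled_ages = I(list(sched)), entry_age = entry,
      onset_age = onset_age, death_age = death_age,
      last_eval_age = last_eval)
    truth_rows[[i]] <- data.frame(
      subject_id = i, b0 = b[1], b1 = b[2], event_time_true = Tdem,
      death_time_true = Tdeath, drop_wave = drop_wave,
      n_waves = co$n_waves)
    score_rows[[i]] <- data.frame(
      subject_id = i, wave = seq_len(co$n_waves), age = sched,
      m_true = mtrue, y_true = y)
  }

  raw_long <- do.call(rbind, long_rows)
  raw_subj <- do.call(rbind, subj_rows)
  truth <- list(subjects = do.call(rbind, truth_rows),
                scores = do.call(rbind, score_rows))
  ds <- prepare_dataset(raw_long, raw_subj, prep)
  ds <- assign_patterns(ds)
  list(dataset = ds, raw_long = raw_long, raw_subj = raw_subj,
       truth = truth, config = cfg)
}

#' Missingness summary of a simulated dataset
#'
#' Per-pattern subject counts, the fraction of scheduled measurements that
#' are missing, and event counts per pattern.
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param dataset the matching prepared dataset.
#' @return a list with `per_pattern` (data frame) and `missing_fraction`.
#' @export
mask_report <- function(truth, dataset) {
  if (!all(dataset$subjects$subject_id %in% truth$subjects$subject_id))
    stop("dataset and truth do not describe the same subjects")
  drp <- dataset$dropout
  ev <- dataset$subjects$event
  per <- do.call(rbind, lapply(split(seq_len(nrow(drp)), drp$pattern),
    function(ix) data.frame(
      pattern = drp$pattern[ix[1]],
      n = length(ix),
      events = sum(ev[ix]),
      observed = sum(drp$n_observed[ix]))))
  rownames(per) <- NULL
  tot_sched <- sum(truth$subjects$n_waves[
    truth$subjects$subject_id %in% dataset$subjects$subject_id])
  obs <- sum(dataset$longitudinal$observed)
  list(per_pattern = per,
       missing_fraction = 1 - obs / tot_sched,
       n_subjects = nrow(dataset$subjects))
}
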