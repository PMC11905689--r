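# Small in-code fixtures shared across test files.

# a minimal valid subject row
subj_row <- function(id, sex = "female", education = 12, birth_year = 1940,
                     cohort_label = "C6", sched = seq(60, 85, 5),
                     entry_age = sched[1], onset_age = NA_real_,
                     death_age = NA_real_, last_eval_age = max(sched) + 8) {
  data.frame(subject_id = id, sex = sex, education = education,
             birth_year = birth_year, cohort_label = cohort_label,
             scheduled_ages = I(list(sched)), entry_age = entry_age,
             onset_age = onset_age, death_age = death_age,
             last_eval_age = last_eval_age)
}

# longitudinal rows for one subject: observed waves given by `obs`
long_rows <- function(id, sched = seq(60, 85, 5), obs = seq_along(sched),
                      scores = NULL) {
  n <- length(sched)
  if (is.null(scores)) scores <- 30 - 0.3 * (sched - sched[1])
  data.frame(subject_id = id, age = sched,
             score = ifelse(seq_len(n) %in% obs, scores, NA_real_),
             wave = seq_len(n), is_first = seq_len(n) == 1L,
             observed = seq_len(n) %in% obs)
}

# a tiny prepared, pattern-labelled dataset with a mix of patterns
tiny_dataset <- function() {
  subj <- rbind(
    subj_row(1, cohort_label = "C6"),                      # completer 0.a
    subj_row(2, cohort_label = "C6"),                      # dropout after 4
    subj_row(3, cohort_label = "C3", sched = seq(65, 75, 5)),  # completer 0.b
    subj_row(4, cohort_label = "C3", sched = seq(65, 75, 5)),  # 2 obs -> "2"
    subj_row(5, cohort_label = "C6", onset_age = 78))      # dementia event
  lng <- rbind(
    long_rows(1),
    long_rows(2, obs = 1:4),
    long_rows(3, sched = seq(65, 75, 5)),
    long_rows(4, sched = seq(65, 75, 5), obs = 1:2),
    long_rows(5))
  ds <- prepare_dataset(lng, subj, prep_rules())
  assign_patterns(ds)
}

# a fast, small simulated dataset + its true spec for fitting tests
quick_sim <- function(n = 120, seed = 7, true_delta = 0,
                      dropout = c(intercept = -20), ...) {
  simulate_cohort(simulation_config(n_subjects = n, seed = seed,
                                    true_delta = true_delta,
                                    dropout_model = dropout, ...))
}

quick_mcmc <- function(seed = 1, chains = 1L, warmup = 250L,
                       iterations = 250L) {
  mcmc_control(chains = chains, warmup = warmup, iterations = iterations,
               seed = seed)
}

# builds a jmsens_fit whose "posterior" is a set of identical known draws,
# so prediction formulas can be checked against closed forms
manual_fit <- function(params, n_rows = 40, sim_n = 12, seed = 3) {
  sim <- quick_sim(n = sim_n, seed = seed)
  spec <- sim$config$spec
  fr <- jmsens:::build_frame(sim$dataset, spec)
  v <- c(params$beta, params$gamma, params$alpha,
         sqrt(params$sigma2), sqrt(params$D[1, 1]), sqrt(params$D[2, 2]),
         params$D[1, 2] / sqrt(params$D[1, 1] * params$D[2, 2]),
         params$baseline_coefs)
  nm <- c(fr$beta_names, paste0("gamma_", colnames(fr$W)),
          "alpha_value", "alpha_slope", "sigma", "sd_b0", "sd_b1", "cor_b",
          paste0("h0_", seq_along(params$baseline_coefs)))
  draws <- matrix(rep(v, each = n_rows), n_rows, length(v),
                  dimnames = list(NULL, nm))
  re <- array(0, c(n_rows, fr$N, 2L))
  structure(list(chains = list(list(params = draws, re = re,
                                    acceptance = NULL)),
                 param_names = nm, spec = spec, frame = fr,
                 dataset = sim$dataset,
                 control = mcmc_control(chains = 1, warmup = 1,
                                        iterations = n_rows, seed = 1)),
            class = "jmsens_fit")
}

known_params <- function(spec = NULL, alpha = c(0, 0), logh = log(0.05),
                         sigma2 = 16) {
  if (is.null(spec)) spec <- simulate_cohort(
    simulation_config(n_subjects = 5, seed = 1))$config$spec
  jm_parameters(
    beta = c(30, rep(0, 3), -2, 0.5, 0, 0, 0),
    gamma = c(0, 0), alpha = alpha, sigma2 = sigma2,
    D = matrix(c(25, 0.5 * 5 * 0.2, 0.5 * 5 * 0.2, 0.04), 2, 2),
    baseline_coefs = rep(logh, spec$baseline_basis$df))
}

# single-cohort recovery-style config: 4 waves, no dropout
recovery_config <- function(n = 300, seed = 1, ...) {
  simulation_config(
    n_subjects = n,
    cohorts = list(list(label = "R4", entry_age_range = c(50, 75),
                        n_waves = 4L, wave_spacing = 5, enroll_year = 1995,
                        weight = 1)),
    dropout_model = c(intercept = -20),
    seed = seed, ...)
}
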