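# one-subject dataset builder for likelihood arithmetic
one_subject_data <- function(y = 30, age = 65, entry = 60, Tev = 80,
                             event = FALSE) {
  subj <- subj_row(1, sched = age, entry_age = entry)
  subj$entry_age <- entry
  lng <- long_rows(1, sched = age, scores = y)
  ds <- analysis_dataset(lng, transform(subj, event = event,
                                        event_age = Tev))
  ds
}

flat_spec <- function() {
  joint_model_spec(
    long_basis = natural_cubic_basis(knots = c(55, 75), boundary = c(40, 90)),
    baseline_basis = bspline_basis(df = 5, boundary = c(30, 100)))
}

zero_params <- function(spec, b = matrix(0, 1, 2), logc = -3) {
  jm_parameters(
    beta = rep(0, 4 + 5), gamma = c(0, 0), alpha = c(0, 0), sigma2 = 9,
    D = diag(c(25, 0.04)), baseline_coefs = rep(logc, spec$baseline_basis$df),
    random_effects = b)
}

test_that("longitudinal mean reduces to intercept + slope terms", {
  spec <- flat_spec()
  p <- zero_params(spec)
  p$random_effects <- c(2, 0.5)
  subj <- list(sex = "female", education = 0, birth_year = 1937)
  m <- longitudinal_mean(subj, 62, p, spec, t_center = 60)
  expect_equal(m, 2 + 0.5 * 2)
  md <- longitudinal_mean(subj, 62, p, spec, t_center = 60, derivative = 1)
  expect_equal(md, 0.5)
})

test_that("trajectory slope matches finite differences with a curved trend", {
  spec <- flat_spec()
  p <- zero_params(spec)
  p$beta[1:4] <- c(35, -0.3, -1.2, 0.8)  # intercept + spline coefficients
  p$beta[5] <- -2.9                       # male
  p$random_effects <- c(3, -0.2)
  subj <- list(sex = "male", education = 12, birth_year = 1941)
  ages <- seq(46, 88, length.out = 10)
  h <- 1e-5
  md <- longitudinal_mean(subj, ages, p, spec, t_center = 60, derivative = 1)
  fd <- (longitudinal_mean(subj, ages + h, p, spec, t_center = 60) -
           longitudinal_mean(subj, ages - h, p, spec, t_center = 60)) / (2 * h)
  expect_lt(max(abs(md - fd)), 1e-6)
})

test_that("log posterior carries the closed-form survival and data terms", {
  spec <- flat_spec()
  ds <- one_subject_data(entry = 60, Tev = 80)
  # constant baseline hazard c, alpha = gamma = 0: censored subject
  # contributes -c * (b - a); only the first-coefficient prior differs
  lp1 <- log_posterior(ds, zero_params(spec, logc = -3), spec)
  lp2 <- log_posterior(ds, zero_params(spec, logc = -2), spec)
  dprior <- dnorm(-3, 0, 10, log = TRUE) - dnorm(-2, 0, 10, log = TRUE)
  expect_equal(lp1 - lp2, -(exp(-3) - exp(-2)) * 20 + dprior,
               tolerance = 1e-9)

  # longitudinal term is the scalar normal log density in the score
  ds1 <- one_subject_data(y = 30); ds2 <- one_subject_data(y = 25)
  p <- zero_params(spec)
  expect_equal(log_posterior(ds1, p, spec) - log_posterior(ds2, p, spec),
               dnorm(30, 0, 3, log = TRUE) - dnorm(25, 0, 3, log = TRUE),
               tolerance = 1e-9)
})

test_that("quadrature cumulative hazard agrees with a dense trapezoid", {
  sim <- quick_sim(n = 15, seed = 5)
  ds <- sim$dataset
  spec <- sim$config$spec
  fr <- jmsens:::build_frame(ds, spec)
  set.seed(99)
  for (r in 1:5) {
    p <- jm_parameters(
      beta = rnorm(length(fr$beta_names), c(33, rep(0, length(fr$beta_names) - 1)), 0.3),
      gamma = rnorm(2, 0, 0.1), alpha = c(rnorm(1, -0.05, 0.02),
                                          rnorm(1, -0.5, 0.2)),
      sigma2 = 16, D = diag(c(25, 0.04)),
      baseline_coefs = rnorm(spec$baseline_basis$df, -4, 0.3),
      random_effects = matrix(rnorm(2 * fr$N, 0, c(3, 0.1)), fr$N, 2,
                              byrow = TRUE))
    pars <- jmsens:::params_to_internal(p)
    comp <- jmsens:::frame_components(fr, pars, p$random_effects)
    i <- which.max(fr$Tev - fr$entry)  # longest follow-up
    grid <- seq(fr$entry[i], fr$Tev[i], length.out = 10001)
    Xg <- jmsens:::beta_design(spec, grid - spec$lag, fr$male[i], fr$edu[i],
                               fr$cohort[i], 0, NULL, 0L)
    Xgd <- jmsens:::beta_design(spec, grid - spec$lag, fr$male[i], fr$edu[i],
                                fr$cohort[i], 0, NULL, 1L)
    b <- p$random_effects[i, ]
    mg <- drop(Xg %*% p$beta) + b[1] + b[2] * (grid - spec$lag - fr$t_center)
    mgd <- drop(Xgd %*% p$beta) + b[2]
    logh <- drop(evaluate_basis(spec$baseline_basis, grid) %*%
                   p$baseline_coefs) +
      sum(p$gamma * fr$W[i, ]) + p$alpha[1] * mg + p$alpha[2] * mgd
    H_trap <- sum(diff(grid) * (exp(logh[-1]) + exp(logh[-length(logh)])) / 2)
    # Gauss-Legendre is not exact across the spline knots inside the
    # interval, so agreement is to ~1e-5 over multi-decade follow-up
    expect_lt(abs(comp$cum[i] - H_trap) / H_trap, 2e-5)
  }
})

test_that("with no association the survival posterior ignores the scores", {
  sim <- quick_sim(n = 30, seed = 6)
  ds <- sim$dataset
  spec <- sim$config$spec
  fr <- jmsens:::build_frame(ds, spec)
  p <- jm_parameters(beta = rep(0, length(fr$beta_names)), gamma = c(0, 0),
                     alpha = c(0, 0), sigma2 = 16, D = diag(c(25, 0.04)),
                     baseline_coefs = rep(-4, spec$baseline_basis$df),
                     random_effects = matrix(0, fr$N, 2))
  p2 <- p; p2$gamma <- c(-0.4, 0.05)
  dl_orig <- log_posterior(ds, p2, spec) - log_posterior(ds, p, spec)
  # permute observed scores across rows: the gamma contrast is unchanged
  set.seed(1)
  perm <- sample(nrow(ds$longitudinal))
  ds_p <- ds
  ds_p$longitudinal$score <- ds$longitudinal$score[perm]
  ds_p$longitudinal$observed <- ds$longitudinal$observed[perm]
  ds_p$longitudinal$score[!ds_p$longitudinal$observed] <- NA
  ds_p$longitudinal$score[ds_p$longitudinal$observed &
                            is.na(ds_p$longitudinal$score)] <- 20
  dl_perm <- log_posterior(ds_p, p2, spec) - log_posterior(ds_p, p, spec)
  expect_equal(dl_orig, dl_perm, tolerance = 1e-10)
})

test_that("log posterior names the offending subject on non-finite input", {
  spec <- flat_spec()
  ds <- one_subject_data()
  p <- zero_params(spec)
  p$random_effects <- matrix(c(Inf, 0), 1, 2)
  expect_error(log_posterior(ds, p, spec), "subject")
})

test_that("fitting is deterministic given the seed and needs events", {
  sim <- quick_sim(n = 60, seed = 9)
  ctl <- quick_mcmc(seed = 3, warmup = 80, iterations = 60)
  f1 <- fit_joint_model(sim$dataset, sim$config$spec, ctl)
  f2 <- fit_joint_model(sim$dataset, sim$config$spec, ctl)
  expect_identical(f1$chains[[1]]$params, f2$chains[[1]]$params)
  expect_identical(f1$chains[[1]]$re, f2$chains[[1]]$re)

  ds0 <- sim$dataset
  ds0$subjects$event <- FALSE
  expect_error(fit_joint_model(ds0, sim$config$spec, ctl), "event")
})

test_that("PSRF behaves on iid, duplicated, and separated chains", {
  set.seed(21)
  iid <- list(matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x")),
              matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x")))
  dg <- convergence_diagnostics(iid)
  expect_gt(dg$summary$psrf_split, 0.99)
  expect_lt(dg$summary$psrf_split, 1.02)
  expect_equal(dg$flagged, character(0))

  dup <- list(iid[[1]], iid[[1]])
  dg2 <- convergence_diagnostics(dup)
  expect_lte(dg2$summary$psrf_basic, 1 + 1e-6)

  sep <- list(iid[[1]], iid[[2]] + 10)
  dg3 <- convergence_diagnostics(sep)
  expect_gt(dg3$summary$psrf_split, 2)
  expect_equal(dg3$flagged, "x")

  expect_warning(convergence_diagnostics(iid[1]), "single chain")
})

test_that("a short fit recovers the residual SD on clean simulated data", {
  sim <- quick_sim(n = 150, seed = 13, cohorts = list(
    list(label = "R4", entry_age_range = c(50, 75), n_waves = 4L,
         wave_spacing = 5, enroll_year = 1995, weight = 1)))
  fit <- fit_joint_model(sim$dataset, sim$config$spec,
                         quick_mcmc(seed = 2, warmup = 300, iterations = 300))
  sm <- summary(fit)
  srow <- sm[sm$parameter == "sigma", ]
  expect_lt(abs(srow$mean - 4), 3 * srow$sd)
  # random-walk blocks sit near the adaptation target; the conditional
  # Gaussian beta proposal accepts much more often
  acc <- fit$chains[[1]]$acceptance
  expect_true(all(acc[c("surv", "theta", "var", "random_effects")] > 0.2 &
                    acc[c("surv", "theta", "var", "random_effects")] < 0.7))
  expect_gt(acc[["beta"]], 0.3)
})
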