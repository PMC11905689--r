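test_that("the generator is bit-identical under a fixed seed", {
  s1 <- quick_sim(n = 50, seed = 19, dropout = c(intercept = 1, value = -0.1))
  s2 <- quick_sim(n = 50, seed = 19, dropout = c(intercept = 1, value = -0.1))
  expect_identical(s1$raw_long, s2$raw_long)
  expect_identical(s1$raw_subj, s2$raw_subj)
  expect_identical(s1$truth, s2$truth)
  s3 <- quick_sim(n = 50, seed = 20, dropout = c(intercept = 1, value = -0.1))
  expect_false(identical(s1$raw_long, s3$raw_long))
})

test_that("without dropout every survivor completes their schedule", {
  sim <- quick_sim(n = 80, seed = 3)
  mr <- mask_report(sim$truth, sim$dataset)
  expect_true(all(sim$truth$subjects$drop_wave ==
                    sim$truth$subjects$n_waves))
  # missingness only from death/dementia truncation, none from dropout
  expect_true(all(sim$dataset$dropout$pattern %in% c("0.a", "0.b")))
  expect_equal(sum(mr$per_pattern$n), nrow(sim$dataset$subjects))
})

test_that("mask report arithmetic matches a forced dropout pattern", {
  # all subjects in a 6-wave cohort dropping after wave 2 -> 4/6 missing
  cfg <- simulation_config(
    n_subjects = 40,
    cohorts = list(list(label = "C6", entry_age_range = c(50, 60),
                        n_waves = 6L, wave_spacing = 5, enroll_year = 1990,
                        weight = 1)),
    dropout_model = c(intercept = 50),  # certain dropout after wave 1...
    death_hazard = c(rate = 1e-8, shape = 0.01, anchor_age = 60),
    true_params = local({
      tp <- default_true_params()
      tp$baseline_coefs[] <- -20  # essentially no dementia
      tp
    }),
    seed = 5)
  sim <- simulate_cohort(cfg)
  # certain dropout after wave 1: 5/6 of scheduled measurements missing
  expect_equal(mask_report(sim$truth, sim$dataset)$missing_fraction, 5 / 6)
  expect_true(all(sim$dataset$dropout$pattern == "2"))
})

test_that("event times follow the exponential law under a constant hazard", {
  rate <- 0.08
  cfg <- simulation_config(
    n_subjects = 5000,
    cohorts = list(list(label = "C1", entry_age_range = c(50, 50.0001),
                        n_waves = 1L, wave_spacing = 5, enroll_year = 2000,
                        weight = 1)),
    true_params = local({
      tp <- default_true_params()
      tp$alpha <- c(0, 0)
      tp$gamma <- c(0, 0)
      tp$baseline_coefs[] <- log(rate)
      tp
    }),
    death_hazard = c(rate = 1e-9, shape = 0.01, anchor_age = 60),
    horizon = 250, seed = 27)
  # wide spline support so the baseline covers the long horizon
  cfg$spec$baseline_basis <- bspline_basis(df = 9, boundary = c(30, 260))
  cfg$spec$long_basis <- natural_cubic_basis(knots = c(55, 75),
                                             boundary = c(35, 95))
  sim <- simulate_cohort(cfg)
  tt <- sim$truth$subjects$event_time_true - 50
  expect_true(all(is.finite(tt)))
  ks <- ks.test(tt, "pexp", rate)
  expect_gt(ks$p.value, 0.01)
})

test_that("latent-decline dropout induces the expected selection effect", {
  # dropout driven by a negative random slope: completers of the long cohort
  # over-represent positive slopes
  sim <- quick_sim(n = 2000, seed = 33,
                   dropout = c(intercept = -1, slope_re = -6))
  tr <- sim$truth$subjects
  completer <- tr$drop_wave == tr$n_waves & tr$n_waves > 1
  expect_gt(mean(tr$b1[completer]), mean(tr$b1[tr$n_waves > 1]) + 0.01)
})

test_that("true post-dropout decline appears only after the dropout wave", {
  sim <- quick_sim(n = 300, seed = 29, true_delta = -2,
                   dropout = c(intercept = 0.5))
  sim0 <- quick_sim(n = 300, seed = 29, true_delta = 0,
                    dropout = c(intercept = 0.5))
  # same seed: identical until the kink; post-dropout true scores differ by
  # exactly delta * years-past-dropout
  tr <- merge(sim$truth$scores, sim0$truth$scores,
              by = c("subject_id", "wave", "age"))
  dw <- sim$truth$subjects$drop_wave[match(tr$subject_id,
                                           sim$truth$subjects$subject_id)]
  da <- tr$age - (tr$age - 5 * (tr$wave - dw))  # dropout age per row
  past <- tr$wave > dw
  expect_equal(tr$m_true.x[!past], tr$m_true.y[!past])
  expect_equal(tr$m_true.x[past] - tr$m_true.y[past],
               -2 * (tr$age[past] - (tr$age[past] - 5 * (tr$wave[past] -
                                                           dw[past]))),
               tolerance = 1e-10)
})

test_that("default study conditions look like a long-running aging cohort", {
  sim <- quick_sim(n = 1000, seed = 3,
                   dropout = c(intercept = 1.5, value = -0.1))
  ds <- sim$dataset
  ev <- mean(ds$subjects$event)
  expect_gt(ev, 0.10); expect_lt(ev, 0.20)
  dead <- mean(!is.na(ds$subjects$death_age))
  expect_gt(dead, 0.30); expect_lt(dead, 0.55)
  mf <- mask_report(sim$truth, ds)$missing_fraction
  expect_gt(mf, 0.22); expect_lt(mf, 0.38)
  expect_setequal(unique(ds$dropout$pattern),
                  c("0.a", "0.b", "2", "3", "4", "5"))
  # the default mean trajectory: mid-life plateau, accelerating decline
  spec <- sim$config$spec; tp <- sim$config$true_params
  m <- drop(jmsens:::beta_design(spec, c(40, 95), 0, 11, 0, FALSE) %*%
              tp$beta)
  expect_lt(abs(m[1] - 39.5), 2)
  expect_lt(abs(m[2] - 14), 3)
})

test_that("mask_report validates subject matching", {
  sim <- quick_sim(n = 20, seed = 2)
  truth2 <- sim$truth
  truth2$subjects <- truth2$subjects[-1, ]
  expect_error(mask_report(truth2, sim$dataset), "same subjects")
})
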