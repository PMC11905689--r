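test_that("delta offsets follow the three sensitivity specifications", {
  # constant: -1 per year past dropout
  expect_equal(delta_offset(delta_constant(-1), t = 70, dropout_age = 65), -5)
  # cubic defaults: rate -1 at age 100, 0 at age 25
  expect_equal(delta_value(delta_cubic(), 100), -1)
  expect_equal(delta_value(delta_cubic(), 25), 0)
  # threshold: dropout at 59 is before the cutoff -> no offset at any age
  expect_equal(delta_offset(delta_threshold(-1, 60), t = c(65, 80, 95),
                            dropout_age = 59), c(0, 0, 0))
  # threshold: dropout after 60 declines 1/year extra
  expect_equal(delta_offset(delta_threshold(-1, 60), t = 70,
                            dropout_age = 62), -8)
})

test_that("every delta spec is continuous at the dropout age", {
  specs <- list(delta_constant(-1), delta_constant(0.5),
                delta_threshold(-1, 60), delta_cubic(),
                delta_cubic(eval_at = "dropout"))
  for (sp in specs) {
    for (da in c(45, 61, 80)) {
      expect_equal(delta_offset(sp, t = da, dropout_age = da), 0)
      expect_equal(delta_offset(sp, t = da - 3, dropout_age = da), 0)
    }
  }
  # cubic is never positive at or above its floor age
  expect_true(all(delta_value(delta_cubic(), seq(25, 110, 5)) <= 0))
})

test_that("imputation targets respect dropout, events, death and gaps", {
  mk <- function(subj, lng) {
    assign_patterns(prepare_dataset(lng, subj,
                                    prep_rules(early_onset_cutoff = 0)))
  }
  # dropout after 65 (sched 60..75), dementia at 72: only age 70 eligible
  subj <- subj_row(1, sched = seq(60, 75, 5), onset_age = 72)
  ds <- mk(subj, long_rows(1, sched = seq(60, 75, 5), obs = 1:2))
  tg <- enumerate_targets(ds)
  expect_equal(tg$age, 70)
  # with dementia at 68 nothing is scheduled in (65, 68): no targets
  subj$onset_age <- 68
  ds <- mk(subj, long_rows(1, sched = seq(60, 75, 5), obs = 1:2))
  expect_equal(nrow(enumerate_targets(ds)), 0L)

  # intermittent gap at 65 with dropout at 70: 65 is never a target
  subj <- subj_row(2, sched = seq(60, 75, 5))
  ds <- mk(subj, long_rows(2, sched = seq(60, 75, 5), obs = c(1, 3)))
  tg <- enumerate_targets(ds)
  expect_equal(tg$age, 75)

  # completers yield nothing
  subj <- subj_row(3, sched = seq(60, 75, 5))
  ds <- mk(subj, long_rows(3, sched = seq(60, 75, 5)))
  expect_equal(nrow(enumerate_targets(ds)), 0L)

  # death bounds imputation strictly
  subj <- subj_row(4, sched = seq(60, 75, 5), death_age = 71)
  ds <- mk(subj, long_rows(4, sched = seq(60, 75, 5), obs = 1:2))
  expect_equal(enumerate_targets(ds)$age, 70)
})

mnar_fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- quick_sim(n = 120, seed = 31, true_delta = -1,
                       dropout = c(intercept = 1.5, value = -0.1))
      fit <- fit_imputation_model(
        sim$dataset,
        imputation_model_spec(sim$config$spec, pattern_df = 1L),
        quick_mcmc(seed = 4, warmup = 200, iterations = 200))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})

test_that("imputation fills only targets, floors at 0, and flags rows", {
  fx <- mnar_fit_fixture()
  ds <- fx$sim$dataset
  comp <- impute_missing(ds, fx$fit, delta_constant(0), K = 3, seed = 5)
  expect_length(comp, 3)
  tg <- enumerate_targets(ds)
  for (k in 1:3) {
    ck <- comp[[k]]
    expect_equal(sum(ck$longitudinal$imputed), nrow(tg))
    expect_true(all(ck$longitudinal$score[ck$longitudinal$imputed] >= 0))
    # observed rows bit-identical to the base dataset
    keep <- !ck$longitudinal$imputed
    expect_identical(ck$longitudinal$score[keep],
                     ds$longitudinal$score[keep])
  }
  # a hugely negative constant delta drives imputations onto the floor
  comp0 <- impute_missing(ds, fx$fit, delta_constant(-1000), K = 1, seed = 5)
  imp <- comp0[[1]]$longitudinal
  expect_true(all(imp$score[imp$imputed] == 0))
})

test_that("scenarios share the fit and differ only in imputed values", {
  fx <- mnar_fit_fixture()
  ds <- fx$sim$dataset
  c0 <- impute_missing(ds, fx$fit, delta_constant(0), K = 2, seed = 9)
  c1 <- impute_missing(ds, fx$fit, delta_constant(-1), K = 2, seed = 9)
  keep <- !c0[[1]]$longitudinal$imputed
  expect_identical(c0[[1]]$longitudinal[keep, c("score", "observed")],
                   c1[[1]]$longitudinal[keep, c("score", "observed")])
  # same seed -> same selected draws and noise: the difference is exactly
  # the delta offset, so imputed means are ordered by delta
  tg <- enumerate_targets(ds)
  d01 <- c1[[1]]$longitudinal$score[c1[[1]]$longitudinal$imputed] -
    c0[[1]]$longitudinal$score[c0[[1]]$longitudinal$imputed]
  yrs <- tg$age - tg$dropout_age
  floored <- c0[[1]]$longitudinal$score[c0[[1]]$longitudinal$imputed] <=
    -yrs | c1[[1]]$longitudinal$score[c1[[1]]$longitudinal$imputed] == 0
  expect_equal(d01[!floored], -yrs[!floored], tolerance = 1e-10)
  expect_error(impute_missing(ds, fx$fit, delta_constant(0), K = 10000,
                              seed = 1), "exceeds")
})

test_that("average imputations shift by delta times years past dropout", {
  fx <- mnar_fit_fixture()
  ds <- fx$sim$dataset
  tg <- enumerate_targets(ds)
  M <- 200
  mean_imp <- function(delta, seed)
    Reduce(`+`, lapply(impute_missing(ds, fx$fit, delta, K = M, seed = seed),
                       function(ck)
                         ck$longitudinal$score[ck$longitudinal$imputed])) / M
  m0 <- mean_imp(delta_constant(0), 11)
  m1 <- mean_imp(delta_constant(-1), 12)
  yrs <- tg$age - tg$dropout_age
  # restrict to targets far from the floor so clipping cannot bias the mean
  ok <- m0 > 12 + max(yrs)
  expect_gt(sum(ok), 5)
  expect_lt(max(abs((m1 - m0)[ok] - (-yrs[ok]))), 2.5)
  # pointwise monotonicity in delta on the same targets
  expect_true(all((m1 - m0)[ok] < 0))
})

test_that("single-pattern imputation model reduces to the substantive model", {
  sim <- quick_sim(n = 40, seed = 17)  # no dropout: all completers
  ds <- sim$dataset
  ds$dropout$pattern <- "0.a"
  spec_s <- sim$config$spec
  spec_i <- imputation_model_spec(spec_s, pattern_df = 1L)
  fr <- jmsens:::build_frame(ds, spec_i)
  # deviation columns are absent when only the reference pattern exists
  expect_equal(fr$beta_names,
               jmsens:::build_frame(ds, spec_s)$beta_names)
  p <- jm_parameters(beta = rep(0.1, length(fr$beta_names)),
                     gamma = c(0, 0), alpha = c(-0.05, -0.5), sigma2 = 16,
                     D = diag(c(25, 0.04)),
                     baseline_coefs = rep(-4, spec_s$baseline_basis$df),
                     random_effects = matrix(0, fr$N, 2))
  expect_equal(log_posterior(ds, p, spec_i), log_posterior(ds, p, spec_s))
})

test_that("pattern-level deviations are recovered from two-pattern data", {
  # two cohorts; pattern-2 subjects get a true level offset of -5
  sim <- quick_sim(n = 150, seed = 23,
                   dropout = c(intercept = 0.1))  # ~50% dropout, MCAR
  ds <- sim$dataset
  pat2 <- ds$dropout$pattern == "2"
  skip_if(sum(pat2) < 15)
  shift <- ds$longitudinal$subject_id %in% ds$subjects$subject_id[pat2]
  ds$longitudinal$score[shift & ds$longitudinal$observed] <-
    ds$longitudinal$score[shift & ds$longitudinal$observed] - 5
  fit <- fit_imputation_model(
    ds, imputation_model_spec(sim$config$spec, pattern_df = 0L),
    quick_mcmc(seed = 6, warmup = 300, iterations = 300))
  sm <- summary(fit)
  dev2 <- sm[sm$parameter == "dev_2_0", ]
  expect_lt(abs(dev2$mean - (-5)), 3 * dev2$sd)
})
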