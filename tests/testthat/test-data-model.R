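test_that("preparation filters apply the onset, censoring and exclusion rules", {
  # dementia at 70: assessments at 70 and 75 are deleted, 65 kept
  subj <- subj_row(1, sched = c(65, 70, 75), onset_age = 70)
  lng <- long_rows(1, sched = c(65, 70, 75))
  ds <- prepare_dataset(lng, subj)
  expect_equal(ds$longitudinal$age, 65)
  expect_true(ds$subjects$event)
  expect_equal(ds$subjects$event_age, 70)
  rep <- attr(ds, "preparation_report")
  expect_equal(rep$rows_after_onset_removed, 2L)

  # non-demented: censored at the earlier of death and last evaluation
  subj <- subj_row(1, sched = c(65, 70), death_age = 80, last_eval_age = 85)
  ds <- prepare_dataset(long_rows(1, sched = c(65, 70)), subj)
  expect_equal(ds$subjects$event_age, 80)
  expect_false(ds$subjects$event)

  # neither death nor evaluation: last assessment + 0.003
  subj <- subj_row(1, sched = c(65, 70))
  subj$last_eval_age <- NA_real_
  ds <- prepare_dataset(long_rows(1, sched = c(65, 70)), subj)
  expect_equal(ds$subjects$event_age, 70.003)

  # early onset before the cutoff: subject dropped entirely
  subj <- rbind(subj_row(1, sched = c(55, 60), onset_age = 60),
                subj_row(2, sched = c(55, 60)))
  lng <- rbind(long_rows(1, sched = c(55, 60)),
               long_rows(2, sched = c(55, 60)))
  ds <- prepare_dataset(lng, subj)
  expect_equal(ds$subjects$subject_id, 2)
  expect_equal(attr(ds, "preparation_report")$early_onset_subjects_removed,
               1L)

  # missing education: listwise deletion with row counts
  subj <- rbind(subj_row(1), subj_row(2, education = NA))
  lng <- rbind(long_rows(1), long_rows(2))
  ds <- prepare_dataset(lng, subj)
  expect_equal(ds$subjects$subject_id, 1)
  rep <- attr(ds, "preparation_report")
  expect_equal(rep$missing_education_subjects_removed, 1L)
  expect_equal(rep$missing_education_rows_removed, 6L)
})

test_that("preparation is idempotent", {
  sim <- quick_sim(n = 80, seed = 11,
                   dropout = c(intercept = 1.5, value = -0.1))
  ds1 <- prepare_dataset(sim$raw_long, sim$raw_subj,
                         prep_rules(early_onset_cutoff = 0))
  sj <- ds1$subjects
  ds2 <- prepare_dataset(ds1$longitudinal, sj,
                         prep_rules(early_onset_cutoff = 0))
  expect_equal(ds2$longitudinal, ds1$longitudinal)
  expect_equal(ds2$subjects$event_age, ds1$subjects$event_age)
  expect_equal(ds2$t_center, ds1$t_center)
})

test_that("dataset validation rejects malformed input", {
  subj <- subj_row(1)
  lng <- long_rows(2)  # unknown subject
  expect_error(prepare_dataset(lng, subj), "unknown subject")
  # negative follow-up
  subj <- subj_row(1, death_age = 50)
  expect_error(prepare_dataset(long_rows(1), subj), "negative follow-up")
  # observed flag inconsistent with score
  subj <- transform(subj_row(1, sched = c(60, 65)), event = FALSE,
                    event_age = 70)
  lng <- long_rows(1, sched = c(60, 65))
  lng$observed[2] <- FALSE  # but score present
  expect_error(analysis_dataset(lng, subj), "observed")
})

test_that("pattern assignment matches the six-pattern scheme", {
  ds <- tiny_dataset()
  pat <- setNames(ds$dropout$pattern, ds$dropout$subject_id)
  expect_equal(unname(pat["1"]), "0.a")  # long-cohort completer
  expect_equal(unname(pat["2"]), "4")    # long-cohort dropout after wave 4
  expect_equal(unname(pat["3"]), "0.b")  # short-cohort completer
  expect_equal(unname(pat["4"]), "2")    # two observed waves
  # subject 5: demented at 78, observed all at-risk waves -> completer
  expect_equal(unname(pat["5"]), "0.a")

  # partition: every subject exactly one label
  expect_false(anyNA(ds$dropout$pattern))
  expect_equal(sum(table(ds$dropout$pattern)), nrow(ds$subjects))
})

test_that("pattern labels are stable under subject removal", {
  ds <- tiny_dataset()
  keep <- ds$subjects$subject_id != 4
  ds2 <- analysis_dataset(
    ds$longitudinal[ds$longitudinal$subject_id != 4, ],
    ds$subjects[keep, ])
  ds2 <- assign_patterns(ds2)
  merged <- merge(ds$dropout[, c("subject_id", "pattern")],
                  ds2$dropout[, c("subject_id", "pattern")],
                  by = "subject_id")
  expect_equal(merged$pattern.x, merged$pattern.y)
})

test_that("non-exhaustive schemes raise a named error", {
  # long-cohort dropout after wave 6 of 7 has no pattern rule
  subj <- subj_row(9, sched = seq(50, 80, 5))
  lng <- long_rows(9, sched = seq(50, 80, 5), obs = 1:6)
  ds <- prepare_dataset(lng, subj)
  expect_error(assign_patterns(ds), "subject 9")
})

test_that("time centering is the observation-weighted mean age", {
  subj <- rbind(subj_row(1, sched = c(60, 70)), subj_row(2, sched = 80))
  lng <- rbind(long_rows(1, sched = c(60, 70)), long_rows(2, sched = 80))
  ds <- prepare_dataset(lng, subj)
  expect_equal(ds$t_center, 70)
  expect_equal(compute_time_center(ds), 70)

  # unobserved rows are excluded
  subj <- subj_row(1, sched = c(50, 60))
  lng <- long_rows(1, sched = c(50, 60), obs = 1)
  ds <- prepare_dataset(lng, subj)
  expect_equal(ds$t_center, 50)

  # degenerate: identical ages
  subj <- rbind(subj_row(1, sched = 55), subj_row(2, sched = 55))
  lng <- rbind(long_rows(1, sched = 55), long_rows(2, sched = 55))
  expect_equal(prepare_dataset(lng, subj)$t_center, 55)
})

test_that("tables round-trip through the delimited dialect", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_jm_tables(ds, dir, "t")
  tabs <- read_jm_tables(file.path(dir, "t_long.csv"),
                         file.path(dir, "t_subjects.csv"))
  ds2 <- analysis_dataset(tabs$longitudinal, tabs$subjects)
  expect_equal(ds2$longitudinal$score, ds$longitudinal$score)
  expect_equal(ds2$subjects$scheduled_ages, ds$subjects$scheduled_ages,
               ignore_attr = TRUE)
  expect_equal(ds2$t_center, ds$t_center)
})
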