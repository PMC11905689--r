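#' Assemble and validate a longitudinal/survival analysis dataset
#'
#' Bundles a long-format table of repeated cognitive assessments with a
#' subject-level table of covariates and event information, validates the
#' cross-references and invariants, and computes the centering age and
#' per-subject dropout information.
#'
#' `longitudinal` must contain columns `subject_id`, `age` (years), `score`
#' (points, `NA` when unobserved), `wave` (1-based index of the scheduled
#' wave), `is_first` (logical, first-ever assessment) and `observed`
#' (logical). `subjects` must contain `subject_id`, `sex` (`"male"`/
#' `"female"`), `education` (years), `birth_year`, `cohort_label`,
#' `scheduled_ages` (list column of numeric vectors, or a `";"`-separated
#' string), `entry_age`, `event_age`, `event` (logical, dementia), and
#' optionally `death_age`, `last_eval_age` and `onset_age` (`NA` where
#' absent). The birth-cohort covariate used in the models is
#' `birth_year - cohort_ref` (default 1937).
#'
#' @param longitudinal data frame of assessments (see Details).
#' @param subjects subject-level data frame (see Details).
#' @param t_center centering age \eqn{\bar t}; if `NULL`, computed by
#'   [compute_time_center()].
#' @param cohort_ref reference birth year for the cohort covariate.
#' @return an object of class `jmsens_data`: a list with elements
#'   `longitudinal`, `subjects`, `dropout` and `t_center`.
#' @export
analysis_dataset <- function(longitudinal, subjects, t_center = NULL,
                             cohort_ref = 1937) {
  longitudinal <- as.data.frame(longitudinal)
  subjects <- as.data.frame(subjects)
  need_l <- c("subject_id", "age", "score", "wave", "is_first", "observed")
  need_s <- c("subject_id", "sex", "education", "birth_year", "cohort_label",
              "scheduled_ages", "entry_age", "event_age", "event")
  miss <- setdiff(need_l, names(longitudinal))
  if (length(miss)) stop("longitudinal table lacks columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(subjects))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (opt in c("death_age", "last_eval_age", "onset_age"))
    if (is.null(subjects[[opt]])) subjects[[opt]] <- NA_real_
  if (!is.list(subjects$scheduled_ages))
    subjects$scheduled_ages <- parse_age_list(subjects$scheduled_ages)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id in subject table")
  unknown <- setdiff(longitudinal$subject_id, subjects$subject_id)
  if (length(unknown))
    stop("longitudinal rows reference unknown subject(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (!all(subjects$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(longitudinal$age < 20 | longitudinal$age > 110))
    stop("assessment ages must lie in [20, 110]")
  if (!identical(longitudinal$observed, !is.na(longitudinal$score)))
    stop("observed flag must match score missingness (observed <=> score present)")
  if (any(subjects$event_age < subjects$entry_age - 1e-9))
    stop("negative follow-up: event_age < entry_age for subject(s) ",
         paste(subjects$subject_id[subjects$event_age <
                                     subjects$entry_age - 1e-9],
               collapse = ", "))
  bad <- vapply(split(longitudinal, longitudinal$subject_id), function(d) {
    d <- d[order(d$wave), ]
    any(diff(d$age) <= 0) || sum(d$is_first) > 1L
  }, logical(1))
  if (any(bad))
    stop("waves must be strictly increasing in age and at most one ",
         "is_first row per subject: ", paste(names(bad)[bad], collapse = ", "))
  longitudinal <- longitudinal[order(match(longitudinal$subject_id,
                                           subjects$subject_id),
                               longitudinal$wave), , drop = FALSE]
  rownames(longitudinal) <- NULL
  ds <- structure(list(longitudinal = longitudinal, subjects = subjects,
                       dropout = NULL, t_center = NA_real_,
                       cohort_ref = cohort_ref),
                  class = "jmsens_data")
  ds$t_center <- if (is.null(t_center)) compute_time_center(ds) else t_center
  ds$dropout <- dropout_info(ds)
  ds
}

parse_age_list <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(s) as.numeric(s))
}

format_age_list <- function(x) {
  vapply(x, function(v) paste(format(v, trim = TRUE), collapse = ";"),
         character(1))
}

#' Observation-weighted mean assessment age
#'
#' Returns the mean age over all *observed* assessments,
#' \eqn{\bar t = \sum_{ij} r_{ij} t_{ij} / \sum_{ij} r_{ij}}, the age used to
#' center time in the longitudinal submodel.
#'
#' @param dataset a `jmsens_data` object.
#' @return the centering age in years.
#' @export
compute_time_center <- function(dataset) {
  obs <- dataset$longitudinal[dataset$longitudinal$observed, ]
  if (nrow(obs) == 0L) stop("no observed assessments; cannot center time")
  mean(obs$age)
}

# Per-subject dropout time: wave index and age of the last observed row.
dropout_info <- function(dataset) {
  obs <- dataset$longitudinal[dataset$longitudinal$observed, ]
  sp <- split(obs, factor(obs$subject_id, levels = dataset$subjects$subject_id))
  out <- data.frame(
    subject_id = dataset$subjects$subject_id,
    n_observed = vapply(sp, nrow, integer(1)),
    last_obs_index = vapply(sp, function(d)
      if (nrow(d)) max(d$wave) else NA_integer_, integer(1)),
    dropout_age = vapply(sp, function(d)
      if (nrow(d)) d$age[which.max(d$wave)] else NA_real_, numeric(1)),
    pattern = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Preparation rules for raw study tables
#'
#' Configuration for [prepare_dataset()]. Defaults mirror a prospective
#' aging-cohort design: assessments at or after dementia onset are removed,
#' censoring for non-demented subjects is the earlier of death and the last
#' dementia evaluation, subjects whose follow-up information is entirely
#' absent are censored one day (0.003 years) after their last assessment,
#' early-onset cases (before 65) are excluded, and subjects with missing
#' education are removed listwise.
#'
#' @param early_onset_cutoff exclude subjects with dementia onset before this
#'   age (years).
#' @param censor_offset years added to the last assessment age when neither a
#'   death age nor an evaluation age is available (default 0.003, about one
#'   day).
#' @param drop_missing_education logical; listwise-delete subjects with
#'   missing education.
#' @param cohort_ref reference birth year for the cohort covariate.
#' @return a list of class `jmsens_prep_rules`.
#' @export
prep_rules <- function(early_onset_cutoff = 65, censor_offset = 0.003,
                       drop_missing_education = TRUE, cohort_ref = 1937) {
  structure(list(early_onset_cutoff = early_onset_cutoff,
                 censor_offset = censor_offset,
                 drop_missing_education = drop_missing_education,
                 cohort_ref = cohort_ref),
            class = "jmsens_prep_rules")
}

#' Prepare raw study tables for joint-model analysis
#'
#' Applies the data-preparation filters to raw long/subject tables and
#' returns a validated [analysis_dataset()]. The raw subject table carries
#' `onset_age` (dementia onset, `NA` if never diagnosed), `death_age` and
#' `last_eval_age` (latest dementia evaluation), from which the event
#' indicator and event/censoring age are derived:
#' \enumerate{
#'   \item assessments at ages >= dementia onset are deleted (onset itself is
#'     treated as post-diagnosis, conservatively);
#'   \item subjects with onset before `rules$early_onset_cutoff` are dropped
#'     entirely;
#'   \item subjects with missing education are dropped with all their rows
#'     (if `rules$drop_missing_education`);
#'   \item for non-demented subjects the censoring age is
#'     `min(death_age, last_eval_age)` ("whichever comes first"); when both
#'     are absent it is the last observed assessment age plus
#'     `rules$censor_offset`.
#' }
#' All removal counts are recorded in `attr(, "preparation_report")`.
#' Re-applying the same rules to the prepared tables is a no-op.
#'
#' @param raw_long long-format assessment table (see [analysis_dataset()]).
#' @param raw_subj raw subject table with `onset_age`, `death_age`,
#'   `last_eval_age` instead of `event`/`event_age`.
#' @param rules a [prep_rules()] object.
#' @return a `jmsens_data` object with a `preparation_report` attribute.
#' @export
prepare_dataset <- function(raw_long, raw_subj, rules = prep_rules()) {
  raw_long <- as.data.frame(raw_long)
  raw_subj <- as.data.frame(raw_subj)
  if (!is.list(raw_subj$scheduled_ages))
    raw_subj$scheduled_ages <- parse_age_list(raw_subj$scheduled_ages)
  for (opt in c("onset_age", "death_age", "last_eval_age"))
    if (is.null(raw_subj[[opt]])) raw_subj[[opt]] <- NA_real_
  unknown <- setdiff(raw_long$subject_id, raw_subj$subject_id)
  if (length(unknown))
    stop("longitudinal rows reference unknown subject(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  report <- list()

  # (a) delete assessments at or after dementia onset
  onset <- raw_subj$onset_age[match(raw_long$subject_id, raw_subj$subject_id)]
  post <- !is.na(onset) & raw_long$age >= onset - 1e-9
  report$rows_after_onset_removed <- sum(post)
  raw_long <- raw_long[!post, , drop = FALSE]

  # (b) early-onset exclusion
  early <- !is.na(raw_subj$onset_age) &
    raw_subj$onset_age < rules$early_onset_cutoff
  report$early_onset_subjects_removed <- sum(early)
  report$early_onset_rows_removed <-
    sum(raw_long$subject_id %in% raw_subj$subject_id[early])
  raw_subj <- raw_subj[!early, , drop = FALSE]
  raw_long <- raw_long[raw_long$subject_id %in% raw_subj$subject_id, ,
                       drop = FALSE]

  # (c) listwise deletion on missing education
  if (isTRUE(rules$drop_missing_education)) {
    noedu <- is.na(raw_subj$education)
    report$missing_education_subjects_removed <- sum(noedu)
    report$missing_education_rows_removed <-
      sum(raw_long$subject_id %in% raw_subj$subject_id[noedu] &
            raw_long$observed)
    raw_subj <- raw_subj[!noedu, , drop = FALSE]
    raw_long <- raw_long[raw_long$subject_id %in% raw_subj$subject_id, ,
                         drop = FALSE]
  }

  # event indicator and event/censoring age
  demented <- !is.na(raw_subj$onset_age)
  cens <- pmin(ifelse(is.na(raw_subj$death_age), Inf, raw_subj$death_age),
               ifelse(is.na(raw_subj$last_eval_age), Inf,
                      raw_subj$last_eval_age))
  obs_rows <- raw_long[raw_long$observed, , drop = FALSE]
  lo <- tapply(obs_rows$age, obs_rows$subject_id, max)
  last_obs <- as.numeric(lo[as.character(raw_subj$subject_id)])
  no_followup <- !demented & !is.finite(cens)
  report$censored_at_last_assessment <- sum(no_followup)
  cens[no_followup] <- last_obs[no_followup] + rules$censor_offset
  raw_subj$event <- demented
  raw_subj$event_age <- ifelse(demented, raw_subj$onset_age, cens)
  if (any(is.na(raw_subj$event_age)))
    stop("could not determine an event/censoring age for subject(s) ",
         paste(raw_subj$subject_id[is.na(raw_subj$event_age)], collapse = ", "))

  keep_obs <- raw_subj$subject_id %in% obs_rows$subject_id
  report$subjects_without_observations_removed <- sum(!keep_obs)
  raw_subj <- raw_subj[keep_obs, , drop = FALSE]
  raw_long <- raw_long[raw_long$subject_id %in% raw_subj$subject_id, ,
                       drop = FALSE]

  ds <- analysis_dataset(raw_long, raw_subj, cohort_ref = rules$cohort_ref)
  report$subjects_retained <- nrow(ds$subjects)
  report$observed_measurements_retained <- sum(ds$longitudinal$observed)
  attr(ds, "preparation_report") <- report
  ds
}

#' Dropout-pattern scheme
#'
#' Configuration for [assign_patterns()]. Cohorts scheduled for at least
#' `long_min_waves` waves are "long" cohorts; the rest are "short".
#'
#' @param long_min_waves minimum number of scheduled waves for a cohort to
#'   count as long (default 5).
#' @param long_cohorts optional explicit character vector of long cohort
#'   labels, overriding the wave-count rule.
#' @param few_obs_max dropouts with at most this many observed waves form the
#'   pooled short-stay pattern `"2"` (default 2).
#' @return a list of class `jmsens_pattern_scheme`.
#' @export
pattern_scheme <- function(long_min_waves = 5L, long_cohorts = NULL,
                           few_obs_max = 2L) {
  structure(list(long_min_waves = long_min_waves,
                 long_cohorts = long_cohorts, few_obs_max = few_obs_max),
            class = "jmsens_pattern_scheme")
}

#' Assign dropout patterns
#'
#' Labels every subject with one of six missing-data patterns defined by
#' cohort design and length of stay: completers of long cohorts are `"0.a"`,
#' completers of short cohorts `"0.b"`, long-cohort dropouts whose last
#' observed scheduled wave is j in \{3, 4, 5\} get pattern `"j"`, and any
#' dropout with one or two observed waves gets the pooled pattern `"2"`
#' (single-observation subjects are deliberately kept in `"2"` so the random
#' intercept/slope structure stays identifiable there).
#'
#' A subject counts as a completer when every scheduled wave they were at
#' risk for (scheduled age before their event, death, or end of follow-up)
#' was observed; waves cut short by dementia or death are not counted as
#' dropout.
#'
#' @param dataset a `jmsens_data` object.
#' @param scheme a [pattern_scheme()].
#' @return the dataset with `dropout$pattern` filled in.
#' @export
assign_patterns <- function(dataset, scheme = pattern_scheme()) {
  stopifnot(inherits(dataset, "jmsens_data"))
  subj <- dataset$subjects
  drop <- dataset$dropout
  if (any(drop$n_observed < 1L))
    stop("every subject needs at least one observed assessment")
  n_sched <- vapply(subj$scheduled_ages, length, integer(1))
  long_cohort <- if (is.null(scheme$long_cohorts)) {
    n_sched >= scheme$long_min_waves
  } else subj$cohort_label %in% scheme$long_cohorts

  horizon <- pmin(ifelse(subj$event, subj$event_age, Inf),
                  ifelse(is.na(subj$death_age), Inf, subj$death_age))
  obs <- dataset$longitudinal[dataset$longitudinal$observed, , drop = FALSE]
  waves_by_subj <- split(obs$wave, factor(obs$subject_id,
                                          levels = subj$subject_id))
  pat <- character(nrow(subj))
  for (i in seq_len(nrow(subj))) {
    sched <- subj$scheduled_ages[[i]]
    at_risk <- which(sched < horizon[i] - 1e-9)
    obs_waves <- waves_by_subj[[i]]
    completer <- length(at_risk) == 0L || all(at_risk %in% obs_waves)
    if (completer) {
      pat[i] <- if (long_cohort[i]) "0.a" else "0.b"
    } else if (drop$n_observed[i] <= scheme$few_obs_max) {
      pat[i] <- "2"
    } else if (long_cohort[i] &&
               drop$last_obs_index[i] %in% c(3L, 4L, 5L)) {
      pat[i] <- as.character(drop$last_obs_index[i])
    } else {
      stop("pattern scheme is not exhaustive: no rule matches subject ",
           subj$subject_id[i], " (cohort ", subj$cohort_label[i],
           ", ", drop$n_observed[i], " observed waves, last index ",
           drop$last_obs_index[i], ")")
    }
  }
  dataset$dropout$pattern <- pat
  dataset
}

#' @export
print.jmsens_data <- function(x, ...) {
  cat("Joint longitudinal/survival dataset\n")
  cat("  subjects:             ", nrow(x$subjects), "\n")
  cat("  assessments observed: ", sum(x$longitudinal$observed),
      " (of ", nrow(x$longitudinal), " rows)\n", sep = "")
  cat("  events:               ", sum(x$subjects$event), "\n")
  cat("  centering age t-bar:  ", round(x$t_center, 2), " years\n", sep = "")
  if (!all(is.na(x$dropout$pattern))) {
    cat("  patterns:\n")
    print(table(x$dropout$pattern))
  }
  invisible(x)
}

#' Read the two delimited input tables
#'
#' @param long_path path to the long-format assessment CSV.
#' @param subj_path path to the subject-level CSV (with `scheduled_ages` as a
#'   `";"`-separated string).
#' @return a list with data frames `longitudinal` and `subjects`.
#' @export
read_jm_tables <- function(long_path, subj_path) {
  lng <- utils::read.csv(long_path, stringsAsFactors = FALSE)
  lng$is_first <- as.logical(lng$is_first)
  lng$observed <- as.logical(lng$observed)
  sbj <- utils::read.csv(subj_path, stringsAsFactors = FALSE)
  sbj$scheduled_ages <- parse_age_list(sbj$scheduled_ages)
  if (!is.null(sbj$event)) sbj$event <- as.logical(sbj$event)
  list(longitudinal = lng, subjects = sbj)
}

#' Write a dataset back to the delimited dialect
#'
#' Writes `<stem>_long.csv`, `<stem>_subjects.csv` and, when present, the
#' preparation report as `<stem>_report.json`.
#'
#' @param dataset a `jmsens_data` object.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
write_jm_tables <- function(dataset, dir, stem = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- file.path(dir, paste0(stem, "_long.csv"))
  sp <- file.path(dir, paste0(stem, "_subjects.csv"))
  sbj <- dataset$subjects
  sbj$scheduled_ages <- format_age_list(sbj$scheduled_ages)
  utils::write.csv(dataset$longitudinal, lp, row.names = FALSE, na = "")
  utils::write.csv(sbj, sp, row.names = FALSE, na = "")
  paths <- c(lp, sp)
  rep <- attr(dataset, "preparation_report")
  if (!is.null(rep)) {
    rp <- file.path(dir, paste0(stem, "_report.json"))
    jsonlite::write_json(rep, rp, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, rp)
  }
  invisible(paths)
}
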