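# Model frame: all design matrices and quadrature layouts precomputed once
# per (dataset, spec), so likelihood evaluations inside MCMC are a handful of
# matrix-vector products.

resolve_spec <- function(dataset, spec) {
  obs_ages <- dataset$longitudinal$age[dataset$longitudinal$observed]
  if (is.null(spec$long_basis))
    spec$long_basis <- natural_cubic_basis(df = spec$long_df, x = obs_ages)
  if (is.null(spec$baseline_basis)) {
    # support must cover every quadrature node: [min entry, max event age]
    lo <- min(dataset$subjects$entry_age)
    hi <- max(dataset$subjects$event_age)
    spec$baseline_basis <- bspline_basis(df = spec$baseline_df,
                                         boundary = c(lo, hi),
                                         x = dataset$subjects$event_age)
  }
  if (spec$pattern_deviations) {
    pats <- sort(unique(dataset$dropout$pattern))
    if (anyNA(dataset$dropout$pattern))
      stop("imputation model requires assigned patterns; run assign_patterns()")
    empty <- setdiff(c(spec$reference_pattern), pats)
    if (length(empty))
      stop("pattern with zero subjects: ", paste(empty, collapse = ", "))
    spec$pattern_levels <- pats
    if (is.null(spec$pattern_basis) && spec$pattern_df > 0L)
      spec$pattern_basis <- natural_cubic_basis(df = spec$pattern_df,
                                                x = obs_ages)
  }
  spec
}

beta_names <- function(spec) {
  nm <- c("(Intercept)", paste0("ns", seq_len(spec$long_basis$df)))
  nm <- c(nm, spec$covariates)
  if (spec$pattern_deviations) {
    for (d in setdiff(spec$pattern_levels, spec$reference_pattern)) {
      nm <- c(nm, paste0("dev_", d, "_0"))
      if (spec$pattern_df > 0L)
        nm <- c(nm, paste0("dev_", d, "_ns", seq_len(spec$pattern_basis$df)))
    }
  }
  nm
}

# Fixed-effect design rows at given ages. `first` is the first-assessment
# indicator at those ages; `pattern` a character vector (or NULL).
beta_design <- function(spec, ages, male, edu, cohort, first, pattern = NULL,
                        deriv = 0L) {
  n <- length(ages)
  male <- rep_len(male, n); edu <- rep_len(edu, n)
  cohort <- rep_len(cohort, n); first <- rep_len(as.numeric(first), n)
  fb <- evaluate_basis(spec$long_basis, ages, deriv)
  if (deriv == 0L) {
    cov_cols <- cbind(male = male, education = edu, first = first,
                      first_age = first * ages, cohort = cohort)
    X <- cbind(1, fb, cov_cols[, spec$covariates, drop = FALSE])
  } else {
    cov_cols <- cbind(male = 0 * male, education = 0 * edu, first = 0 * first,
                      first_age = first, cohort = 0 * cohort)
    X <- cbind(0, fb, cov_cols[, spec$covariates, drop = FALSE])
  }
  if (spec$pattern_deviations) {
    stopifnot(!is.null(pattern))
    pattern <- rep_len(pattern, n)
    db <- if (spec$pattern_df > 0L)
      evaluate_basis(spec$pattern_basis, ages, deriv) else NULL
    for (d in setdiff(spec$pattern_levels, spec$reference_pattern)) {
      ind <- as.numeric(pattern == d)
      Xd <- cbind(if (deriv == 0L) ind else 0 * ind,
                  if (!is.null(db)) ind * db)
      X <- cbind(X, Xd)
    }
  }
  colnames(X) <- beta_names(spec)
  X
}

build_frame <- function(dataset, spec) {
  spec <- resolve_spec(dataset, spec)
  subj <- dataset$subjects
  N <- nrow(subj)
  tc <- dataset$t_center
  male <- as.numeric(subj$sex == "male")
  edu <- subj$education
  cohort <- subj$birth_year - dataset$cohort_ref
  pattern <- if (spec$pattern_deviations) dataset$dropout$pattern else NULL

  obs <- dataset$longitudinal[dataset$longitudinal$observed, , drop = FALSE]
  id <- match(obs$subject_id, subj$subject_id)
  X <- beta_design(spec, obs$age, male[id], edu[id], cohort[id],
                   obs$is_first, if (is.null(pattern)) NULL else pattern[id])
  z <- obs$age - tc

  Wnames <- spec$surv_covariates
  W <- cbind(male = male, education = edu)[, Wnames, drop = FALSE]

  # quadrature layout on [entry_i, T_i]
  gl <- gl_rule(spec$n_quad)
  a <- subj$entry_age; Tt <- subj$event_age
  half <- (Tt - a) / 2; mid <- (Tt + a) / 2
  keep <- which(half > 1e-10)
  idq <- rep(keep, each = spec$n_quad)
  tq <- rep(mid[keep], each = spec$n_quad) +
    rep(half[keep], each = spec$n_quad) * rep(gl$x, times = length(keep))
  wq <- rep(half[keep], each = spec$n_quad) * rep(gl$w, times = length(keep))

  lag_des <- function(ages, ids) {
    la <- ages - spec$lag
    list(
      X  = beta_design(spec, la, male[ids], edu[ids], cohort[ids], 0,
                       if (is.null(pattern)) NULL else pattern[ids], 0L),
      Xd = beta_design(spec, la, male[ids], edu[ids], cohort[ids], 0,
                       if (is.null(pattern)) NULL else pattern[ids], 1L),
      z  = la - tc)
  }
  lq <- lag_des(tq, idq)
  lT <- lag_des(Tt, seq_len(N))
  Bq <- evaluate_basis(spec$baseline_basis, tq, 0L)
  BT <- evaluate_basis(spec$baseline_basis, Tt, 0L)

  list(spec = spec, t_center = tc, N = N,
       y = obs$score, id = id, X = X, z = z,
       nobs_i = tabulate(id, N),
       male = male, edu = edu, cohort = cohort, pattern = pattern,
       entry = a, Tev = Tt, delta = as.numeric(subj$event), W = W,
       XtX = crossprod(X),
       idq = idq, tq = tq, wq = wq,
       Xq = lq$X, Xqd = lq$Xd, zq = lq$z, Bq = Bq,
       XT = lT$X, XTd = lT$Xd, zT = lT$z, BT = BT,
       beta_names = beta_names(spec))
}

# --- likelihood pieces ------------------------------------------------------

rowsum_full <- function(x, id, N) {
  out <- numeric(N)
  rs <- rowsum(x, id)
  out[as.integer(rownames(rs))] <- rs
  out
}

# trajectory value/derivative at quadrature nodes and event times
surv_traj <- function(fr, beta, b) {
  list(mq  = drop(fr$Xq %*% beta) + b[fr$idq, 1L] + b[fr$idq, 2L] * fr$zq,
       mdq = drop(fr$Xqd %*% beta) + b[fr$idq, 2L],
       mT  = drop(fr$XT %*% beta) + b[, 1L] + b[, 2L] * fr$zT,
       mdT = drop(fr$XTd %*% beta) + b[, 2L])
}

surv_loglik <- function(fr, traj, bthq, bthT, wgam, alpha) {
  loghq <- bthq + wgam[fr$idq] + alpha[1] * traj$mq + alpha[2] * traj$mdq
  cum <- rowsum_full(fr$wq * exp(loghq), fr$idq, fr$N)
  loghT <- bthT + wgam + alpha[1] * traj$mT + alpha[2] * traj$mdT
  list(ll = fr$delta * loghT - cum, cum = cum, loghT = loghT)
}

long_loglik <- function(fr, res, sigma2) {
  rss_i <- rowsum_full(res^2, fr$id, fr$N)
  -0.5 * fr$nobs_i * log(2 * pi * sigma2) - rss_i / (2 * sigma2)
}

re_loglik <- function(b, D) {
  ldet <- log(D[1, 1] * D[2, 2] - D[1, 2]^2)
  Dinv <- solve(D)
  q <- b[, 1]^2 * Dinv[1, 1] + 2 * b[, 1] * b[, 2] * Dinv[1, 2] +
    b[, 2]^2 * Dinv[2, 2]
  -log(2 * pi) - 0.5 * ldet - 0.5 * q
}

ld_half_t <- function(x, df, scale) {
  stats::dt(x / scale, df, log = TRUE) - log(scale) + log(2)
}

# pars: list(beta, gamma, alpha, log_sigma, log_sd1, log_sd2, zrho, theta)
pars_prior <- function(pars, pr) {
  sigma <- exp(pars$log_sigma)
  sd1 <- exp(pars$log_sd1); sd2 <- exp(pars$log_sd2)
  rho <- tanh(pars$zrho)
  sum(stats::dnorm(pars$beta, 0, pr$beta_sd, log = TRUE)) +
    sum(stats::dnorm(pars$gamma, 0, pr$gamma_sd, log = TRUE)) +
    sum(stats::dnorm(pars$alpha, 0, pr$alpha_sd, log = TRUE)) +
    ld_half_t(sigma, pr$sigma_df, pr$sigma_scale) + pars$log_sigma +
    ld_half_t(sd1, pr$re_sd_df, pr$re_sd_scale) + pars$log_sd1 +
    ld_half_t(sd2, pr$re_sd_df, pr$re_sd_scale) + pars$log_sd2 +
    log1p(-rho^2) +
    stats::dnorm(pars$theta[1], 0, pr$baseline_first_sd, log = TRUE) +
    sum(stats::dnorm(diff(pars$theta), 0, pr$baseline_rw_scale, log = TRUE))
}

pars_D <- function(pars) {
  sd1 <- exp(pars$log_sd1); sd2 <- exp(pars$log_sd2)
  rho <- tanh(pars$zrho)
  matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2, 2)
}

params_to_internal <- function(params) {
  D <- params$D
  sd1 <- sqrt(D[1, 1]); sd2 <- sqrt(D[2, 2])
  rho <- D[1, 2] / (sd1 * sd2)
  list(beta = params$beta, gamma = params$gamma, alpha = params$alpha,
       log_sigma = log(sqrt(params$sigma2)),
       log_sd1 = log(sd1), log_sd2 = log(sd2),
       zrho = atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12)),
       theta = params$baseline_coefs)
}

internal_to_params <- function(pars, b = NULL) {
  jm_parameters(beta = pars$beta, gamma = pars$gamma, alpha = pars$alpha,
                sigma2 = exp(2 * pars$log_sigma), D = pars_D(pars),
                baseline_coefs = pars$theta, random_effects = b)
}

frame_components <- function(fr, pars, b) {
  beta <- pars$beta
  sigma2 <- exp(2 * pars$log_sigma)
  res <- fr$y - drop(fr$X %*% beta) - b[fr$id, 1L] - b[fr$id, 2L] * fr$z
  traj <- surv_traj(fr, beta, b)
  bthq <- drop(fr$Bq %*% pars$theta)
  bthT <- drop(fr$BT %*% pars$theta)
  wgam <- drop(fr$W %*% pars$gamma)
  sv <- surv_loglik(fr, traj, bthq, bthT, wgam, pars$alpha)
  list(ll_long = long_loglik(fr, res, sigma2),
       ll_surv = sv$ll,
       ll_re = re_loglik(b, pars_D(pars)),
       res = res, traj = traj, bthq = bthq, bthT = bthT, wgam = wgam,
       cum = sv$cum, loghT = sv$loghT)
}

#' Log posterior density of the joint model
#'
#' Sums, over subjects, the Gaussian longitudinal log likelihood of the
#' observed scores, the survival log likelihood
#' \eqn{\delta_i \log h_i(T_i) - \int_{a_i}^{T_i} h_i(s) ds} (delayed entry
#' at the enrollment age, integral by Gauss--Legendre quadrature), the
#' random-effects normal log density, and the log priors.
#'
#' @param dataset a `jmsens_data` object.
#' @param params a [jm_parameters()] object including `random_effects`.
#' @param spec a [joint_model_spec()] (bases are resolved from the data if
#'   unset).
#' @param priors a [prior_config()].
#' @return the scalar log posterior (unnormalized).
#' @export
log_posterior <- function(dataset, params, spec = joint_model_spec(),
                          priors = prior_config()) {
  fr <- build_frame(dataset, spec)
  b <- params$random_effects
  if (is.null(b)) stop("params must include random_effects")
  pars <- params_to_internal(params)
  comp <- frame_components(fr, pars, b)
  ll_i <- comp$ll_long + comp$ll_surv + comp$ll_re
  if (any(!is.finite(ll_i)))
    stop("non-finite log posterior for subject(s) ",
         paste(dataset$subjects$subject_id[!is.finite(ll_i)], collapse = ", "))
  sum(ll_i) + pars_prior(pars, priors)
}

#' Subject-specific longitudinal mean (or its slope)
#'
#' Evaluates \eqn{m_i(t)} (or \eqn{m_i'(t)}) for given parameters. In the
#' derivative, only the first-assessment-by-age interaction contributes a
#' fixed-covariate time derivative, and only while `first = TRUE`.
#'
#' @param subject one-row data frame (or list) with `sex`, `education`,
#'   `birth_year`.
#' @param t ages (years) at which to evaluate.
#' @param params a [jm_parameters()]; `random_effects` may be a length-2
#'   vector `(b0, b1)` for this subject.
#' @param spec a `jm_spec` with resolved bases.
#' @param t_center centering age \eqn{\bar t}.
#' @param derivative 0 for the value, 1 for the slope.
#' @param first logical (recycled): is the assessment at `t` the subject's
#'   first-ever assessment?
#' @param pattern pattern label, required for imputation-model specs.
#' @param cohort_ref reference birth year.
#' @return numeric vector, score points (or points/year).
#' @export
longitudinal_mean <- function(subject, t, params, spec, t_center,
                              derivative = 0L, first = FALSE,
                              pattern = NULL, cohort_ref = 1937) {
  b <- params$random_effects
  if (is.null(b)) b <- c(0, 0)
  b <- as.numeric(b)
  male <- as.numeric(subject$sex == "male")
  X <- beta_design(spec, t, male, subject$education,
                   subject$birth_year - cohort_ref, first, pattern,
                   as.integer(derivative))
  if (derivative == 0L) drop(X %*% params$beta) + b[1] + b[2] * (t - t_center)
  else drop(X %*% params$beta) + b[2]
}
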