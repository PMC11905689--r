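#' Specify the substantive joint model
#'
#' Defines the longitudinal mixed-effects submodel
#' \deqn{y_i(t) = m_i(t) + \epsilon_i(t), \quad
#'       m_i(t) = f(t) + x_i(t)^\top\beta + b_{0i} + b_{1i}(t - \bar t)}
#' and the proportional-hazards submodel
#' \deqn{h_i(t) = h_0(t)\exp\{\gamma^\top w_i + \alpha_1 m_i(t - L) +
#'       \alpha_2 m_i'(t - L)\}}
#' with delayed entry at the enrollment age. The smooth age trend \eqn{f} is
#' a natural cubic spline; the log baseline hazard \eqn{\log h_0} is a cubic
#' B-spline. Fixed covariates are sex (male indicator), education years, a
#' first-assessment indicator (practice effect), its interaction with age,
#' and birth cohort (birth year minus a reference year); the hazard
#' covariates \eqn{w_i} are sex and education. The association acts on the
#' trajectory lagged by `lag` years; inside the hazard the first-assessment
#' indicator is set to 0, so the hazard tracks post-practice memory.
#'
#' @param long_basis natural cubic [natural_cubic_basis()] for \eqn{f};
#'   `NULL` to place knots from the observed assessment ages at fit time
#'   (boundary at the 0.5%/99.5% age quantiles, interior at equally spaced
#'   quantiles).
#' @param long_df degrees of freedom of \eqn{f} when `long_basis` is `NULL`.
#' @param baseline_basis B-spline basis for \eqn{\log h_0}; `NULL` to build
#'   one from the event/censoring ages at fit time.
#' @param baseline_df number of B-spline basis functions when
#'   `baseline_basis` is `NULL`.
#' @param lag association lag \eqn{L} in years (default 5).
#' @param covariates fixed-effect covariates, a subset of
#'   `c("male", "education", "first", "first_age", "cohort")`.
#' @param surv_covariates hazard covariates, subset of
#'   `c("male", "education")`.
#' @param n_quad Gauss--Legendre nodes per survival integral (default 15).
#' @return an object of class `jm_spec`.
#' @export
joint_model_spec <- function(long_basis = NULL, long_df = 3L,
                             baseline_basis = NULL, baseline_df = 9L,
                             lag = 5,
                             covariates = c("male", "education", "first",
                                            "first_age", "cohort"),
                             surv_covariates = c("male", "education"),
                             n_quad = 15L) {
  stopifnot(lag >= 0)
  covariates <- match.arg(covariates,
                          c("male", "education", "first", "first_age",
                            "cohort"), several.ok = TRUE)
  surv_covariates <- match.arg(surv_covariates, c("male", "education"),
                               several.ok = TRUE)
  structure(list(long_basis = long_basis, long_df = as.integer(long_df),
                 baseline_basis = baseline_basis,
                 baseline_df = as.integer(baseline_df),
                 lag = lag, covariates = covariates,
                 surv_covariates = surv_covariates,
                 n_quad = as.integer(n_quad),
                 pattern_deviations = FALSE,
                 reference_pattern = NULL, pattern_basis = NULL,
                 pattern_df = NULL),
            class = "jm_spec")
}

#' Specify the pattern-mixture imputation model
#'
#' Extends a substantive [joint_model_spec()] with pattern-specific smooth
#' deviations: the longitudinal mean becomes
#' \deqn{m_i(t) = f_{ref}(t) + \sum_{d \ne ref} I(d_i = d) f_d(t) +
#'       x_i(t)^\top\beta + b_{0i} + b_{1i}(t - \bar t)}
#' where each deviation \eqn{f_d} is an intercept plus a natural cubic
#' spline. The survival submodel is retained unchanged so imputations are
#' informed by both the longitudinal and the event data. The sensitivity
#' offset \eqn{\Delta (t - t_{iF_i})_+} is zero on observed data and is added
#' only at imputation time (see [impute_missing()]).
#'
#' @param base a substantive `jm_spec`.
#' @param reference_pattern the pattern whose smooth is the reference
#'   (default `"0.a"`).
#' @param pattern_df df of the spline part of each deviation (0 gives
#'   intercept-only deviations).
#' @param pattern_basis optional explicit [natural_cubic_basis()] shared by
#'   the deviations.
#' @return a `jm_spec` with `pattern_deviations = TRUE`.
#' @export
imputation_model_spec <- function(base = joint_model_spec(),
                                  reference_pattern = "0.a",
                                  pattern_df = 3L, pattern_basis = NULL) {
  spec <- base
  spec$pattern_deviations <- TRUE
  spec$reference_pattern <- reference_pattern
  spec$pattern_df <- as.integer(pattern_df)
  spec$pattern_basis <- pattern_basis
  spec
}

#' Prior configuration
#'
#' Independent normal priors on the regression coefficients and association
#' weights; half-t priors on the residual SD and the random-effect SDs with
#' a uniform prior on the random-effect correlation; a first-difference
#' (random-walk) normal prior on the log-baseline-hazard coefficients.
#'
#' @param beta_sd,gamma_sd,alpha_sd normal prior SDs.
#' @param sigma_scale,sigma_df half-t scale/df for the residual SD
#'   (score points).
#' @param re_sd_scale,re_sd_df half-t scale/df for the random-effect SDs.
#' @param baseline_first_sd normal prior SD on the first baseline
#'   coefficient.
#' @param baseline_rw_scale SD of successive differences of baseline
#'   coefficients (the smoothness scale of \eqn{\log h_0}).
#' @return a list of class `jm_priors`.
#' @export
prior_config <- function(beta_sd = 100, gamma_sd = 10, alpha_sd = 10,
                         sigma_scale = 10, sigma_df = 3,
                         re_sd_scale = 10, re_sd_df = 3,
                         baseline_first_sd = 10, baseline_rw_scale = 2) {
  structure(list(beta_sd = beta_sd, gamma_sd = gamma_sd, alpha_sd = alpha_sd,
                 sigma_scale = sigma_scale, sigma_df = sigma_df,
                 re_sd_scale = re_sd_scale, re_sd_df = re_sd_df,
                 baseline_first_sd = baseline_first_sd,
                 baseline_rw_scale = baseline_rw_scale),
            class = "jm_priors")
}

#' MCMC settings
#'
#' @param chains number of chains.
#' @param warmup adaptation iterations (discarded).
#' @param iterations post-warmup iterations per chain.
#' @param thin keep every `thin`-th post-warmup draw; must divide
#'   `iterations`.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param priors a [prior_config()].
#' @param target_accept proposal-adaptation target acceptance rate.
#' @return a list of class `jm_mcmc`.
#' @export
mcmc_control <- function(chains = 2L, warmup = 1000L, iterations = 2000L,
                         thin = 1L, seed = 1L, priors = prior_config(),
                         target_accept = 0.45) {
  stopifnot(chains >= 1L, warmup >= 1L, iterations >= 1L, thin >= 1L)
  if (iterations %% thin != 0L) stop("thin must divide iterations")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 seed = as.integer(seed), priors = priors,
                 target_accept = target_accept),
            class = "jm_mcmc")
}

#' Joint-model parameter set
#'
#' Container for one full parameter configuration: regression coefficients
#' `beta` (intercept, spline coefficients of the age trend, covariates, and
#' pattern-deviation coefficients for imputation models), hazard coefficients
#' `gamma`, association weights `alpha = c(value, slope)`, residual variance
#' `sigma2`, random-effect covariance `D` (2x2 SPD), log-baseline-hazard
#' coefficients, and optionally the per-subject random effects (N x 2).
#'
#' @param beta,gamma,alpha,baseline_coefs numeric vectors.
#' @param sigma2 residual variance (> 0), score points squared.
#' @param D 2x2 symmetric positive-definite matrix.
#' @param random_effects optional N x 2 matrix of `(b0, b1)`.
#' @return an object of class `jm_parameters`.
#' @export
jm_parameters <- function(beta, gamma, alpha, sigma2, D, baseline_coefs,
                          random_effects = NULL) {
  stopifnot(length(alpha) == 2L, sigma2 > 0)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D))) || any(eigen(D, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0))
    stop("D must be symmetric positive definite")
  structure(list(beta = beta, gamma = gamma, alpha = as.numeric(alpha),
                 sigma2 = sigma2, D = D,
                 baseline_coefs = as.numeric(baseline_coefs),
                 random_effects = random_effects),
            class = "jm_parameters")
}
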