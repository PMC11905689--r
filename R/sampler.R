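# Adaptive Metropolis-within-Gibbs sampler for the joint model.
#
# Fixed parameters are updated in four blocks (regression coefficients;
# hazard covariates + association weights; baseline-hazard coefficients;
# variance parameters) with multivariate normal random-walk proposals whose
# scale and covariance adapt during warmup (Robbins-Monro on the log step
# size towards the target acceptance rate, empirical covariance of the
# history). Random effects are updated jointly across subjects with
# per-subject acceptance, which is valid because subjects are conditionally
# independent given the fixed parameters. Adaptation is frozen after warmup
# so the post-warmup draws form a fixed-kernel Markov chain.

init_state <- function(fr, priors) {
  XtX <- crossprod(fr$X) + diag(1e-6, ncol(fr$X))
  beta <- drop(solve(XtX, crossprod(fr$X, fr$y)))
  res <- fr$y - drop(fr$X %*% beta)
  sigma <- max(stats::sd(res), 0.5)
  py <- sum(fr$Tev - fr$entry)
  rate <- max(sum(fr$delta), 0.5) / py
  pars <- list(beta = beta, gamma = rep(0, ncol(fr$W)), alpha = c(0, 0),
               log_sigma = log(sigma), log_sd1 = log(max(sigma, 1)),
               log_sd2 = log(0.2), zrho = 0,
               theta = rep(log(rate), fr$spec$baseline_basis$df))
  b <- matrix(0, fr$N, 2)
  # rough empirical intercepts speed up burn-in
  resid_mean <- rowsum_full(res, fr$id, fr$N) / pmax(fr$nobs_i, 1L)
  b[, 1] <- resid_mean * 0.8
  list(pars = pars, b = b, beta_cov0 = solve(XtX) * sigma^2)
}

new_block <- function(d, cov0 = NULL) {
  list(d = d, lam = 0, mu = rep(0, d),
       cov = if (is.null(cov0)) diag(d) * 0.01 else cov0,
       emp = matrix(0, d, d), n = 0, acc = 0, try = 0)
}

propose_block <- function(blk, x) {
  S <- blk$cov * exp(2 * blk$lam) * 2.38^2 / blk$d
  ch <- tryCatch(chol(S + diag(1e-10, blk$d)), error = function(e) NULL)
  if (is.null(ch)) ch <- diag(sqrt(diag(S)) + 1e-6, blk$d)
  x + drop(stats::rnorm(blk$d) %*% ch)
}

adapt_block <- function(blk, x, accp, it) {
  g <- 1 / (5 + it)^0.6
  blk$lam <- blk$lam + g * (accp - blk$target)
  dx <- x - blk$mu
  blk$mu <- blk$mu + g * dx
  blk$emp <- blk$emp + g * (tcrossprod(dx) - blk$emp)
  blk$n <- blk$n + 1
  if (blk$n > 50) blk$cov <- blk$emp + diag(1e-8, blk$d)
  blk
}

mcmc_chain <- function(fr, control, chain_id) {
  set.seed(control$seed + chain_id - 1L)
  pr <- control$priors
  st <- init_state(fr, pr)
  pars <- st$pars; b <- st$b
  comp <- frame_components(fr, pars, b)
  lp_prior <- pars_prior(pars, pr)
  target <- control$target_accept

  blocks <- list(
    beta = new_block(length(pars$beta), st$beta_cov0 + diag(1e-4,
                                                            length(pars$beta))),
    surv = new_block(length(pars$gamma) + 2L,
                     diag(c(rep(0.05, length(pars$gamma)), 0.02, 0.5)^2)),
    theta = new_block(length(pars$theta), diag(0.2^2, length(pars$theta))),
    var = new_block(4L, diag(0.05^2, 4L)))
  for (nm in names(blocks)) blocks[[nm]]$target <- target
  lam_re <- rep(0, fr$N)
  acc_re <- 0; try_re <- 0

  # translation moves: shift an intercept-like fixed effect and compensate
  # through the random effects, leaving the likelihood exactly invariant
  # (these directions are near-unidentified marginally and mix poorly under
  # componentwise updates). Move types: global intercept vs b0; raw-age
  # coefficient vs b1 (with an intercept correction via t-bar); each
  # pattern-deviation intercept vs that pattern's b0.
  trans <- list(list(col = match("(Intercept)", fr$beta_names),
                     subj = seq_len(fr$N), type = "b0", lam = 0))
  if ("ns1" %in% fr$beta_names)
    trans <- c(trans, list(list(col = match("ns1", fr$beta_names),
                                subj = seq_len(fr$N), type = "b1",
                                lam = -3)))
  for (cn in grep("^dev_.*_0$", fr$beta_names, value = TRUE)) {
    d <- sub("^dev_(.*)_0$", "\\1", cn)
    trans <- c(trans, list(list(col = match(cn, fr$beta_names),
                                subj = which(fr$pattern == d), type = "b0",
                                lam = 0)))
  }

  n_iter <- control$warmup + control$iterations
  keep_every <- control$thin
  n_keep <- control$iterations %/% keep_every
  p_fix <- length(unlist(pars[c("beta", "gamma", "alpha")])) + 4L +
    length(pars$theta)
  draws <- matrix(NA_real_, n_keep, p_fix)
  re_draws <- array(NA_real_, c(n_keep, fr$N, 2L))
  k <- 0L

  sum3 <- function(c1) sum(c1$ll_long) + sum(c1$ll_surv) + sum(c1$ll_re)
  ll_cur <- sum3(comp)

  for (it in seq_len(n_iter)) {
    warm <- it <= control$warmup

    ## block 1: beta -------------------------------------------------------
    # independence Metropolis from the exact Gaussian conditional given the
    # longitudinal data and prior; the acceptance ratio reduces to the
    # survival likelihood ratio, so this is near-Gibbs whenever the hazard
    # carries little extra information about beta
    sigma2 <- exp(2 * pars$log_sigma)
    rvec <- fr$y - b[fr$id, 1L] - b[fr$id, 2L] * fr$z
    prec <- fr$XtX / sigma2 + diag(1 / pr$beta_sd^2, length(pars$beta))
    ch <- chol(prec)
    mu_b <- backsolve(ch, forwardsolve(t(ch), crossprod(fr$X, rvec) / sigma2))
    bprop <- drop(mu_b + backsolve(ch, stats::rnorm(length(pars$beta))))
    pars2 <- pars; pars2$beta <- bprop
    comp2 <- frame_components(fr, pars2, b)
    d <- sum(comp2$ll_surv) - sum(comp$ll_surv)
    accp <- if (is.na(d)) 0 else min(1, exp(d))
    if (stats::runif(1) < accp) {
      pars <- pars2; comp <- comp2
      lp_prior <- pars_prior(pars, pr); ll_cur <- sum3(comp)
      blocks$beta$acc <- blocks$beta$acc + !warm
    }
    blocks$beta$try <- blocks$beta$try + !warm

    ## block 2: gamma + alpha (trajectory unchanged) -----------------------
    ga <- c(pars$gamma, pars$alpha)
    ga2 <- propose_block(blocks$surv, ga)
    ng <- length(pars$gamma)
    gamma2 <- ga2[seq_len(ng)]; alpha2 <- ga2[ng + 1:2]
    wgam2 <- drop(fr$W %*% gamma2)
    sv2 <- surv_loglik(fr, comp$traj, comp$bthq, comp$bthT, wgam2, alpha2)
    dpr <- sum(stats::dnorm(ga2, 0, c(rep(pr$gamma_sd, ng),
                                      rep(pr$alpha_sd, 2)), log = TRUE)) -
      sum(stats::dnorm(ga, 0, c(rep(pr$gamma_sd, ng),
                                rep(pr$alpha_sd, 2)), log = TRUE))
    d <- sum(sv2$ll) - sum(comp$ll_surv) + dpr
    accp <- if (is.na(d)) 0 else min(1, exp(d))
    if (stats::runif(1) < accp) {
      pars$gamma <- gamma2; pars$alpha <- alpha2
      comp$wgam <- wgam2; comp$ll_surv <- sv2$ll
      comp$cum <- sv2$cum; comp$loghT <- sv2$loghT
      lp_prior <- lp_prior + dpr; ll_cur <- sum3(comp)
      blocks$surv$acc <- blocks$surv$acc + !warm
    }
    blocks$surv$try <- blocks$surv$try + !warm
    if (warm) blocks$surv <- adapt_block(blocks$surv,
                                         c(pars$gamma, pars$alpha), accp, it)

    ## block 3: baseline coefficients --------------------------------------
    th2 <- propose_block(blocks$theta, pars$theta)
    bthq2 <- drop(fr$Bq %*% th2); bthT2 <- drop(fr$BT %*% th2)
    sv2 <- surv_loglik(fr, comp$traj, bthq2, bthT2, comp$wgam, pars$alpha)
    dpr <- stats::dnorm(th2[1], 0, pr$baseline_first_sd, log = TRUE) +
      sum(stats::dnorm(diff(th2), 0, pr$baseline_rw_scale, log = TRUE)) -
      stats::dnorm(pars$theta[1], 0, pr$baseline_first_sd, log = TRUE) -
      sum(stats::dnorm(diff(pars$theta), 0, pr$baseline_rw_scale, log = TRUE))
    d <- sum(sv2$ll) - sum(comp$ll_surv) + dpr
    accp <- if (is.na(d)) 0 else min(1, exp(d))
    if (stats::runif(1) < accp) {
      pars$theta <- th2
      comp$bthq <- bthq2; comp$bthT <- bthT2
      comp$ll_surv <- sv2$ll; comp$cum <- sv2$cum; comp$loghT <- sv2$loghT
      lp_prior <- lp_prior + dpr; ll_cur <- sum3(comp)
      blocks$theta$acc <- blocks$theta$acc + !warm
    }
    blocks$theta$try <- blocks$theta$try + !warm
    if (warm) blocks$theta <- adapt_block(blocks$theta, pars$theta, accp, it)

    ## block 4: variances (log sigma, log sds, atanh rho) ------------------
    v <- c(pars$log_sigma, pars$log_sd1, pars$log_sd2, pars$zrho)
    v2 <- propose_block(blocks$var, v)
    pars2 <- pars
    pars2$log_sigma <- v2[1]; pars2$log_sd1 <- v2[2]
    pars2$log_sd2 <- v2[3]; pars2$zrho <- v2[4]
    ll_long2 <- long_loglik(fr, comp$res, exp(2 * v2[1]))
    ll_re2 <- re_loglik(b, pars_D(pars2))
    lp2 <- pars_prior(pars2, pr)
    d <- sum(ll_long2) + sum(ll_re2) + lp2 -
      sum(comp$ll_long) - sum(comp$ll_re) - lp_prior
    accp <- if (is.na(d)) 0 else min(1, exp(d))
    if (stats::runif(1) < accp) {
      pars <- pars2
      comp$ll_long <- ll_long2; comp$ll_re <- ll_re2
      lp_prior <- lp2; ll_cur <- sum3(comp)
      blocks$var$acc <- blocks$var$acc + !warm
    }
    blocks$var$try <- blocks$var$try + !warm
    if (warm) blocks$var <- adapt_block(
      blocks$var, c(pars$log_sigma, pars$log_sd1, pars$log_sd2, pars$zrho),
      accp, it)

    ## block 5: random effects, all subjects, per-subject acceptance -------
    sds <- c(exp(pars$log_sd1), exp(pars$log_sd2))
    eps <- cbind(stats::rnorm(fr$N, 0, sds[1]),
                 stats::rnorm(fr$N, 0, sds[2])) * exp(lam_re)
    b2 <- b + eps
    sigma2 <- exp(2 * pars$log_sigma)
    res2 <- comp$res - eps[fr$id, 1L] - eps[fr$id, 2L] * fr$z
    ll_long2 <- long_loglik(fr, res2, sigma2)
    dmq <- eps[fr$idq, 1L] + eps[fr$idq, 2L] * fr$zq
    dmdq <- eps[fr$idq, 2L]
    loghq2 <- comp$bthq + comp$wgam[fr$idq] +
      pars$alpha[1] * (comp$traj$mq + dmq) +
      pars$alpha[2] * (comp$traj$mdq + dmdq)
    cum2 <- rowsum_full(fr$wq * exp(loghq2), fr$idq, fr$N)
    loghT2 <- comp$loghT + pars$alpha[1] * (eps[, 1L] + eps[, 2L] * fr$zT) +
      pars$alpha[2] * eps[, 2L]
    ll_surv2 <- fr$delta * loghT2 - cum2
    ll_re2 <- re_loglik(b2, pars_D(pars))
    d_i <- (ll_long2 + ll_surv2 + ll_re2) -
      (comp$ll_long + comp$ll_surv + comp$ll_re)
    accp_i <- pmin(1, exp(ifelse(is.na(d_i), -Inf, d_i)))
    acc <- stats::runif(fr$N) < accp_i
    if (any(acc)) {
      b[acc, ] <- b2[acc, ]
      rows_l <- acc[fr$id]; rows_q <- acc[fr$idq]
      comp$res[rows_l] <- res2[rows_l]
      comp$traj$mq[rows_q] <- comp$traj$mq[rows_q] + dmq[rows_q]
      comp$traj$mdq[rows_q] <- comp$traj$mdq[rows_q] + dmdq[rows_q]
      comp$traj$mT[acc] <- comp$traj$mT[acc] + eps[acc, 1L] +
        eps[acc, 2L] * fr$zT[acc]
      comp$traj$mdT[acc] <- comp$traj$mdT[acc] + eps[acc, 2L]
      comp$cum[acc] <- cum2[acc]; comp$loghT[acc] <- loghT2[acc]
      comp$ll_long[acc] <- ll_long2[acc]
      comp$ll_surv[acc] <- ll_surv2[acc]
      comp$ll_re[acc] <- ll_re2[acc]
      ll_cur <- sum3(comp)
    }
    if (warm) lam_re <- lam_re + (accp_i - target) / (5 + it)^0.6
    else { acc_re <- acc_re + sum(acc); try_re <- try_re + fr$N }

    ## block 6: likelihood-invariant translation moves ---------------------
    Dcur <- pars_D(pars)
    for (ti in seq_along(trans)) {
      tr <- trans[[ti]]
      dlt <- stats::rnorm(1, 0, exp(tr$lam))
      b2 <- b[tr$subj, , drop = FALSE]
      beta2 <- pars$beta
      beta2[tr$col] <- beta2[tr$col] + dlt
      if (tr$type == "b0") {
        b2[, 1L] <- b2[, 1L] - dlt
      } else {
        b2[, 2L] <- b2[, 2L] - dlt
        beta2[1L] <- beta2[1L] - dlt * fr$t_center
      }
      ll_re2 <- re_loglik(b2, Dcur)
      d <- sum(ll_re2) - sum(comp$ll_re[tr$subj]) +
        sum(stats::dnorm(beta2, 0, pr$beta_sd, log = TRUE)) -
        sum(stats::dnorm(pars$beta, 0, pr$beta_sd, log = TRUE))
      accp <- if (is.na(d)) 0 else min(1, exp(d))
      if (stats::runif(1) < accp) {
        pars$beta <- beta2
        b[tr$subj, ] <- b2
        comp$ll_re[tr$subj] <- ll_re2
        lp_prior <- pars_prior(pars, pr)
        ll_cur <- sum3(comp)
      }
      if (warm) trans[[ti]]$lam <- tr$lam + (accp - target) / (5 + it)^0.6
    }

    ## record --------------------------------------------------------------
    if (!warm && (it - control$warmup) %% keep_every == 0L) {
      k <- k + 1L
      draws[k, ] <- c(pars$beta, pars$gamma, pars$alpha,
                      exp(pars$log_sigma), exp(pars$log_sd1),
                      exp(pars$log_sd2), tanh(pars$zrho), pars$theta)
      re_draws[k, , ] <- b
    }
  }

  nm <- c(fr$beta_names,
          paste0("gamma_", colnames(fr$W)), "alpha_value", "alpha_slope",
          "sigma", "sd_b0", "sd_b1", "cor_b",
          paste0("h0_", seq_along(pars$theta)))
  colnames(draws) <- nm
  acc_rates <- c(vapply(blocks, function(bl)
    if (bl$try > 0) bl$acc / bl$try else NA_real_, numeric(1)),
    random_effects = if (try_re > 0) acc_re / try_re else NA_real_)
  list(params = draws, re = re_draws, acceptance = acc_rates)
}

#' Fit the Bayesian joint model
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler targeting
#' [log_posterior()] and returns post-warmup, thinned draws of all fixed
#' parameters and subject-level random effects. Fully reproducible: the same
#' data, spec and control give bit-identical draws.
#'
#' @param dataset a `jmsens_data` object with at least one event.
#' @param spec a [joint_model_spec()] or [imputation_model_spec()].
#' @param control a [mcmc_control()].
#' @return an object of class `jmsens_fit` with elements `chains` (one list
#'   per chain: `params` draw matrix, `re` random-effect array,
#'   `acceptance`), `param_names`, `spec` (with resolved bases), `frame`,
#'   `dataset`, `control` and `diagnostics`.
#' @export
fit_joint_model <- function(dataset, spec = joint_model_spec(),
                            control = mcmc_control()) {
  stopifnot(inherits(dataset, "jmsens_data"))
  if (sum(dataset$subjects$event) < 1L)
    stop("no events in dataset: baseline hazard is unidentifiable")
  fr <- build_frame(dataset, spec)
  chains <- lapply(seq_len(control$chains), function(cid)
    mcmc_chain(fr, control, cid))
  fit <- structure(list(chains = chains,
                        param_names = colnames(chains[[1]]$params),
                        spec = fr$spec, frame = fr, dataset = dataset,
                        control = control),
                   class = "jmsens_fit")
  fit$diagnostics <- if (control$chains > 1L) convergence_diagnostics(fit)
    else suppressWarnings(convergence_diagnostics(fit))
  bad <- vapply(chains, function(ch) any(!is.finite(ch$params)), logical(1))
  if (any(bad)) stop("sampler produced non-finite draws; check the data ",
                     "and priors (chains: ", paste(which(bad), collapse = ","),
                     ")")
  fit
}

#' Fit the pattern-mixture imputation model
#'
#' Convenience wrapper: requires assigned dropout patterns, upgrades the
#' spec with [imputation_model_spec()] if needed, and fits with
#' [fit_joint_model()]. On observed data the sensitivity offset is
#' identically zero, so no `delta` enters the fit; `delta` only matters at
#' imputation time.
#'
#' @inheritParams fit_joint_model
#' @return a `jmsens_fit`.
#' @export
fit_imputation_model <- function(dataset, spec = imputation_model_spec(),
                                 control = mcmc_control()) {
  if (anyNA(dataset$dropout$pattern))
    stop("assign_patterns() must be run before fitting the imputation model")
  if (!isTRUE(spec$pattern_deviations)) spec <- imputation_model_spec(spec)
  tab <- table(dataset$dropout$pattern)
  if (any(tab == 0L))
    stop("pattern with zero subjects: ",
         paste(names(tab)[tab == 0L], collapse = ", "))
  fit_joint_model(dataset, spec, control)
}

# stacked draw matrix across chains (optionally a subset of parameters)
draw_matrix <- function(fit, pars = NULL) {
  m <- do.call(rbind, lapply(fit$chains, `[[`, "params"))
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

n_draws_total <- function(fit) sum(vapply(fit$chains, function(ch)
  nrow(ch$params), integer(1)))

# parameters of draw j (global index across stacked chains) as jm_parameters
draw_params <- function(fit, j) {
  per <- vapply(fit$chains, function(ch) nrow(ch$params), integer(1))
  ch <- findInterval(j - 1L, cumsum(c(0L, per)), rightmost.closed = TRUE)
  jloc <- j - c(0L, cumsum(per))[ch]
  v <- fit$chains[[ch]]$params[jloc, ]
  b <- fit$chains[[ch]]$re[jloc, , ]
  nmb <- fit$frame$beta_names
  ng <- ncol(fit$frame$W)
  gamma <- v[paste0("gamma_", colnames(fit$frame$W))]
  sd1 <- v[["sd_b0"]]; sd2 <- v[["sd_b1"]]; rho <- v[["cor_b"]]
  jm_parameters(beta = v[nmb], gamma = gamma,
                alpha = c(v[["alpha_value"]], v[["alpha_slope"]]),
                sigma2 = v[["sigma"]]^2,
                D = matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2),
                           2, 2),
                baseline_coefs = v[grep("^h0_", names(v))],
                random_effects = matrix(b, ncol = 2L))
}
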