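#' Partial history of a new subject
#'
#' Covariates plus observed assessments for a subject who is event-free at
#' their last available measurement, the conditioning set for dynamic
#' prediction.
#'
#' @param sex `"male"` or `"female"`.
#' @param education years of education.
#' @param birth_year calendar birth year.
#' @param ages assessment ages (years), increasing.
#' @param scores observed scores at those ages.
#' @param first logical vector marking the first-ever assessment (default:
#'   the earliest).
#' @return an object of class `jmsens_history`; `last_seen` is the landmark
#'   age `s`.
#' @export
new_subject_history <- function(sex, education, birth_year, ages, scores,
                                first = NULL) {
  stopifnot(length(ages) == length(scores), !is.unsorted(ages))
  if (length(ages) == 0L) stop("history must contain at least one observation")
  if (is.null(first)) first <- seq_along(ages) == 1L
  structure(list(sex = sex, education = education, birth_year = birth_year,
                 ages = as.numeric(ages), scores = as.numeric(scores),
                 first = as.logical(first), last_seen = max(ages)),
            class = "jmsens_history")
}

# precomputed design pieces for one new subject, given a fitted model
history_frame <- function(fit, history) {
  spec <- fit$spec
  fr <- fit$frame
  male <- as.numeric(history$sex == "male")
  cohort <- history$birth_year - fit$dataset$cohort_ref
  pat <- if (spec$pattern_deviations) spec$reference_pattern else NULL
  entry <- min(history$ages); s <- history$last_seen
  Xo <- beta_design(spec, history$ages, male, history$education, cohort,
                    history$first, pat)
  gl <- gl_rule(spec$n_quad)
  mk_nodes <- function(a, b) {
    half <- (b - a) / 2
    tq <- (a + b) / 2 + half * gl$x
    list(t = tq, w = half * gl$w)
  }
  qd <- if (s > entry) mk_nodes(entry, s) else list(t = numeric(0),
                                                   w = numeric(0))
  lagd <- function(tq) list(
    X = beta_design(spec, tq - spec$lag, male, history$education, cohort, 0,
                    pat, 0L),
    Xd = beta_design(spec, tq - spec$lag, male, history$education, cohort, 0,
                     pat, 1L),
    z = tq - spec$lag - fr$t_center)
  list(spec = spec, male = male, cohort = cohort, edu = history$education,
       wvec = c(male = male,
                education = history$education)[spec$surv_covariates],
       entry = entry, s = s, y = history$scores,
       Xo = Xo, zo = history$ages - fr$t_center,
       qd = qd,
       Bq = if (length(qd$t)) evaluate_basis(spec$baseline_basis, qd$t, 0L)
            else matrix(0, 0, spec$baseline_basis$df),
       lag = lagd(qd$t), t_center = fr$t_center, pat = pat)
}

hf_logtarget <- function(hf, p, b) {
  mu <- drop(hf$Xo %*% p$beta) + b[1] + b[2] * hf$zo
  ll <- sum(stats::dnorm(hf$y, mu, sqrt(p$sigma2), log = TRUE))
  if (length(hf$qd$t)) {
    wlin <- sum(p$gamma * hf$wvec)
    mq <- drop(hf$lag$X %*% p$beta) + b[1] + b[2] * hf$lag$z
    mdq <- drop(hf$lag$Xd %*% p$beta) + b[2]
    logh <- drop(hf$Bq %*% p$baseline_coefs) + wlin +
      p$alpha[1] * mq + p$alpha[2] * mdq
    ll <- ll - sum(hf$qd$w * exp(logh))
  }
  Dinv <- solve(p$D)
  ldet <- log(p$D[1, 1] * p$D[2, 2] - p$D[1, 2]^2)
  ll - log(2 * pi) - 0.5 * ldet -
    0.5 * (b[1]^2 * Dinv[1, 1] + 2 * b[1] * b[2] * Dinv[1, 2] +
             b[2]^2 * Dinv[2, 2])
}

#' Sample a new subject's random effects given their history
#'
#' For each retained posterior draw of the model parameters, draws the new
#' subject's random effects from their conditional posterior (longitudinal
#' likelihood of the history, times the probability of remaining event-free
#' up to the landmark age, times the N(0, D) prior) with a short seeded
#' Metropolis chain warm-started at the previous draw.
#'
#' @param fit a `jmsens_fit`.
#' @param history a [new_subject_history()].
#' @param n_draws number of posterior draws to use (evenly spaced through
#'   the stacked chains).
#' @param seed integer seed.
#' @param mh_steps Metropolis steps per parameter draw.
#' @return list with `b` (`n_draws` x 2 matrix) and `draw_index`.
#' @export
sample_new_random_effects <- function(fit, history, n_draws = 200L,
                                      seed = 1L, mh_steps = 20L) {
  stopifnot(inherits(fit, "jmsens_fit"), inherits(history, "jmsens_history"))
  if (length(history$ages) < 1L)
    stop("history must contain at least one observation")
  hf <- history_frame(fit, history)
  M <- n_draws_total(fit)
  n_draws <- min(n_draws, M)
  idx <- unique(round(seq(1, M, length.out = n_draws)))
  set.seed(seed)
  b <- c(0, 0)
  out <- matrix(NA_real_, length(idx), 2L)
  for (j in seq_along(idx)) {
    p <- draw_params(fit, idx[j])
    step <- chol(p$D) * 1.2
    lt <- hf_logtarget(hf, p, b)
    if (!is.finite(lt)) { b <- c(0, 0); lt <- hf_logtarget(hf, p, b) }
    if (!is.finite(lt)) stop("non-finite conditional target for new subject")
    for (m in seq_len(mh_steps)) {
      bp <- b + drop(stats::rnorm(2) %*% step)
      ltp <- hf_logtarget(hf, p, bp)
      if (is.finite(ltp) && stats::runif(1) < exp(ltp - lt)) {
        b <- bp; lt <- ltp
      }
    }
    out[j, ] <- b
  }
  list(b = out, draw_index = idx)
}

#' Dynamic prediction of memory and cumulative incidence
#'
#' For a new, event-free subject with a partial longitudinal history,
#' predicts the memory trajectory and the cumulative incidence of the event
#' (CIF) from the landmark age `s` to `horizon`. For each retained posterior
#' draw the subject's random effects are sampled from their conditional
#' posterior; the memory curve summarizes \eqn{m_{new}(t)} over (parameter,
#' random-effect) draws and the CIF is
#' \eqn{1 - S(u \mid b, \theta)/S(s \mid b, \theta)} with the survival
#' function from the quadrature cumulative hazard. Intervals are pointwise
#' 2.5/97.5% draw quantiles.
#'
#' @param object a `jmsens_fit`.
#' @param history a [new_subject_history()].
#' @param horizon prediction horizon age (years), beyond `s` and within the
#'   baseline-hazard basis support.
#' @param grid_step age grid step (years).
#' @param n_draws posterior draws to use.
#' @param seed integer seed.
#' @param ... unused.
#' @return a data frame of class `jmsens_prediction` with columns `age`,
#'   `memory_mean`, `memory_lo`, `memory_hi`, `cif_mean`, `cif_lo`,
#'   `cif_hi`.
#' @export
predict.jmsens_fit <- function(object, history, horizon, grid_step = 1,
                               n_draws = 200L, seed = 1L, ...) {
  stopifnot(inherits(history, "jmsens_history"))
  s <- history$last_seen
  if (horizon <= s) stop("horizon must exceed the landmark age ", s)
  bb <- object$spec$baseline_basis$boundary_knots
  if (horizon > bb[2] + 1e-9)
    stop("horizon ", horizon, " lies beyond the baseline-hazard basis ",
         "support (upper boundary ", bb[2], "); refit with an extended ",
         "baseline basis")
  hf <- history_frame(object, history)
  re <- sample_new_random_effects(object, history, n_draws, seed)
  nd <- nrow(re$b)
  grid <- unique(c(seq(s, horizon, by = grid_step), horizon))
  G <- length(grid)
  spec <- object$spec
  Xg <- beta_design(spec, grid, hf$male, hf$edu, hf$cohort, 0, hf$pat)
  zg <- grid - hf$t_center
  # per-interval quadrature nodes for the post-landmark cumulative hazard
  gl <- gl_rule(7L)
  a0 <- grid[-G]; b0 <- grid[-1]
  half <- (b0 - a0) / 2
  tq <- rep((a0 + b0) / 2, each = 7L) + rep(half, each = 7L) * gl$x
  wq <- rep(half, each = 7L) * gl$w
  seg <- rep(seq_len(G - 1L), each = 7L)
  Bq <- evaluate_basis(spec$baseline_basis, tq, 0L)
  Xq <- beta_design(spec, tq - spec$lag, hf$male, hf$edu, hf$cohort, 0,
                    hf$pat, 0L)
  Xqd <- beta_design(spec, tq - spec$lag, hf$male, hf$edu, hf$cohort, 0,
                     hf$pat, 1L)
  zq <- tq - spec$lag - hf$t_center

  mem <- matrix(NA_real_, nd, G)
  cif <- matrix(NA_real_, nd, G)
  for (j in seq_len(nd)) {
    p <- draw_params(object, re$draw_index[j])
    b <- re$b[j, ]
    mem[j, ] <- drop(Xg %*% p$beta) + b[1] + b[2] * zg
    wlin <- sum(p$gamma * hf$wvec)
    logh <- drop(Bq %*% p$baseline_coefs) + wlin +
      p$alpha[1] * (drop(Xq %*% p$beta) + b[1] + b[2] * zq) +
      p$alpha[2] * (drop(Xqd %*% p$beta) + b[2])
    Hseg <- rowsum_full(wq * exp(logh), seg, G - 1L)
    cif[j, ] <- 1 - exp(-c(0, cumsum(Hseg)))
  }
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975))
  qm <- qs(mem); qc <- qs(cif)
  out <- data.frame(age = grid,
                    memory_mean = colMeans(mem),
                    memory_lo = qm[1, ], memory_hi = qm[2, ],
                    cif_mean = colMeans(cif),
                    cif_lo = qc[1, ], cif_hi = qc[2, ])
  class(out) <- c("jmsens_prediction", "data.frame")
  attr(out, "landmark") <- s
  out
}

#' @export
plot.jmsens_prediction <- function(x, which = c("memory", "cif"), ...) {
  which <- match.arg(which)
  if (which == "memory") {
    graphics::plot(x$age, x$memory_mean, type = "l", ylim =
                     range(x$memory_lo, x$memory_hi),
                   xlab = "age (years)", ylab = "memory score", ...)
    graphics::lines(x$age, x$memory_lo, lty = 2)
    graphics::lines(x$age, x$memory_hi, lty = 2)
  } else {
    graphics::plot(x$age, x$cif_mean, type = "l", ylim = c(0, 1),
                   xlab = "age (years)", ylab = "cumulative incidence", ...)
    graphics::lines(x$age, x$cif_lo, lty = 2)
    graphics::lines(x$age, x$cif_hi, lty = 2)
  }
  invisible(x)
}
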