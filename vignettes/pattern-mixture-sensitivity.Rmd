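---
title: "Pattern-mixture sensitivity analysis for joint models of cognition and dementia risk"
author: "jmsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-mixture sensitivity analysis for joint models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Longitudinal aging cohorts lose participants, and the people who leave tend
to be those whose cognition is declining. When the decision to drop out
depends on the (unobserved) cognitive values themselves, the missingness is
*not at random* (MNAR), and analyses of the observed data alone — however
sophisticated — can be biased in ways the observed data cannot reveal.
`jmsens` implements a pragmatic answer: fit the model of interest under the
conventional assumptions, then re-fit it under a family of explicit,
interpretable MNAR scenarios and see which conclusions survive.

The model of interest is a Bayesian joint model of a bounded memory score
and the hazard of dementia, with age as the time scale. Two features make
the setting unusual and drive most design choices below: dementia onset is
observed from registry follow-up *even after* study dropout (so the
time-to-event outcome is complete while the longitudinal outcome is not),
and death acts as censoring.

## The substantive model

For subject $i$ at age $t$ (years),

$$y_i(t) = m_i(t) + \varepsilon_i(t), \qquad
  m_i(t) = f(t) + x_i(t)^\top\beta + b_{0i} + b_{1i}(t-\bar t),$$

with $\varepsilon_i(t) \sim N(0, \sigma^2)$ independent of
$(b_{0i}, b_{1i}) \sim N(0, D)$. The smooth age trend $f$ is a natural cubic
spline (3 df by default). The fixed covariates are a male indicator,
education (years), a first-assessment indicator and its interaction with age
(practice effects: performance improves on repeated testing, less so at
older ages), and birth cohort (birth year minus 1937). Time is centered at
$\bar t$, the mean age over observed assessments.

The hazard of dementia, with delayed entry at the enrollment age, is

$$h_i(t) = h_0(t)\exp\{\gamma^\top w_i + \alpha_1\, m_i(t-L) +
  \alpha_2\, m_i'(t-L)\},$$

where $w_i$ = (male, education), $L = 5$ years by default (a scientific
choice: current dementia risk against memory level and slope five years
earlier, unrelated to the wave spacing), and $\log h_0$ is a cubic B-spline
(9 basis functions by default). Inside the hazard the first-assessment
indicator is set to 0: we take the hazard to track post-practice memory.
This is an interpretive choice, configurable in principle via the design
matrix, and is documented rather than asserted as the only option.

### Numerical choices

* **Spline bases.** The natural cubic basis is the truncated-power natural
  basis, so values *and* first derivatives are exact analytic expressions
  and the basis is exactly linear outside its boundary knots. Linear-tail
  extrapolation is also how $m_i(t-L)$ is evaluated when the lag reaches
  below the boundary knot (no truncation of the lag). Default knots:
  boundary at the 0.5%/99.5% quantiles of observed assessment ages,
  interior at equally spaced quantiles; the baseline B-spline spans
  [min entry age, max event age] so every quadrature node is inside its
  support. All knots are stored in the fitted object so fits are exactly
  reproducible.
* **Survival integrals.** $\int_a^{T} h_i(s)\,ds$ uses 15-point
  Gauss–Legendre per subject (configurable). On log-linear hazards this is
  accurate to below 1e-8 relative error over 30-year intervals; across
  spline knots the integrand is only piecewise-smooth and accuracy is
  ~1e-5, which is far below the Monte-Carlo error of any MCMC summary.
* **Priors.** N(0, 100^2) on regression coefficients (the score scale runs
  to 76, so the intercept needs genuine room — a N(0, 10^2) prior visibly
  shrinks it), N(0, 10^2) on $\gamma$ and $\alpha$, half-$t_3$ on $\sigma$
  and the random-effect SDs, uniform on the random-effect correlation, and
  a first-difference Gaussian random walk (scale 2) on the baseline
  coefficients as a smoothness prior.

### The sampler

`fit_joint_model()` runs an adaptive Metropolis-within-Gibbs sampler:

1. $\beta$ — independence Metropolis from the *exact* Gaussian conditional
   given the longitudinal data and prior; the acceptance ratio reduces to
   the survival likelihood ratio, so this block is near-Gibbs (acceptance
   typically 0.6–0.9).
2. $(\gamma, \alpha)$, 3. baseline coefficients, 4.
   $(\log\sigma, \log sd_0, \log sd_1, \mathrm{atanh}\,\rho)$ — multivariate
   random walks whose scale and covariance adapt during warmup towards a
   0.4–0.5 acceptance rate.
5. Random effects — all subjects proposed jointly, accepted per subject
   (valid because subjects are conditionally independent), with per-subject
   adaptive scales.
6. Translation moves — the global intercept vs. all $b_0$, the raw-age
   coefficient vs. all $b_1$ (with an intercept correction through
   $\bar t$), and each pattern-deviation intercept vs. its pattern's
   $b_0$. These directions leave the likelihood exactly invariant and are
   near-unidentified marginally; without the moves they dominate the
   autocorrelation time.

Adaptation freezes after warmup, so kept draws come from a fixed-kernel
chain. Every chain is seeded (`seed + chain - 1`); identical configuration
gives bit-identical draws. Convergence is monitored with split-PSRF,
effective sample sizes, and per-block acceptance rates
(`convergence_diagnostics()`).

## The pattern-mixture imputation model

Dropout patterns group subjects by cohort design and length of stay:
completers of long (≥ 5 scheduled waves) cohorts (`0.a`), completers of
short cohorts (`0.b`), long-cohort dropouts after their 3rd/4th/5th
scheduled wave (`3`, `4`, `5`), and any dropout with one or two observed
waves (`2`). Pattern `2` deliberately pools single-observation subjects:
a random intercept *and* slope model is not identifiable from patterns with
one observation per subject, so they are merged with the two-observation
dropouts. A subject truncated by dementia or death before their next
scheduled wave is a completer — they did not withdraw.

The imputation model replaces $f(t)$ by a reference smooth plus
pattern-specific deviations (each an intercept plus a natural cubic spline,
df configurable; the deviation spline can be switched off for small data),
keeping common covariate effects and the survival submodel, so imputations
are informed by both the longitudinal and the event process. On observed
data the sensitivity offset is identically zero, so a single imputation-model
fit serves every scenario.

Missing post-dropout assessments are imputed at their scheduled ages,
strictly after the dropout age and strictly before dementia onset (for
events) and death (for the deceased); intermittent gaps are never imputed.
For each of $K$ selected posterior draws, the imputed score is the
pattern-specific mean using that draw's fixed effects *and that subject's
random-effect draw from the same posterior draw* (joint coherence — we do
not re-simulate from $N(0, D)$), plus the sensitivity offset
$\Delta_{\text{eff}} (t - t_{F})_+$, plus fresh measurement noise, floored
at 0. There is no cap at the maximum score by default (only the floor is
part of the imputation rule; a cap flag exists but is off).

Three $\Delta$ families are provided: constant; an age-threshold rule
(dropout at or before 60 keeps the pre-dropout trend, later dropout declines
an extra 1 point/year by default — younger dropouts mostly leave for
reasons unrelated to cognition, and imputing extra decline for them would
make the youngest participants the steepest decliners); and an age-varying
cubic $\Delta(\text{age}) = -((\text{age}-25)/75)^3$, which is 0 at 25,
near zero before 60 and $-1$ at 100. The cubic is evaluated at the
*imputation* age (so the additional decline steepens with age); evaluating
at the dropout age is available via `eval_at = "dropout"`. Whether the
accrual should instead integrate the age-varying slope over
$(t_F, t)$ is a genuinely open design point; the pointwise form is
implemented and the alternative is a one-line change in `delta_value()`.

Draw selection is uniform without replacement and scenario-keyed: each
scenario uses its own seed stream, so scenarios are independent yet the
whole analysis is reproducible, and changing $\Delta$ changes only imputed
values, never the fitted imputation-model draws.

## Workflow and pooling

`run_sensitivity()` orchestrates: (A) substantive fit on observed data (the
MAR baseline); (B) one imputation-model fit; (C) per scenario, $K$
imputations and $K$ substantive refits; (D) pooled summaries and a
side-by-side table (`MAR`, `delta0`, `delta-1`, `age_varying`).

Two pooling rules are reported. The default concatenates each imputation's
chains and pools the $K$ draw sets into one mixture (mean, SD, 2.5/97.5%
quantiles, and the within/between-imputation variance decomposition);
`rubin_pool()` additionally applies the classical combination rules
(within + $(1 + 1/K)\times$ between, $t$ reference) as a cross-check. The
mixture quantiles are *not* inflated by between-imputation variance beyond
what the mixture itself carries; where that distinction matters the Rubin
output is the conservative companion. With $K = 5$ and ~19% missing
information the relative efficiency loss versus infinitely many imputations
is $100(1-(1+\gamma/K)^{-1}) \approx 4\%$ — the package's default $K$
accepts that loss.

Refits of completed datasets keep the *base* dataset's $\bar t$ and spline
knots, so all scenarios and the MAR baseline share one parameterization and
their coefficient tables are directly comparable.

## Dynamic prediction

For a new, event-free subject with a partial history, `predict()` draws the
subject's random effects from their conditional posterior (history
likelihood × probability of remaining event-free to the landmark ×
$N(0,D)$) with a short seeded Metropolis chain, *re-sampling the random
effects for every retained parameter draw*, so the credible bands reflect
both parameter and random-effect uncertainty. The memory curve summarizes
$m_{\text{new}}(t)$; the cumulative incidence is
$1 - S(u \mid b, \theta) / S(s \mid b, \theta)$ per draw, which is 0 at the
landmark and monotone within every draw by construction. Predictions beyond
the baseline-spline support are refused with advice to refit with an
extended basis. Scenario-wise curves come from predicting with each
scenario's refits (`keep_fits = TRUE` in `run_sensitivity()`); the observed
history is held fixed across scenarios.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it is the package's
test bed and defines the validation conditions. It emulates a multi-cohort
prospective design: three enrollment cohorts (6, 3 and 1 scheduled waves;
40/30/30% weights) with waves 5 years apart, entry ages 35–85 by cohort,
bounded scores, per-wave logistic dropout that may depend on the *latent*
current memory value or the slope random effect (MNAR by construction),
dementia onset simulated by numerically inverting each subject's
quadrature-evaluated cumulative hazard under the true joint model, Gompertz
death (rate 0.01, shape 0.09, anchor 60 — roughly human old-age mortality),
and a registry window extending 8 years past the final scheduled wave in
which dementia and death remain observable after dropout. The default true
parameters give a mean trajectory declining from ~40 points at 40 to ~14 at
95, ~15% dementia, ~40% death, and ~30% of scheduled measurements missing —
the shape of a long-running aging cohort. An optional true post-dropout
extra slope (`true_delta`) realizes exactly the kind of MNAR mechanism the
sensitivity analysis probes.

Two deliberate departures from realism, both switchable:

* scores are *not* clipped to [0, 76] by default — clipping breaks the
  Gaussian error model and would confound parameter-recovery validation
  (`clip_scores = TRUE` exists for demonstrations);
* the dataset returned for validation is prepared without the early-onset
  exclusion, again so the generating model holds exactly; the study-like
  filters (`prep_rules()`) are applied when the generator feeds the CLI
  pipeline.

What passing recovery tests therefore show is that the estimator recovers
the truth *when the model is correct*; they do not certify behavior under
boundedness, measurement floors/ceilings, or misspecified trajectories in
real cohort data.

## Validation choices and problem sizes

The shipped tests exercise: analytic identities of the $\Delta$ machinery
and pooling rules; quadrature against closed forms and a dense trapezoid
oracle; parameter recovery on 5 replicates of 300 subjects × 4 waves with
2 chains × 2000 kept draws (coverage of 95% intervals for 10 monitored
parameters); the direction of the sensitivity analysis on 5 replicates of
200 subjects with true post-dropout slope $-1$ ($K = 5$, value-dependent
MNAR dropout); conditional random-effect sampling against the closed-form
mixed-model conditional; and bit-identical reruns of the full pipeline.
These sizes are the package's validation choices: large enough that
coverage and ordering statements are meaningful, small enough to run
routinely.

Two empirical regularities from those runs are worth stating. First,
seed-matched imputed means are pointwise non-increasing in $\Delta$ — the
floor at 0 is monotone, so this holds deterministically. Second,
delta-adjusted refits tend to *attenuate* the slope–hazard association
relative to $\Delta = 0$: steeply declining imputed trajectories accrue
event-free exposure among dropouts who never develop dementia, diluting the
slope–event contrast. Users should expect more negative $\Delta$ scenarios
to weaken, not sharpen, estimated associations, and should read the
scenario table as a robustness range rather than a bias correction.

## Known limitations

* The longitudinal outcome is modeled as unbounded Gaussian; floor/ceiling
  effects of a bounded score are not modeled (only the imputation floor).
* Death is non-informative censoring; an illness–death model is out of
  scope.
* Only the longitudinal outcome is imputed — never the event time, never
  intermittent gaps, never anything after death or onset.
* $\Delta$ is a user-declared sensitivity input. It is not estimable from
  the observed data, and the package deliberately provides no machinery to
  "choose" it.
* The sampler is pure R; it is fast enough for cohorts of a few thousand
  subjects, but very large studies would warrant a compiled or
  gradient-based backend (the seed/reproducibility contract is the
  interface such a backend must honor).
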