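# jmsens

Pattern-mixture multiple-imputation sensitivity analysis for Bayesian joint
models of longitudinal cognition and time to dementia.

## The problem

In long-running aging cohorts, participants who are declining are the ones
most likely to stop attending — so the missing memory scores are plausibly
*missing not at random* (MNAR), and no analysis of the observed data alone
can verify or correct that. Meanwhile dementia diagnoses are often complete
(registry follow-up continues after dropout) and death censors follow-up.
`jmsens` targets exactly this configuration. It is aimed at biostatisticians
analyzing prospective cohort studies who want their joint-model conclusions
stress-tested against explicit, interpretable dropout assumptions.

## The model and the method

The substantive model is a joint model on the age scale with delayed entry:

* longitudinal submodel:
  `y_i(t) = f(t) + x_i(t)'β + b_0i + b_1i (t − t̄) + ε_i(t)`,
  with `f` a natural cubic spline, covariates sex, education, a
  first-assessment (practice) indicator, practice × age, and birth cohort;
* hazard submodel:
  `h_i(t) = h_0(t) exp{γ'w_i + α₁ m_i(t−5) + α₂ m_i'(t−5)}`,
  a B-spline log baseline hazard and a lagged current-value +
  current-slope association.

The sensitivity analysis follows the multiple-imputation route:

1. fit the substantive model to the observed data (the MAR baseline);
2. fit a *pattern-mixture* imputation model once — the age trend gains
   pattern-specific smooth deviations for six dropout patterns defined by
   cohort design and length of stay;
3. for each sensitivity scenario Δ (the assumed extra decline, in
   points/year, after dropout: constant, threshold-at-60, or the
   age-varying cubic `Δ(age) = −((age−25)/75)³`), impute every missing
   post-dropout score K times from the posterior, adding
   `Δ_eff · (t − t_dropout)₊`, flooring at 0;
4. refit the substantive model on each completed dataset and pool across
   imputations (mixture pooling, with Rubin's rules as a cross-check);
5. compare the scenario-wise estimates, and the scenario-wise dynamic
   predictions of memory and cumulative dementia incidence for new
   subjects.

A seeded synthetic-cohort generator with known truth (MNAR dropout tied to
the latent trajectory, registry-observed events, Gompertz death) is part of
the package and backs its entire test suite.

## Worked example

```r
library(jmsens)

sim <- simulate_cohort(simulation_config(n_subjects = 200, seed = 42,
  true_delta = -1, dropout_model = c(intercept = 1.5, value = -0.1)))
print(sim$dataset)
#> Joint longitudinal/survival dataset
#>   subjects:              200
#>   assessments observed: 479 (of 632 rows)
#>   events:                56
#>   centering age t-bar:  61.12 years
#>   patterns:
#> 0.a 0.b   2   3   4   5
#>  43 108  35   7   4   3

sens <- run_sensitivity(
  sim$dataset,
  substantive = sim$config$spec,
  imputation  = imputation_model_spec(sim$config$spec, pattern_df = 1),
  scenarios   = list(delta_constant(0), delta_threshold(-1, 60),
                     delta_cubic()),
  K = 5,
  control = mcmc_control(chains = 2, warmup = 500, iterations = 500,
                         seed = 42))

tab <- sens$table
tab[tab$parameter %in% c("male", "education", "alpha_value",
                         "alpha_slope", "sigma"), ]
#>    parameter                     MAR                  delta0
#>         male -2.900 (-4.666, -1.060) -2.662 (-5.131, -0.606)
#>    education    0.721 (0.430, 1.031)    0.689 (0.343, 1.086)
#>  alpha_value -0.040 (-0.063, -0.008) -0.056 (-0.089, -0.020)
#>  alpha_slope -1.553 (-3.316, -0.335) -1.752 (-3.630, -0.373)
#>        sigma    4.152 (3.842, 4.452)    4.087 (3.738, 4.420)
#>                  delta-1             age_varying
#>  -3.002 (-5.211, -0.903) -3.032 (-5.386, -0.893)
#>     0.704 (0.356, 1.090)    0.720 (0.376, 1.032)
#>  -0.054 (-0.094, -0.012) -0.059 (-0.098, -0.028)
#>  -1.205 (-2.224, -0.111)  -1.280 (-2.598, 0.035)
#>     4.163 (3.777, 4.566)    4.198 (3.826, 4.582)
```

Reading the table: each column is one assumption about post-dropout
decline; each cell is a pooled posterior mean with 2.5/97.5% quantiles.
Here (data generated with a true extra post-dropout slope of −1, true
`α₁ = −0.07`, `α₂ = −1.5`, `σ = 4`) both association weights stay negative
under every scenario — worse memory and steeper decline predict higher
dementia risk regardless of the dropout assumption — while the slope
association is attenuated under the more pessimistic Δ scenarios, a
behavior discussed in the methods vignette. Take the spread across columns,
not any single column, as the robustness statement.

Dynamic prediction for a new subject under the MAR fit:

```r
h <- new_subject_history("female", 11, 1937, ages = c(60, 65, 70),
                         scores = c(30, 28, 25))
pred <- predict(sens$mar, h, horizon = 90, n_draws = 200, seed = 1)
plot(pred, "cif")
```

A thin command-line driver covering the whole pipeline
(`simulate`, `prepare`, `fit`, `impute`, `sensitivity`, `predict`, `pool`
over a YAML config) ships in `inst/cli/`; see
`system.file("cli", "example-config.yaml", package = "jmsens")`.

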