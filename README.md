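# dyadmnl

Bayesian multilevel multinomial logistic regression for **directed dyadic
behavioral observations** — event records in which one individual (the
initiator) directs one of *K* coded behaviors at another (the recipient).
The package was built for naturalistic observation studies of child-to-child
social behavior (hundreds of children nested in households, thousands of
events over 19 behavior categories), and for the methodologists who want to
validate that style of analysis end-to-end on synthetic communities with
known ground truth.

## The model

For initiator *i* and recipient *j*, event categories follow a multinomial
logit with a fixed reference category *K* (*ownership assertion* in the
default taxonomy):

```
log(π_k,i,j / π_K,i,j) = α_k + ν^I_k,i + ν^R_k,j + h^I_k,[i] + h^R_k,[j]
                         + Σ_m β_k,Im x_Im + Σ_m β_k,Rm x_Rm + β_k,H x_H
```

with correlated individual-level random effects `ν` per role (and
optionally household-level `h`), drawn from zero-mean multivariate normals
whose covariance is split into per-category scales and a correlation
matrix with an LKJ(2) prior on its Cholesky factor, in a non-centered
parameterization. Four variants (`i`, `ih`, `iF`, `ihF`) switch the
household effects and the fixed-effect blocks (age, sex, age × sex for
each role, plus a same-household indicator) on and off. Posteriors are
sampled with the package's own seeded No-U-Turn HMC sampler
(Rcpp/Armadillo, analytic gradients); models are compared by WAIC with
Akaike-style weights; and the posterior is post-processed into the
analysis surfaces: random-effect SDs, cross-behavior correlations with
significance flags, predicted-probability scenarios and contrasts at zero
random effects, age-trend labels, and dyad-level descriptives.

## Worked example

Simulate a community from a known truth (the packaged recovery study:
8 behavior categories, 60 children in 25 households, 2500 events,
planted initiator correlations +0.5 between categories 1–2 and −0.5
between 1–3), fit the generating variant, and inspect what comes back:

```r
library(dyadmnl)

sim <- simulate_dataset(recovery_config(seed = 101), demo_truth())
sim$data
#> dyad_data: 2500 events, 60 children, 25 households, 8 behavior categories

fit <- fit_model(model_spec("iF", sim$taxonomy), sim$data,
                 mcmc_config(chains = 3, iter = 1500, warmup = 500,
                             seed = 202))
fit
#> dyad_fit: variant iF | 3 chains x 1000 retained draws | 952 parameters
#>   divergences: 0 | mean accept: 0.936

diagnose(fit)
#> Diagnostics over 952 parameters
#>   max R-hat: 1.0083
#>   divergences per chain: 0, 0, 0

head(posterior_summary(fit), 3)
#>      param  mean    sd lower upper
#> 1 alpha[1] 0.668 0.195 0.283 1.051
#> 2 alpha[2] 0.572 0.186 0.189 0.928
#> 3 alpha[3] 1.102 0.180 0.753 1.449
```

The generating intercepts were (0.55, 0.5, 0.5): the first two posteriors
sit on them; the third lands high in this realization, consistent with
the roughly nominal interval coverage measured over all 56 fixed-effect
parameters (93% at the 95% level in this run). The planted cross-behavior
correlations come back from the Cholesky recomposition with the right
signs and magnitudes:

```r
rc <- recompose_correlations(fit, "initiator")
rc[rc$l == 1 & rc$k <= 3,
   c("k", "l", "mean", "lower", "upper", "significant")]
#>   k l   mean   lower  upper significant
#> 1 2 1  0.371 -0.0374  0.715       FALSE
#> 2 3 1 -0.496 -0.8057 -0.130        TRUE
```

WAIC comparison recovers the generating variant against the
intercept-only alternative:

```r
fit_i <- fit_model(model_spec("i", sim$taxonomy), sim$data,
                   mcmc_config(chains = 3, iter = 1500, warmup = 750,
                               seed = 203))
compare_models(i = fit_i, iF = fit)
#>   model    waic se_waic delta se_delta weight
#> 1    iF 8304.52   88.13  0.00       NA      1
#> 2     i 8376.43   85.59 71.91    21.82      0
```

Predicted probabilities and contrasts read off the fixed effects at zero
random effects — for example full age curves via
`predict_probabilities(fit, prediction_scenario("initiator_age",
grid = seq(0, 12, 0.5)))` followed by `label_age_trend()`, or
boy-initiated versus girl-initiated contrasts via `contrast_scenarios()`.

Published four-model WAIC tables can be fed straight into the comparison:

```r
compare_models(list(Model_i = 33229.93, Model_ih = 33239.64,
                    Model_iF = 32843.83, Model_ihF = 32841.64))
#>       model     waic se_waic  delta se_delta weight
#> 1 Model_ihF 32841.64      NA   0.00       NA  0.749
#> 2  Model_iF 32843.83      NA   2.19       NA  0.251
#> 3   Model_i 33229.93      NA 388.29       NA  0.000
#> 4  Model_ih 33239.64      NA 398.00       NA  0.000
```

## Package layout

| Area | Functions |
| --- | --- |
| Data I/O | `load_roster`, `load_observations`, `write_*`, `build_design` |
| Synthetic communities | `sim_config`, `simulate_community`, `draw_truth`, `make_truth`, `demo_truth`, `recovery_config`, `simulate_observations`, `simulate_dataset` |
| Model | `model_spec`, `prior_config`, `linear_predictor`, `category_probabilities`, `log_likelihood_pointwise`, `log_prior` |
| Fitting | `fit_model`, `mcmc_config`, `mcmc_profile`, `diagnose`, `rhat`, `posterior_summary`, `extract_par` |
| Comparison | `waic`, `compare_models` |
| Reporting | `recompose_correlations`, `random_effect_sds`, `prediction_scenario`, `predict_probabilities`, `contrast_scenarios`, `label_age_trend`, `dyad_descriptives` |

The methods vignette (`vignettes/dyadic-multinomial-models.Rmd`) documents
the model, priors, sampler, generator and the package's design decisions.
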