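---
title: "Multilevel multinomial models for dyadic behavioral observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel multinomial models for dyadic behavioral observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The data structure and the model

`dyadmnl` analyzes *directed dyadic events*: records of one individual (the
initiator) directing one of $K$ categorically coded behaviors at another
individual (the recipient). The motivating application is naturalistic
observation of child-to-child social behavior in a village community —
around two hundred children nested in households, thousands of observed
behaviors over $K = 19$ categories — but nothing in the implementation is
specific to that setting beyond the default taxonomy.

Writing $\pi_{k,i,j}$ for the probability that an event initiated by child
$i$ toward child $j$ falls in category $k$, the model is a multinomial
logistic regression on $K-1$ log-odds contrasts against a fixed reference
category (category $K$, *ownership assertion* in the default taxonomy):

$$
\log\left(\frac{\pi_{k,i,j}}{\pi_{K,i,j}}\right)
 = \alpha_k + \nu^I_{k,i} + \nu^R_{k,j}
 + h^I_{k,[i]} + h^R_{k,[j]}
 + \sum_m \beta_{k,Im} x_{Im} + \sum_m \beta_{k,Rm} x_{Rm}
 + \beta_{k,H}\, x_H ,
$$

for $k = 1, \dots, K-1$, with the reference contrast pinned at zero. Four
variants switch terms on and off (`model_spec()`):

* **i** — intercepts plus correlated individual-level random effects
  $\nu^I, \nu^R$ for each child in each role;
* **ih** — adds household-level random effects $h^I, h^R$ with their own
  correlation structure, nested (each child belongs to one household);
* **iF** — adds the fixed-effect blocks: initiator age, sex, age × sex;
  the same for the recipient; and the same-household indicator $x_H$;
* **ihF** — all of the above.

Each child carries a full $(K-1)$-vector of random effects per role, drawn
from a zero-mean multivariate normal whose covariance is decomposed into a
correlation matrix and per-category scales. The off-diagonal correlations
are scientifically central: they say whether children who initiate (or
receive) more of one behavior also initiate (or receive) more or less of
another.

## Priors

Following the model statement: standard normal priors on intercepts and
fixed effects; an LKJ prior with shape 2 on the Cholesky factor of each
correlation matrix; standard normal non-centered innovations. The prior on
the random-effect scales is not part of the model statement; we default to
half-normal(0, 1), record it in every output, and expose it in
`prior_config()` so a prior-sensitivity analysis is one configuration
change. Random effects use the non-centered parameterization
$\nu = \mathrm{diag}(\sigma)\, L\, z$ with $z$ standard normal and $L$ the
correlation Cholesky factor, which removes the scale-location funnel that
frustrates gradient-based samplers in hierarchical models.

## Interpretation conventions

Sex is coded female = 0, male = 1 and ages are standardized, so $\alpha_k$
is the log-odds (against the reference behavior) for a female-to-female,
different-household dyad at the sample-average ages. Continuous covariates
are standardized per role by their own event-level mean and SD — the
pooling rule is not uniquely determined by the model statement; per-role
standardization keeps each column exactly mean-zero/SD-one, and the choice
is recorded in the stored `scaler` so that prediction scenarios expressed
in natural units (years) are transformed identically. Episode structure is
recorded in the data files but ignored by the likelihood: events are
treated as conditionally independent multinomial draws given covariates
and random effects, which matches an analysis that amalgamates responses
over observation episodes.

# Posterior computation

The posterior is sampled by a No-U-Turn Hamiltonian Monte Carlo sampler
implemented in the package (Rcpp/Armadillo), with hand-derived analytic
gradients of the joint log density on the unconstrained scale. The sampler
backend is deliberately self-contained: the only requirements are
reproducible seeded NUTS and per-draw pointwise log-likelihoods, and both
are satisfied without external probabilistic-programming dependencies.
The unconstrained parameterization is:

* scales through $\log \sigma$;
* correlation Cholesky factors through $\tanh$-transformed canonical
  partial correlations (the same construction Stan uses), with the exact
  tanh and partial-correlation-to-factor Jacobians included in the target;
* everything else identity.

Correctness of the gradients is enforced in the test suite by
finite-difference comparison on all four variants, and the C++ joint
density is checked to equal the R-level `log_prior()` +
`log_likelihood_pointwise()` + Jacobian terms to machine precision.

Warmup uses dual-averaging step-size adaptation toward a 0.9 acceptance
target and Stan-style expanding-window estimation of a diagonal mass
matrix; after warmup both are frozen. Momenta, slice variables and
doubling directions are drawn from R's RNG, so `set.seed()`-derived chain
seeds make every fit bit-reproducible. Divergent transitions (energy error
above 1000) are counted per chain, and a divergence rate over 10% attaches
a warning to the fit.

Two operating points are packaged as `mcmc_profile()`: a full-scale
profile (3 chains × 10000 iterations, 5000 warmup) for real field
datasets, and a desk profile (3 × 1500, half warmup) for simulation
studies. Convergence is assessed with split rank-normalized
R-hat and bulk effective sample size (`diagnose()`), and posterior
summaries use empirical percentile intervals throughout; "significant"
always means the 95% percentile interval excludes zero, with a
Bonferroni-flagged column emitted alongside wherever many pairs are tested
at once (no correction is applied in the primary output because the
original analysis applies none).

# Model comparison

`waic()` computes the Widely Applicable Information Criterion from the
draws × events pointwise log-likelihood matrix:
$\mathrm{lppd} = \sum_n \log \frac{1}{S}\sum_s e^{\ell_{sn}}$ (via
log-sum-exp), $p_{\mathrm{WAIC}} = \sum_n \mathrm{Var}_s(\ell_{sn})$, and
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, with a standard
error from the event-level dispersion of pointwise contributions.
`compare_models()` reports each model's difference from the minimum-WAIC
model and Akaike-style weights $w_m \propto e^{-\Delta_m/2}$, interpreted
as the probability that model $m$ predicts best on new data among the
candidates; pairwise delta standard errors against the best model are
included when pointwise matrices are available.

# Reporting surfaces

* `recompose_correlations()` rebuilds, per draw, each correlation matrix
  from its sampled Cholesky factor ($L L^\top$) and summarizes every
  category pair with posterior mean, percentile interval and significance
  flags.
* `random_effect_sds()` summarizes the per-category random-effect SDs per
  role — the quantity that shows how much unobserved individual (or
  household) heterogeneity each behavior carries, and how much of it the
  demographic covariates absorb when moving from variant `i` to `iF`.
* `predict_probabilities()` evaluates, per draw, the $K$-simplex at zero
  random effects for a scenario fixed on the natural scale (years, sex
  labels, household status), optionally varying one covariate over a grid;
  "average child" means all random effects zero and continuous covariates
  at the event-level sample mean, consistent with the standardization
  base. Each draw contributes a complete simplex, so posterior means are
  means of probabilities, not probabilities of means.
* `contrast_scenarios()` differences two scenarios draw-by-draw and flags
  categories whose difference interval excludes zero (e.g. boy-initiated
  minus girl-initiated probability of each behavior).
* `label_age_trend()` classifies each category's posterior-mean curve over
  an age grid as increasing, decreasing, or peaked; "monotone" is judged
  with a small tolerance (`tol`, default 1e-6) on successive differences,
  and a peaked curve reports the yearly interval containing the grid
  argmax. The default grid is 0-12 years in half-year steps; the bracket
  conventions of finer published tables imply sub-year resolution, which
  the half-year grid provides.
* `dyad_descriptives()` reproduces the descriptive surfaces: totals,
  unique directed dyads and events-per-dyad by behavior × same/different
  household × same/different sex, plus per-child and per-household
  participation counts (each event counts once for the initiator and once
  for the recipient, so the per-child mean is $2N/I$).

Unique pairs are *directed* dyads by default, since initiator and
recipient sex combinations are distinguished in the descriptive figures
this mirrors.

# The synthetic-community generator

Because the original field data are archived externally, every stage of
the pipeline is validated against a generator that draws full communities
and event histories from the variant-`ihF` generative process with known
parameters (`sim_config()`, `simulate_community()`, `draw_truth()`,
`simulate_observations()`).

What the defaults emulate: 213 children in 70 households with sizes 1-9
(the exact-sum constraint fixes the mean at $213/70 \approx 3.04$; a
truncated negative-binomial size law supplies dispersion in the observed
regime), a 49% male sex ratio, right-skewed ages on $[0, 12)$ (scaled
Beta(1.5, 2.5), mean ≈ 4.5 y), 6507 events over 19 categories, and event
traffic concentrated within households. Dyad exposure — who is observed
with whom, how often — is a nuisance process the behavioral model never
touches; we draw gamma-weighted multinomial allocations over directed
dyads (equivalent to overdispersed negative-binomial dyad counts
conditioned on the total) with a same-household weight multiplier (default
80, chosen so that roughly half of all events are within-household, as in
the observed community). Exposure is independent of behavior category
given the dyad. Ages are fixed per child by default; an optional
time-varying mode spreads each child's events over a two-year window with
continuously increasing age.

What the generator does **not** emulate: episode narratives and their
internal dependence, reactive (response) behaviors, multi-party
interactions, kinship links between households, seasonal or locational
structure in exposure. Passing recovery tests therefore demonstrates that
the estimation machinery is correct under the model's own assumptions —
not that those assumptions hold in any particular field dataset.

Reduced-category presets (e.g. $K = 4$, $K = 8$) are first-class: desk
validation studies use them so that full posterior recovery runs in
minutes. The packaged reference study (`demo_truth()` +
`recovery_config()`) uses $K = 8$, 60 children in 25 households, 2500
events, fixed effects within one prior SD, scales up to 0.6 and two
planted initiator correlations (+0.5, −0.5), sampled with 3 chains × 1500
iterations (500 warmup); this yields all R-hat < 1.01, near-nominal
coverage of fixed effects, and planted correlations recovered with the
correct sign — the test suite and `scripts/acceptance.R` recompute all of
this from scratch. Two aspects of that study are deliberate experimental
design rather than field emulation. First, its exposure process is nearly
balanced (mild gamma overdispersion, small same-household multiplier):
under the field-like, strongly skewed exposure defaults a handful of
heavily observed children dominate the random-effect likelihood, so the
effective (exposure-weighted) correlation in any one realization can sit
far from the population value, and no estimator can be benchmarked
against the planted truth. Second, the intercepts make the categories
carrying the planted correlations the most frequent ones: a
cross-behavior correlation is only estimable when both behaviors occur
several times per child, and with 2500 events over 60 children and 8
categories, pairs planted on rare categories are attenuated toward the
prior regardless of sampler quality. Both effects are worth knowing about
when interpreting correlation estimates from real observational data.
Other validation problem sizes (chosen to keep each check sharp but
quick) are recorded in the individual tests: e.g. generative-consistency
at 30000 events on a two-child community, calibration at 2000 events with
$K = 4$.

# Numerical choices and degenerate inputs

* Probabilities always go through log-sum-exp; unnormalized $e^\eta$ is
  never materialized. Simplexes sum to 1 to 1e-12 by construction.
* Standardization refuses zero-variance age columns; the stored scaler
  makes it idempotent and reusable for prediction scenarios.
* Initialization jitters unconstrained parameters uniformly, with
  non-centered innovations started near zero and log-scales started in
  $[e^{-1.5}, e^{-0.5}]$; a non-finite density at the initial point is an
  error rather than a silent retry.
* `n_events = 0` yields an empty, schema-correct dataset, not an error.
* The LKJ normalizing constant is computed exactly via the canonical
  partial correlation Beta factorization, so `log_prior()` is a proper
  log-density, testable term by term.
* Ties in the age-trend argmax resolve to the earliest grid point
  (`which.max`), and the peak interval is reported as
  $[\lfloor a \rfloor, \lfloor a \rfloor + 1)$.

# Known limitations

* The additive linear predictor contains no cross-role interactions
  (initiator sex × recipient sex, sex × household). Contrasts conditional
  on the partner's attributes are computed from predicted-probability
  cells instead; if the data-generating process truly interacts across
  roles, variant `iF`/`ihF` can only approximate it. The covariate set is
  configurable, so such terms can be added to the design explicitly.
* WAIC is the only comparison criterion (no cross-validation, stacking or
  Bayes factors), matching the analysis this package operationalizes.
* The sampler adapts only a diagonal mass matrix; strongly correlated
  posteriors (e.g. nearly unidentified scales for very rare categories)
  mix more slowly and show up in R-hat/ESS rather than being repaired
  automatically.
* Percentile intervals from finite draws are noisy in their extreme
  quantiles; thinning the posterior by large factors perturbs band edges
  by Monte-Carlo error in either direction.
* Household-level effects are exchangeable across households; kinship ties
  *between* households (a known feature of the motivating community) are
  out of scope, as are household-level covariates.
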