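---
title: "Methods: a stochastic (st)age-structured model of a cooperative breeder"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic (st)age-structured model of a cooperative breeder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warblerSMPM)
```

## The biological setting

The model describes a saturated island population of a facultatively
cooperative breeder such as the Seychelles warbler. A fixed number of
territories (`termax`, default 111.2 in units of breeding females) is held
by **dominants**; the rest of the population consists of **subordinates**,
split into **helpers** (who assist a dominant's brood) and
**non-helpers**. Subordinates can only become breeders by winning a vacant
territory; helpers and non-helpers differ in their per-capita success in
that competition, and potentially in survival and in the reproduction of
the dominant they assist.

## State and census

The census runs on half-year steps. The state vector stacks, in order,

* dominants on an age grid from 1 to 15 years (29 classes),
* helpers on a grid from 0.5 to 15 years (30 classes),
* non-helpers on the same grid (30 classes),

with a *recursive top class*: birds at 15 years that survive remain at 15.
Two density covariates are computed fresh at each census: the standardised
population size `N` (raw total minus a standardisation mean, divided by a
standardisation sd, defaults 170 and 15) and the subordinate-to-dominant
ratio `r`.

## Demographic rates

Every demographic probability is logistic in a linear predictor
(`logistic_rate()`):

* `S_d`, `S_h`, `S_u` — seasonal survival of dominants, helpers,
  non-helpers;
* `R_d` — reproduction of a dominant, a mixture over help received:
  with probability `p_help(age, r)` the helped rate (`q = 1`) applies,
  otherwise the unhelped rate (`q = 0`);
* `R_h` — reproduction of helpers (subordinate co-breeding);
* `f` — the probability that an offspring recruits as a helper, a function
  of the mother's age and of density.

Intercepts of the six seasonal functions vary among seasons; slopes are
fixed. Environmental stochasticity enters by *kernel resampling*: each
step draws one season uniformly at random from the kernel and uses that
season's full intercept vector, which preserves the within-season
covariance of the six channels while imposing no temporal autocorrelation.
`p_help` is the only non-seasonal function; by default it peaks at 10
years of age and increases with `r`.

## The weighted lottery

With expected surviving dominants `sum(S_d * d)`, the vacancy count is
`x = max(0, termax - sum(S_d * d))`. Surviving helpers (`nh`) and
non-helpers (`nu`) compete with per-capita weights `exp(beta)` and 1:

```
g_u = min(1, x / (exp(beta) * nh + nu))
g_h = min(1, exp(beta) * x / (exp(beta) * nh + nu))
```

When neither cap binds, `g_h * nh + g_u * nu = x` exactly (vacancy
conservation) and `g_h / g_u = exp(beta)`; the caps apply independently.
The default `beta = -0.549` handicaps helpers per capita.

`fit_beta()` estimates `beta` from individual transition records
(stage, `x`, `nh`, `nu`, outcome) by maximising the Bernoulli
log-likelihood of the capped probabilities, with a Wald confidence
interval from the numerical Hessian. A grid pre-scan rejects records whose
likelihood is flat (e.g. all probabilities saturated), and boundary
solutions are reported as errors rather than estimates.

## One projection step

`project_step()` assembles, from the time-*t* state, the realized
projection matrix `K_t` and returns `n(t + 0.5) = K_t n(t)`:
survival and ageing within stage, promotion of subordinates into the
dominant class of their post-ageing age, and reproduction evaluated on the
*time-t* counts, with newborns entering the 0.5-year helper or non-helper
class according to `f` applied at the mother's age. `simulate()` iterates
this with kernel resampling, retains post-burn-in states, the mean realized
matrix and 20 chunk-mean matrices, and truncates (with a warning) if the
population goes numerically extinct.

## Fitness measures

**Cohort LRS** (`track_cohort()`): after one resident burn-in, each of
`n_cohorts` replicates continues the resident simulation with fresh
seasonal draws and projects a measure-zero unit cohort (helper or
non-helper, age 0.5) alongside it using the resident environment's
realized rates and lottery probabilities; expected offspring accrue each
census until the cohort mass is below tolerance. The spread across
cohorts reflects environmental stochasticity only; expected LRS per cohort
is strictly positive, never zero-inflated.

**Markov chains with rewards** (`reward_chain()`, `lrs_moments()`): in a
frozen environment the transition-only matrix `U` and the per-class
Bernoulli reproduction probabilities give closed-form moments of LRS via
the recursions

```
rho1 = (I - U')^{-1} p
rho2 = (I - U')^{-1} (p + 2 p o U' rho1)
rho3 = (I - U')^{-1} (p + 3 p o U' rho1 + 3 p o U' rho2)
```

using that all raw moments of a Bernoulli reward equal `p`.
`simulate_lifetimes()` is an independent Monte-Carlo cross-check and, at
the individual level, exhibits the zero inflation that expected-value
cohorts cannot.

**Reproductive values** (`reproductive_values()`): the dominant left
eigenvector of the mean realized matrix, normalised to the age-1 dominant
class, with interquartile bands across chunk-mean matrices.

## Perturbation analyses

**Retrospective** (`ltre_random_design()`): each post-burn-in step is a
random draw of the six intercepts with a recorded next-step population
size; a random forest regressed on the six channels attributes normalised
variance-reduction importance (percent) and reports the variance explained.
An analytic cross-check multiplies common-random-number finite-difference
sensitivities of the stationary mean by the channels' among-season standard
deviations and squares them. The two decompositions answer related but
different questions: the forest captures realized step-level response
(survival channels act with delay and interact with density), the analytic
version a local linearisation of the mean; agreement is expected in the
identity of dominant channels, not in exact percentages.

**Prospective** (`elasticity()`): the proportional response of the
stochastic mean population size,
`(log N(x(1 + delta)) - log N(x)) / log(1 + delta)`. Because logit-scale
intercepts can be negative, "proportional perturbation of the parameter"
is adopted as the definition (multiplicative on the intercept itself).
Perturbable channels are the six seasonal intercepts, the `p_help`
intercept, the helper-presence contrast `q` inside `R_d`, and `termax`.
Base and perturbed runs share the seasonal draw sequence (common random
numbers), which removes most Monte-Carlo noise from the difference.

## The individual-based model

`ibm_simulate()` replays the same rates with whole birds: Bernoulli
survival and reproduction per individual, help status drawn per dominant,
and an integer number of vacancies `round(termax) - (surviving dominants)`
filled by weighted sampling without replacement (helper weight
`exp(beta)`). Divergences from the density model are deliberate and
documented: vacancies are integers, the lottery is a without-replacement
draw rather than independent caps, and realized individual LRS is
zero-inflated and right-skewed. Lifetimes still open at the end of a run
are censored; summaries of "complete lifetimes" therefore under-represent
long successful dominant careers unless the horizon is generous.
`posterior_predictive_check()` wraps this into an ensemble of artificial
datasets with a fraction of subordinate stage labels masked
(`mask_status()`), mimicking missing behavioural classification.

## Synthetic generator and default calibration

`synthetic_kernel_spec()` draws per-season intercepts from a multivariate
normal with channel means, among-season sds and a cross-channel
correlation (default 0.3; good seasons are good for several rates at
once). By default helpers and non-helpers share one subordinate-survival
draw per season (`S_h` and `S_u` identical columns, still separately
perturbable).

The default calibration was chosen once, against the published scale of
the study system, and then frozen:

* capacity 111.2 held full at every census;
* about 50 helpers and 11–12 non-helpers at quasi-equilibrium
  (total population near 170, matching the standardisation mean);
* high adult dominant survival (about 0.84 per half-year at the
  population mean), with a late-life decline (cubic age term);
* most subordinates young (roughly two thirds of helper mass and three
  quarters of non-helper mass below 2 years), subordinate totals
  fluctuating over a several-fold range across seasons;
* among-season variance concentrated in dominant reproduction and
  survival.

What the generator does *not* emulate: temporal autocorrelation of
seasons, observation error, sex structure, territory quality
heterogeneity, and immigration/emigration (the island is treated as
closed).

## Numerical choices

* Horizons: stationary summaries in the examples use 3000–4000 steps with
  1000–1500 burn-in; tests use shorter runs chosen for speed. These sizes
  are package choices, not estimates of mixing times; doubling them moves
  headline quantities by well under a percent.
* Derived seeds are always taken below 2^31; every public stochastic
  function accepts a seed.
* The equilibrium solver is plain fixed-point iteration (the map is
  strongly contracting at the default calibration).
* Finite-difference sensitivities use a cube-root-of-epsilon step scaled
  by the parameter magnitude, under common random numbers.
* `fit_beta()` uses `stats::optimize` on a bounded interval with explicit
  flat-likelihood and boundary diagnostics rather than an unbounded
  quasi-Newton search.

## Interface decisions

The package follows the classic R modelling idiom: S3 model objects with
`print`, `summary`, `coef`, `confint`, `simulate` and `plot` methods, and
base-R internals. There is no command-line interface; the single
entry-point script (`scripts/acceptance.R`) exists to reproduce the
headline quantities as JSON and is a thin wrapper over exported functions.
File formats are plain text throughout: CSV for kernels and transition
records, YAML for configurations, JSON for results.

## Limitations

* The model is female-only and ignores within-territory group composition
  beyond "help received or not".
* Expected-value cohorts cannot express zero-inflated individual LRS; use
  the reward-chain simulator or the IBM for individual-level
  distributions.
* The random-forest LTRE attributes variance of the *next-step*
  population size; slow-acting channels are partly absorbed into density
  feedback and their importance is conservative.
* Elasticities are defined on logit-scale intercepts; comparisons across
  channels with very different intercept magnitudes should be interpreted
  with that scale in mind.
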