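---
title: "Modelling crash injury severity with a random-parameters logit with heterogeneity in means and variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crash injury severity with a random-parameters logit with heterogeneity in means and variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crashmixl)
library(dplyr)
```

## The modelling problem

Police-reported crash records classify the most severe injury in a crash on
the five-level KABCO scale (K fatal, A incapacitating, B evident, C
possible, O no injury).  Severity research typically collapses these to
three classes — severe injury (`SI` = K + A), minor injury (`MIN` = B + C)
and no injury (`NI` = O) — and models the class probabilities as a function
of crash attributes coded as 0/1 indicators (rollover, fatigue, rural
location, daylight, and so on).  A recurring question for large-truck
safety is whether the factors driving severity differ between trucks
licensed in the analysis state ("in-state") and trucks from elsewhere
("out-of-state"): `partition_residency()` builds exactly that split, and
`descriptive_table()` produces the count/percent cross-tabulations such
studies print.

## The model

Each severity class $k$ has a linear severity (utility) function for crash
$n$:

$$S_{kn} = \beta_k X_{kn} + \varepsilon_{kn},$$

with i.i.d. standard Gumbel (extreme value type I) errors, so that with
fixed coefficients the class probabilities are multinomial logit.  Every
explanatory indicator is *defined for* exactly one class: it enters only
that class's function.  One constant is estimated where declared (the
conventional layout for this model family puts it in the `NI` function; the reference
class is `NI`).

Coefficients need not be fixed.  A **random parameter** varies across
crashes with a mixing distribution, giving the mixed-logit probability

$$P_n(k) = \int \frac{e^{\beta_k X_{kn}}}{\sum_j e^{\beta_j X_{jn}}}
          f(\beta \mid \varphi)\, d\beta .$$

The package's central extension is **heterogeneity in the means and
variances** of the random parameters: for random coefficient $k$ of crash
$n$,

$$\beta_{kn} = \beta + \delta_k z_{kn}
             + \sigma_k \exp(\omega_k w_{kn})\, v_{kn},$$

where $z$ are observed attributes shifting the coefficient's mean with
loadings $\delta_k$, $w$ are attributes scaling its standard deviation
multiplicatively through $\exp(\omega_k w)$, and $v$ is a standard normal
disturbance (normal mixing is the default; lognormal, uniform and
triangular are available per term).  With all $\sigma_k = 0$ the model
degenerates exactly to plain multinomial logit — the test suite exploits
this as an oracle link.

## Estimation

The mixing integral has no closed form, so the likelihood is simulated:
per observation, the chosen-class probability is averaged over draws of
$v$, and the log of that average is summed.  Draws are **Halton
sequences** — deterministic low-discrepancy radical-inverse sequences in a
prime base — mapped to normals by the inverse CDF (`halton_cube()`).
Defaults and the reasoning behind them:

* **1000 draws per observation** (`n_draws`), the conventional count for
  accurate simulated estimation of this model class; studies of reduced
  scale in this package's own tests use 30–500 draws.
* **Primes in order** (2, 3, 5, …), one dimension per random coefficient.
  Plain Halton is well behaved at the 1–3 random dimensions typical here;
  a seeded digit-scrambling option exists for higher dimensions, off by
  default.
* **Discard 10** initial points per dimension, dropping the coarse,
  strongly patterned prefix of each sequence.
* **Per-observation blocks**: each observation receives its own contiguous,
  non-overlapping segment of the sequence, the standard arrangement for
  cross-sectional simulated likelihood.

`fit_mixed_logit()` maximises the simulated log-likelihood with BFGS.  The
gradient is the exact analytic score of the simulated objective (a
finite-difference cross-check is part of the test suite), computed
alongside the likelihood; draws are held fixed across evaluations (common
random numbers), so the objective the optimiser sees is smooth and
deterministic.  $\sigma_k$ is estimated unconstrained and interpreted
through its absolute value, avoiding boundary failures at $\sigma = 0$;
reports show the positive scale.  Standard errors invert the numerically
differenced Hessian at the optimum, falling back to the BHHH outer product
of per-observation scores when the Hessian is singular; when both fail the
standard errors are reported missing rather than fabricated.  Convergence
is reported with the iteration count and the gradient max-norm (threshold
`1e-4`), with an iteration cap of 500.

Numerical guards: softmax utilities are shifted by the row maximum before
exponentiation; a simulated probability that underflows to zero is floored
at `1e-300` with a warning.  The probability-location identity (adding a
common constant to all three utilities leaves the likelihood unchanged)
and the per-draw sum-to-one identity are enforced by tests.

## Fit statistics and post-estimation

* **Null log-likelihood** (`null_loglik()`): the headline convention is
  *equal shares*, $-N \ln 3$, which is the likelihood with every parameter
  zero; published three-class severity tables of this kind print exactly
  this quantity.  A *constants-only* mode, $N \sum_k s_k \ln s_k$ at the
  empirical shares, is also provided, and every fit stores both with a
  label saying which one the reported pseudo-$\rho^2$ used.
* **McFadden pseudo-**$\rho^2$ (`pseudo_r2()`): $1 - LL_{conv}/LL_0$.
* **Sign shares** (`share_sign()`): for a normally distributed random
  coefficient, $100\,\Phi(\pm\,\text{mean}/\text{sd})$ is the percentage
  of crashes with a positive (negative) coefficient — the standard way to
  summarise a random parameter whose mean and standard deviation imply
  both signs occur.
* **Marginal effects** (`marginal_effects()`): for indicator variables the
  effect on each class probability of flipping the indicator 0→1, other
  covariates held at observed values, averaged over the estimation sample
  (not evaluated at covariate means).  Random coefficients are collapsed
  to their estimated means.  Because the mean of $\beta_{kn}$ is
  observation-specific ($\beta + \delta_k z_{kn}$), the default respects
  the $\delta$ shift per observation; a strict grand-mean variant
  (`include_mean_shifters = FALSE`) is available and announces itself.
  Each row's three effects sum to zero by construction.  Display rounding
  is four decimals; raw values are what the functions return.
* **Transferability** (`lr_transferability()`): the likelihood-ratio test
  $LR = -2\,[LL(\beta_{all}) - LL(\beta_{g1}) - LL(\beta_{g2})]$ against
  the $\chi^2$ quantile with degrees of freedom equal to the summed
  separate-model parameters minus the pooled ones.  A negative statistic
  (possible under simulation noise when the pooled spec is not exactly
  nested) is reported as-is with a warning.
* **Significance screening**: the conventional retention rule for this
  literature — keep terms whose t-statistic reaches the 90% two-tailed
  level — is surfaced as a `significant_90` flag in `tidy()`, never as
  automatic stepwise removal.

## The synthetic-data generator

Crash databases of this kind are typically restricted, so the package
carries a first-class generator implementing the model's own
data-generating process: independent Bernoulli indicator covariates with
configurable prevalence (`generate_design()`), random coefficients
realised per the heterogeneity construction (`realize_coefficients()`),
and outcomes as the argmax of systematic utilities plus inverse-CDF Gumbel
draws (`simulate_outcomes()`, errors via $-\ln(-\ln u)$).  Ground truth,
the seed, the realised coefficient draws and the realised utilities travel
with the dataset, so recovery tests can interrogate every layer.

`preset_scenario()` fixes a reference configuration chosen once to mirror
the scale of a five-year statewide large-truck extract: about 7000
records; indicator prevalences between 0.015 and 0.55 (the range spanned
by fatigue-type rare factors up to daylight-type common ones); one
normally distributed random coefficient (rural, defined for severe
injury, mean −1.01, sd 2.21) with one mean-shifter (interstate) and one
variance-shifter (collision with a tree); and fixed coefficients of
magnitude 0.5–2.  z- and w-attributes are drawn from the same indicator
pool as the utility covariates, matching how such models are specified in
practice.

What the generator does **not** emulate: correlations among indicators
(real contributing-factor categories are near-mutually-exclusive; the
generator treats indicators as independent, with one-hot structure left to
the scenario author), year-over-year drift, and reporting error in the
KABCO codes.  Passing recovery tests therefore demonstrate that the
estimator inverts its own data-generating process at realistic scale —
not that any particular field dataset satisfies the model's assumptions.

## Design choices made where the design was open

* **Equal-shares null as default.**  The constants-only convention is
  arguably the better-grounded baseline, but the equal-shares value is
  what tables in this literature print as "log-likelihood at zero", and a
  default should reproduce what practitioners expect to see; both are
  always computed and labelled.
* **Analytic scores rather than finite differences.**  The score of the
  simulated objective is available in closed form at negligible extra
  cost per evaluation; finite differences would multiply estimation cost
  by roughly twice the parameter count and add step-size error.
* **Records are quarantined, never dropped.**  Loaders route rows with
  invalid severity codes or out-of-vocabulary levels to a reported
  quarantine attribute, because silent filtering is the commonest source
  of irreproducible Ns in crash studies.
* **Weak identification is acknowledged.**  The mean and standard
  deviation of a random coefficient on a moderately prevalent indicator
  are only weakly identified in a cross-section of a few thousand
  records: individual fits can land far from the truth while attaining a
  higher simulated likelihood.  The package's quality claims are
  therefore phrased as likelihood dominance and as error that shrinks
  with sample size (the test suite runs a 20-seed study at n = 1000,
  2500 and 5000 with 100 draws), not as per-fit closeness.

## Problem sizes used by the checks

The bundled tests and the reproduction script deliberately run at reduced
scale chosen to exercise every code path at statistically meaningful
sizes: single fits at n ≤ 4000 with up to 500 draws, the recovery study
at 100 draws, size/power studies of the transferability test with 20–30
replications of two 600–800-record groups, and oracle comparisons at
n ≤ 200 where brute-force evaluation is exact.

## Worked example

```{r example, eval = FALSE}
sc <- preset_scenario(n = 4000, seed = 42)
crashes <- simulate_scenario(sc, kabco = TRUE)

descriptive_table(crashes, "rural")

spec <- as_ml_spec(sc$truth, n_draws = 200)
fit <- fit_mixed_logit(crashes, spec)
glance(fit)
tidy(fit)
share_sign(tidy(fit)$estimate[6], tidy(fit)$estimate[8], "positive")
marginal_effects(fit)
autoplot(fit)
```

## Known limitations

No panel (repeated-crash) correlation structure, no correlated random
parameters, no nested or latent-class variants, no ordered-response
models, and no Bayesian estimation.  Marginal effects cover indicator
variables only, which is all this model family uses.
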