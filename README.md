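# crashmixl

Crash injury severity analysis with a random-parameters (mixed)
multinomial logit whose random coefficients carry **heterogeneity in both
their means and their variances**, estimated by simulated maximum
likelihood with Halton draws.

The package is written for road-safety analysts working with
police-reported crash records: crashes classified on the KABCO injury
scale, explanatory variables coded as 0/1 indicators, and a three-class
outcome — severe injury (`SI` = K + A), minor injury (`MIN` = B + C), no
injury (`NI` = O).  A typical study question it supports end-to-end:
*do the factors driving large-truck crash severity differ between
in-state and out-of-state drivers?*

## The model

Each severity class `k` has a severity function for crash `n`

    S_kn = beta_k' X_kn + eps_kn,      eps ~ i.i.d. Gumbel (EV type I)

so class probabilities are multinomial logit, mixed over random
coefficients

    P_n(k) = ∫ softmax_k(beta' X_n) f(beta | phi) d beta.

A random coefficient varies across crashes as

    beta_kn = beta + delta_k' z_kn + sigma_k * exp(omega_k' w_kn) * v_kn

with observed mean-shifters `z`, variance-shifters `w`, and standard
normal `v` (lognormal / uniform / triangular mixing optional).  The
likelihood is simulated with Halton quasi-random draws (1000 per
observation by default) and maximised by BFGS with exact analytic
scores.  Post-estimation: average discrete-change marginal effects,
McFadden pseudo-R², normal sign shares `100*Phi(±mean/sd)`, and the
likelihood-ratio transferability test
`LR = -2[LL_pooled - LL_group1 - LL_group2]` against a chi-square
critical value.

Because crash databases of this kind are usually restricted, the package
includes a first-class synthetic-data generator implementing exactly this
data-generating process with stored ground truth, used by the test suite
for parameter-recovery and size/power studies.

## Worked example

```r
library(crashmixl)

sc      <- preset_scenario(n = 4000, seed = 42)   # known ground truth
crashes <- simulate_scenario(sc, kabco = TRUE)

descriptive_table(crashes, "rural")
#>   variable level  n_SI pct_SI n_MIN pct_MIN  n_NI pct_NI n_total
#> 1 rural    0       243   11.1   282    12.8  1671   76.1    2196
#> 2 rural    1       196   10.9   241    13.4  1367   75.8    1804

spec <- as_ml_spec(sc$truth, n_draws = 200)
fit  <- fit_mixed_logit(crashes, spec)
glance(fit)
#>   n_obs n_parameters n_draws logLik null_logLik null_mode    pseudo_r_squared converged
#> 1  4000            9     200 -2775.      -4394. equal_shares            0.369 TRUE

tidy(fit)
#>   term                   role     estimate std.error statistic significant_90
#> 1 const:NI               constant    1.94     0.0498     39.0  TRUE
#> 2 SI:rollover            fixed       1.24     0.145       8.61 TRUE
#> 3 SI:daylight            fixed      -0.778    0.116      -6.71 TRUE
#> 4 MIN:fatigue            fixed       0.551    0.264       2.08 TRUE
#> 5 NI:rear_end            fixed      -0.709    0.0921     -7.70 TRUE
#> 6 mean:rural             mean       -1.13     0.693      -1.64 FALSE
#> 7 delta:rural:interstate delta      -0.339    0.285      -1.19 FALSE
#> 8 sigma:rural            sigma       2.02     0.745       2.71 TRUE
#> 9 omega:rural:tree       omega       0.954    0.460       2.07 TRUE
```

The generating values were constant 2.0, rollover 1.33, daylight −0.86,
fatigue 0.52, rear-end −0.71, and a random rural coefficient with mean
−1.01, sd 2.21, interstate mean-shift −0.57 and tree variance-loading
0.63 — each recovered within sampling error.  The fitted random
coefficient implies the rural indicator *increases* severe-injury
propensity for a minority of crashes:

```r
share_sign(-1.13, 2.02, "positive")
#>    mean    sd sign     share_pct share_pct_rounded
#> 1 -1.13  2.02 positive      28.7              28.7

marginal_effects(fit)
#>   variable defined_for    me_SI   me_MIN   me_NI
#> 1 rollover SI           0.117   -0.0178  -0.0988
#> 2 daylight SI          -0.0535   0.00821  0.0453
#> 3 fatigue  MIN         -0.00692  0.0758  -0.0688
#> 4 rear_end NI           0.0455   0.0836  -0.129
#> 5 rural    SI          -0.0740   0.0115   0.0625
```

Marginal-effect rows sum to zero: flipping one indicator reallocates
probability among the three classes.  `autoplot(fit)` and
`autoplot(marginal_effects(fit))` give the standard coefficient and
effect charts; `partition_residency()` + `run_fit_report()` run the full
two-group comparison with the transferability test.

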