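# antddm

Hierarchical Bayesian drift-diffusion modelling of the Attention Network
Task (ANT), for researchers studying attention and perceptual
decision-making in clinical cohorts — in particular the dissociation
between *evidence accumulation* (drift rate) and *response caution*
(decision boundary) across dementia groups, and how trial-by-trial brain
network activity relates to drift rate.

## The model

Two-choice decisions are modelled as a Wiener diffusion: evidence
accumulates at mean rate *v* (drift) from an unbiased starting point
between absorbing boundaries separated by *a*, and the response time is
the first-passage time plus a non-decision time *t₀* (diffusion scale
*s* = 1, accuracy coding, 5% uniform contaminants). Subject parameters are
shrunk toward clinical-group hyper-distributions, condition effects enter
with treatment coding against the congruent baseline,

v(s,k) = v(s) + b₁·Condition(k)  a(s,k) = a(s) + b₂·Condition(k)

and z-scored single-trial network beta series can enter the drift
equation with group-level-only regression coefficients,

v(s,k) = v(s) + b₁·Condition(k) + b₂·BetaSeries(s,k).

Estimation is multi-chain adaptive Metropolis-within-Gibbs over the exact
Wiener first-passage likelihood (small-time/large-time series expansions,
C++). Model variants (drift-varying, boundary-varying, both) are compared
by DIC; fits are checked with posterior predictive simulation; group
contrasts use posterior-overlap tail mass (*P* < 5% ⇒ credible
difference) and covariate couplings the percentage of posterior mass on
one side of zero (*P* > 95% ⇒ credible effect).

The package also ships the surrounding study machinery: an ANT-schedule
and clinical-cohort simulator (the generating configuration reproduces
the qualitative Control/AD/LBD ordering), a network-BOLD run synthesizer,
single-trial beta-series GLM estimation with motion/DVARS QC, and
inclusion filters (5–6 runs, ≥ 70% correct, ≤ 10% missed responses).

## Worked example

```r
library(antddm)

# simulate a small two-group cohort on the real task schedule
cohort <- generate_cohort(default_group_specs()[c("Control", "LBD")],
                          n_subjects_per_group = 4,
                          schedule_config(n_runs = 5), seed = 42,
                          dt = 1e-3)
kept <- run_inclusion_filters(cohort$trials)

# fit the full model (drift and boundary condition-dependent)
model <- build_model(ddm_model_spec(varies = c("v", "a")), kept$trials)
fit <- sample_posterior(model, mcmc_config(n_samples = 5000,
                                           n_burn_in = 2000, seed = 1))
glance(fit)
#> # A tibble: 1 x 7
#>   n_chains n_draws n_parameters n_subjects n_trials max_rhat runtime_s
#>      <int>   <int>        <int>      <int>    <int>    <dbl>     <dbl>
#> 1        2    3000           44          8     1438     1.07      42.2

subset(tidy(fit), grepl("mu_v", term))
#> # A tibble: 2 x 8
#>   term          estimate std.error conf.low conf.high  rhat flagged degenerate
#>   <chr>            <dbl>     <dbl>    <dbl>     <dbl> <dbl> <lgl>   <lgl>
#> 1 mu_v[Control]     2.84     0.285     2.28      3.41  1.02 FALSE   FALSE
#> 2 mu_v[LBD]         1.64     0.338     0.98      2.33  1.00 FALSE   FALSE
```

The group-mean congruent drift rates (`mu_v`, evidence units/s at
diffusion scale 1) recover the generating values (Control 2.8, LBD 1.6);
`max_rhat < 1.1` indicates converged chains. Group contrasts and
condition effects:

```r
cp <- reconstruct_condition_posteriors(fit)
ov <- condition_overlap_matrix(cp, seed = 1)
subset(ov, parameter == "v" & condition == "congruent")
#> # A tibble: 1 x 6
#>   parameter condition group_a group_b     P significant
#>   <chr>     <chr>     <chr>   <chr>   <dbl> <lgl>
#> 1 v         congruent Control LBD     0.867 TRUE
```

`P` is the posterior-overlap percentage: 0.87% of the paired posterior
difference mass opposes the dominant direction, a credible drift-rate
reduction in the LBD-like group. `autoplot(fit)` draws the per-condition
posterior densities by group; `posterior_predictive(fit)` checks the fit
against the observed accuracy and RT quantiles.

The full study replica — three model variants, DIC table, predictive
checks, overlap matrix, covariate regression — is one call:
`run_study(pipeline_config(...))`.

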