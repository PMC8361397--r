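---
title: "Hierarchical drift-diffusion modelling of a conflict attention task: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical drift-diffusion modelling of a conflict attention task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The decision model

`antddm` analyses two-choice conflict tasks (a flanker-style Attention
Network Task with congruent, incongruent-EASY and incongruent-HARD trials)
with the drift-diffusion model. Evidence $x(t)$ accumulates as a Wiener
process with drift $v$ from a starting point $z = z_{\mathrm{rel}} \cdot a$
between absorbing boundaries $0$ and $a$; absorption at $a$ is the correct
response (accuracy coding), and the observed response time is the
first-passage time plus a non-decision time $t_0$ covering stimulus
encoding and motor output.

**Diffusion-scale convention.** The diffusion coefficient is fixed at
$s = 1$, the convention of the hierarchical-Bayesian toolbox lineage this
package follows. Parameter magnitudes are *not* comparable to values
reported under the alternative $s = 0.1$ convention (they differ by a
factor of 10). A self-similarity test (`f(t/c^2; cv, a/c) = c^2 f(t; v,a)`)
guards against accidental convention changes.

**Accuracy coding and the unbiased start.** Left/right responses are
assumed counterbalanced, so the starting point is fixed at
$z_{\mathrm{rel}} = 0.5$ and boundaries are coded correct/error. Stimulus
coding is deliberately not implemented.

**Contaminants.** A fraction `p_outlier` (default 0.05) of responses is
modelled as uniform on $(0, \texttt{rt\_max})$ with a fair coin for the
choice. `rt_max` defaults to the 3 s response window of the task. Both
values are configuration, not estimates: the mixture makes the likelihood
finite for any positive response time, which the samplers rely on.

**Density evaluation.** The first-passage density is computed from the
small-time and large-time series expansions of the Wiener first-passage
distribution, choosing per evaluation whichever series needs fewer terms
for a truncation error below `eps` (default $10^{-6}$, assessed on the
normalized-time density). Both expansions are implemented in C++; the
defective densities integrate to 1 within $10^{-4}$ across the tested
parameter grid.

**Trial simulation.** The reference sampler integrates the evidence path
by Euler–Maruyama steps (`dt = 1e-4` s by default) with a Brownian-bridge
crossing correction: between consecutive states at distances $d_0, d_1$
from a barrier, the bridge crosses with probability
$\exp(-2 d_0 d_1 / \mathrm{d}t)$. The naive scheme overestimates passage
times by $O(\sqrt{\mathrm{d}t})$ — enough to be detected against the
closed forms at $10^5$ trials — while the corrected scheme agrees with the
closed-form absorption probability and mean decision time within Monte
Carlo error. Posterior predictive simulation uses `dt = 1e-3` by default;
at that resolution the residual bias is far below the width of the
predictive intervals it feeds.

# The hierarchical model

For subject $s$ in clinical group $g$ on trial $k$:

$$v_{s,k} = v_s + b^{(v)}_{g,\mathrm{cond}(k)} + \textstyle\sum_j
\beta^{(j)}_{g}\, x^{(j)}_{s,k}, \qquad
a_{s,k} = a_s + b^{(a)}_{g,\mathrm{cond}(k)},$$

with treatment coding against the congruent baseline (two indicator
coefficients per varying parameter per group), non-decision time constant
across conditions, and trial-wise covariates $x^{(j)}$ (z-scored network
beta series) entering drift with **group-level-only** coefficients — one
per group, shared across that group's subjects, which sidesteps the
collinearity a subject-level coefficient would introduce. Subject
baselines $v_s, a_s, t_{0,s}$ are drawn from group-specific normal
hyper-distributions, giving each clinical group its own location and scale
so group posteriors can be compared directly.

The three model variants of interest are: (1) drift varies by condition,
boundary constant; (2) boundary varies, drift constant; (3) both vary.

**Priors** (the study's source material does not state priors; these are
weakly informative defaults in the toolbox tradition, all configurable):
group-mean drift $\mathcal N(2, 3^2)$; group-mean boundary
$\mathcal N(1.5, 1^2)$ truncated to $(0.3, 4)$; group-mean non-decision
time $\mathcal N(0.3, 0.25^2)$ truncated to $(0.05, 1)$; between-subject
SDs half-normal(1); condition effects $\mathcal N(0, 2^2)$; covariate
coefficients $\mathcal N(0, 1)$.

**Sampler.** Adaptive Metropolis-within-Gibbs. Group means are updated by
exact conjugate (truncated-)normal Gibbs draws given the subject values;
all other parameters use random-walk Metropolis (log-scale for SDs, with
two SD passes per sweep since they cost no likelihood evaluations and mix
slowest). Proposal scales adapt in batches toward an acceptance rate of
0.25–0.45 during burn-in and are frozen afterwards, so retained draws come
from a fixed kernel. Chains start from data-informed, overdispersed
initializations (jittered logit-accuracy drift, boundary near 1.5,
non-decision time near half the fastest response). At least two chains are
required; convergence is monitored with the split-chain Gelman–Rubin
statistic, flagged at $\hat R \ge 1.1$.

**Presets.** The desk-scale default is 5 000 iterations with 2 000
burn-in and 2 chains, which fits a 45-subject cohort in minutes. The
published-study preset (95 000 samples, 35 000 burn-in, thinning 5) is
available as `study_mcmc_config()`. The recovery experiments in the
acceptance suite retain 5 000 draws after a 2 000-iteration burn-in
(7 000 total), reading "5 000 draws" as retained draws in the
`sample(N, burn)` convention of the toolbox lineage.

# Model evaluation

**DIC.** $\mathrm{DIC} = \bar D + p_D$ with $\bar D$ the posterior mean
deviance and $p_D = \bar D - D(\bar\theta)$. $\bar\theta$ is the
per-parameter posterior mean on the sampling scale — $p_D$ is
parameterization-dependent and this choice is deliberate and documented.

**Posterior predictive checks** simulate full replicate datasets on the
observed design for 500 posterior draws (configurable) and compare
accuracy and the 10/30/50/70/90% RT quantiles per group and condition,
locating each observed statistic by percentile rank. The fixed summary
set is a concrete rendering of "key patterns of the data".

**Posterior overlap.** Group contrasts use the paired-difference tail
mass: $P = 100\min\{\Pr(\Delta > 0), \Pr(\Delta < 0)\}$ over paired draw
streams, flagged at $P < 5$. The phrase "percentage of overlap" could also
mean the density overlapping coefficient; both are implemented
(`method = "tail"` and `"density"`), tail mass — the toolbox-community
convention — being the default used everywhere.

**Probability of non-zero.** For covariate coefficients,
$P = 100\max\{\Pr(\beta > 0), \Pr(\beta < 0)\}$ with the dominant sign,
flagged at $P > 95$.

# The synthetic-cohort generator

The generator is first-class, tested code: it defines the study
conditions under which every pipeline property is assessed.

**Task schedule.** 36 trials per run, 5 or 6 runs (180/216 trials), a
200 ms cue, twelve cue–target delays (0.700–3.200 s) and twelve
target–cue delays (4.300–8.300 s) each used exactly three times per run in
random order, a 3 s response window, and an equal 12/12/12 condition split
(the split is not stated in the source protocol; equal is assumed). A run's
events always fit the 156-volume, TR 1.92 s acquisition.

**Groups.** Three clinical groups with invented generating values chosen
once to reproduce the qualitative clinical pattern — Control drift
(2.8, 2.2, 2.0) across (congruent, EASY, HARD), AD (2.0, 1.5, 1.3), LBD
(1.6, 1.1, 0.9); boundaries 2.0 (Control) vs 1.5 (patients); non-decision
times 0.35/0.45/0.55 s; between-subject SDs 0.3/0.2/0.05; dorsal-attention
coupling +0.3 everywhere, default-network coupling +0.1/+0.05/−0.2.
Subject baselines are normal (positively truncated for boundary and
non-decision time); condition effects are group-level, matching the fitted
model. Trials slower than the response window become censored records so
the inclusion filters (≥ 70% correct, ≤ 10% missed, 5–6 runs; both
boundaries retained at equality, applied overall rather than per run) have
something to act on.

For model-selection studies the default boundaries are condition-invariant
and would make the boundary-varying variants unidentifiable improvements;
`model_selection_group_specs()` therefore adds boundary condition effects
of −0.25/−0.50, a magnitude comfortably detectable at 108 trials per
subject.

**What the generator does not emulate:** sequential dependencies between
trials (post-error slowing, fatigue, fluctuations), within-subject
condition-effect variability, non-uniform contaminants, and any real
coupling structure between the two network covariates (they are generated
independently). Passing recovery tests therefore show the pipeline is
self-consistent under its own assumptions — not that those assumptions
hold in patient data.

**BOLD runs.** Network-averaged series at TR 1.92 s, 156 volumes: stick
events at target onset scaled by per-trial amplitudes (percent signal
change) through a double-gamma canonical HRF (peak ≈ 5 s, undershoot
≈ 15 s, unit peak), slow cosine drift (periods ≥ 200 s), a random-walk
six-parameter motion series leaking linearly into the signal, and AR(1)
noise (SD 0.4% signal, lag correlation 0.3 by default — conservative for
a time course averaged over many voxels). The single-trial
GLM uses one regressor per trial, the six motion parameters, an intercept,
and a discrete-cosine high-pass basis with
$\lfloor 2L/128\,\mathrm{s}\rfloor$ columns ($L$ the run length; 4 columns
for a 299.52 s run). Events are modelled as zero-duration sticks because
trial durations vary with the response and the protocol does not state
duration modelling. Percent-signal scaling divides by the run mean by
default (the practical choice when the baseline is unknown; exact
recovery holds when the true baseline is supplied). AR(1) prewhitening
(single pooled lag from OLS residuals) is available but off by default.
Beta series are z-scored per subject across all runs before entering the
drift regression.

**QC.** Frame-to-frame motion summaries pool the absolute first
differences of the translation (mm) and rotation (degree) columns. DVARS
is the per-transition RMS over voxels of the temporal derivative; the
standardized variant divides by a half-IQR-based robust estimate of the
frame-difference SD, so stationary noise averages ≈ 1 and the statistic is
scale-invariant. The exact standardization of the script the study cites
is not public; this documented approximation is used instead.

# Numerical and design choices, in brief

- **Degenerate inputs:** zero-variance beta series raise an error on
  z-scoring; rank-deficient GLM designs fall back to a ridge solve with a
  warning; zero within-chain variance reports $\hat R$ as degenerate
  rather than dividing by zero; non-finite deviance draws are counted and
  excluded from DIC with a warning.
- **Determinism:** every stochastic function takes a seed; the pipeline
  derives per-stage seeds from one master seed and stamps reports with a
  configuration hash, so identical configurations give identical reports.
- **Problem sizes.** The recovery experiment uses the full study-shaped
  cohort (3 groups × 15 subjects × 216 trials; 5 000 retained draws × 2
  chains). Model-selection replicates are run at the reduced size of
  5 subjects/group × 108 trials with 3 replicates; the covariate-recovery
  experiment uses one group of 15 subjects × 216 trials. These sizes are
  the package's documented experiment definitions.
- **Recovery metrics.** With 15 subjects per group and a between-subject
  drift SD of 0.3, the group-mean drift estimate carries irreducible
  subject-sampling noise of about 0.08 per cell; recovery bias is
  therefore assessed as the mean absolute error over the nine
  group × condition cells (alongside 95% interval coverage of the
  generating values), not as a per-cell maximum, which would mostly
  measure cohort luck.

# Known limitations

- Inter-trial variability parameters of the full Ratcliff model
  ($s_v, s_t, s_z$) are intentionally absent — the modelled study used
  none.
- The sampler is random-walk based; it is validated by conjugate oracles
  and recovery tests, but posteriors for strongly correlated
  scale parameters mix more slowly than a gradient-based sampler would.
- The response-window censoring in the generator is not modelled in the
  likelihood (missed trials are excluded, as in the study); with slow
  parameter regimes this induces a small selection bias that is visible in
  recovery experiments and discussed in the test suite.
- Group contrasts at the default cohort size separate clearly for
  patient-vs-control comparisons; the LBD-vs-AD drift gap (0.4) is close
  enough to the cohort-level sampling noise that an unlucky cohort draw
  can push individual condition contrasts above the $P < 5$ line.
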