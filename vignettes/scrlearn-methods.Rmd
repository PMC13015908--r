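---
title: "Methods: trial-level SCR modelling in Pavlovian threat conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-level SCR modelling in Pavlovian threat conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
**scrlearn**: what each component assumes, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The experimental design being modelled

A cued Pavlovian threat-conditioning session with a within-participant
active/sham stimulation factor. Four visual cues form two pairs, each with
one threat cue (CS+) and one safety cue (CS−); one pair is presented under
active stimulation, the other under sham. The session has five phases:
threat acquisition (120 cue trials), a 4-trial retention probe, extinction
training (40 trials), three unsignaled reinstatement shocks followed by a
4-trial recovery probe, and re-extinction (40 trials). During acquisition
each CS+ is reinforced by the shock (US) on exactly 50% of its
presentations; the CS− is never reinforced, and no cue trial after
acquisition carries a US. Trials run in four-trial blocks holding a single
pair (two CS+, two CS− in randomized order), with never more than two
consecutive blocks of the same pair; intertrial intervals are jittered in
8–10 s, interblock intervals in 19–21 s. The four cue identities are
rotated over participants through a 4-cycle Latin square
(`counterbalance_code`), so each identity serves each role equally often
across participants.

`generate_schedule()` constructs such sequences by randomized backtracking
over the pair-block sequence (which always terminates, unlike plain
rejection sampling) and enforces two further choices that the design
leaves open: the reinforced CS+ presentations are placed under the global
exact-50% constraint with at most three consecutive reinforced
presentations per cue (avoiding degenerate streaks while keeping placement
otherwise uniform), and the retention/recovery probes are represented as
two adjacent two-trial mini-blocks, one per pair, covering each cue
identity exactly once. `validate_schedule()` re-checks every constraint
and reports failures rather than raising.

## The observation model and its three hierarchical variants

Each cue carries an expected shock value `EV` in [0, 1], updated per trial
by the Rescorla-Wagner rule `EV <- EV + LR * (US - EV)`. Observed
square-root transformed SCR amplitudes are Gaussian around a linear
function of the pre-update EV, with separate intercept and slope for
unreinforced (CR) and reinforced (CR+UR) trials and a participant-specific
residual SD. Predicted amplitudes are kept non-negative through a *soft*
constraint: a penalty `-kappa * min(0, mean)^2` on the log density
(`kappa = 10` by default). A quadratic penalty preserves gradient
smoothness, which matters for the sampler; hard truncation of the
likelihood would not.

The three variants differ only in which trials they see and how the
learning rate is built:

* **acquisition**: acquisition trials; per-participant `lr`; initial EV 0
  for both cues (participants receive no contingency instructions, so zero
  prior shock expectancy; configurable).
* **extinction**: extinction trials (all US = 0, so the prediction error
  is simply −EV); per-participant `lr`; initial EVs per cue imported from
  the last acquisition trial (`seed_extinction_evs()`, identity mapping;
  when seeding from a fit, the posterior-mean terminal EV, equal to the
  mean of per-draw terminal EVs). Because there are no reinforced trials,
  the CR+UR branch is dropped from this variant's parameter set.
* **emotional learning state**: acquisition and extinction jointly, with
  `LR = lr_shared * (1 + phase * bias)`, `phase = +1` during acquisition
  and −1 during extinction. The effective rate is centered on `lr_shared`
  and modulated symmetrically across phases; with `|bias| < 1` and
  `lr_shared <= 0.5` it cannot leave [0, 1], and it is clipped (with zero
  gradient) otherwise. EV carries over from the end of acquisition into
  extinction within each cue stream, so the seeding is implicit.

Hierarchy: group means are standard normal, group SDs half-Cauchy(0, 1)
(the positive half — SDs must be positive, and this is the universal
reading of that prior), and individual parameters are non-centered:
`theta_i = mu + sd * z_i` with standard-normal `z_i`. Link functions keep
individual parameters admissible for any real-valued draw: inverse-logit
for learning rates, `tanh` for the state bias, `exp` for the residual SD,
identity for the observation coefficients. Observation parameters are
re-estimated per fit in the separate acquisition and extinction models and
shared across phases within the emotional-state model. Individual point
estimates for group contrasts are posterior means; group contrasts default
to the pooled-variance two-sample t test (degrees of freedom
n1 + n2 − 2), with Welch available.

## Sampling and convergence

Posteriors are explored with Hamiltonian Monte Carlo using exact analytic
gradients: the RW recursion admits a cheap forward sensitivity recursion
(`dEV/dLR`), so each leapfrog step costs one pass over the data. Warmup
uses dual-averaging step-size adaptation toward a 0.95 acceptance target
and two diagonal mass-matrix updates (at 45% and 90% of warmup, from the
draws since the previous update, regularized toward unit scale); the
trajectory length is `t_sim / step size` leapfrog steps (default
`t_sim = 6`, capped at 192) with mild random jitter to avoid periodicity.
Divergent trajectories (energy error > 1000 or non-finite density) are
rejected and counted. These defaults were chosen for reliable mixing of
the non-centered hierarchy at short warmup; they are exposed in
`sampler_config()`.

Two profiles mirror common practice: `"full"` (4 chains, 200 warmup, 1800
post-warmup iterations per chain) and `"test"` (2 chains, 200/400) for
simulation studies and the test suite. Both are gated by the same rule:
split-chain potential scale reduction factor (split-Rhat) below 1.1 for
every parameter; `fit_*` warns whenever the maximum exceeds it, and
degenerate inputs (constant amplitudes) are flagged rather than silently
fit. Zero-variance chains make split-Rhat undefined; `split_rhat()`
returns `NA` with a warning in that case.

## The synthetic-data generator

`simulate_experiment()` / `simulate_cohort()` draw participant parameters
from the same hierarchical links the models use and run the generative
model forward over a fresh schedule per participant (counterbalance
rotated, independent randomization). Amplitudes are drawn on the sqrt-μS
scale and hard-truncated at zero — measured trough-to-peak amplitudes are
non-negative by construction — and the μS amplitude is the square.

Choices worth knowing:

* **Learning-rate coupling.** By default per-phase rates derive from the
  emotional-state mechanism: `lr_acq = lr_shared (1 + bias)`,
  `lr_ext = lr_shared (1 - bias)`. The `"control"` arm has a positive bias
  (0.4 on the tanh scale: fast learning, slow forgetting); the
  `"amygdala"` arm has the bias removed, emulating stimulation that slows
  acquisition and speeds extinction. Set `couple_rates = FALSE` to draw
  the two rates independently.
* **Observation scale.** Defaults (`a_cr = 0.35`, `b_cr = 0.5`,
  `a_crur = 0.7`, `b_crur = 0.5`, `sigma = 0.15`, all sqrt-μS) describe
  robustly conditioned responders: baseline CR ≈ 0.12 μS, asymptotic
  differential ≈ 0.5 μS, reinforced responses ≈ 1 μS. At this scale the
  zero-truncation bound binds on ~1% of trials, keeping the generator in
  the observation model's well-specified regime — deliberate, because the
  recovery and calibration studies are meant to probe estimation, not
  robustness to truncation, and conditioning studies routinely exclude
  participants who fail to show differential responding. Heavier-tailed,
  nonresponse-rich cohorts can be emulated by lowering the intercepts.
* **Probe trials.** The retention and recovery probes (one unreinforced
  presentation per cue) are generated as read-outs of the current
  association *without* an RW update. This makes the generative process
  exactly conjugate to the phase models — extinction is seeded by the
  final acquisition EV, and the joint emotional-state likelihood matches
  the simulated process — at the cost of ignoring the negligible learning
  carried by a single unreinforced presentation.
* **Reinstatement.** The three unsignaled shocks carry no cue, receive no
  amplitude, and do not perturb cue EVs; reinstatement-induced recovery of
  responding is not part of the learning model and is not emulated.
* **Raw traces.** `synthesize_trace()` builds 500-Hz electrodermal traces
  as a tonic baseline plus difference-of-exponentials responses (rise
  0.75 s, decay 2 s, unit-normalized peak) scaled to exact trough-to-peak
  amplitudes, plus optional Gaussian noise. Any smooth unimodal kernel
  would do — the scorer is shape-agnostic. Kernels are truncated at the
  point where they fall to 1e−8 of peak and shifted so the support edge is
  continuous (an abrupt edge would plant artifactual micro-deflections).
  Overlapping responses (onsets closer than the ~2%-of-peak decay time)
  are an error because the scorer assumes the first response in its window
  is isolated.

What the generator does **not** emulate: physiological EDA detail
(sudomotor dynamics, tonic drift, habituation of the UR), response-latency
variability, movement artifacts, nonstationary noise, or trial-order
effects beyond the RW process. Passing recovery tests therefore
demonstrates the estimators work when their assumptions hold approximately
— not that real electrodermal data satisfy those assumptions.

## SCR scoring

Trough-to-peak scoring with the standard rules: only the first response
whose *onset* (the trough: a local minimum followed by a strictly
increasing run) falls 1.0–4.0 s after CS onset; ascent from trough to peak
at most 5.0 s; amplitudes below 0.01 μS are nonresponses. The window is
applied to the response onset — so a peak may legitimately fall after the
window — because the amplitude/ascent/window rule set comes from scoring
conventions that window the initial deflection; this reading is flagged
for sensitivity analysis since the alternative (windowing the peak) is not
excluded by the rules themselves. Nonresponses are recorded as amplitude 0
and retained downstream, the dominant field convention, which keeps trial
counts balanced. The transformed score is the square root of the raw
amplitude. Scoring is offset-free and scale-equivariant by construction;
no smoothing is applied before detection (a moving average can be added
upstream if needed). Deflections smaller than 1e−12 μS are discarded as
floating-point dust.

## Permutation inference

Trial series (participants × trials) of differential sqrt-SCR are tested
nonparametrically: within-participant contrasts by sign-flipping each
participant's series (exact under exchangeability of the paired contrast;
exhaustive enumeration available up to 2^20 flips), between-group
contrasts by label permutation. Per permutation the per-trial t series is
enhanced by 1-D threshold-free cluster enhancement,
`score[i] = Σ_h extent(i,h)^E h^H dh`, with defaults `E = 1` (extent in
1-D is a run length) and `H = 2` (standard TFCE practice); `dh` defaults
to 1/100 of the maximum absolute statistic, and the max score per
permutation forms the family-wise-error null. One-sided tests enhance the
positive part only; two-sided tests enhance each sign separately.
P-values use the add-one estimator `(1 + #{null ≥ obs}) / (n_perm + 1)`,
so they are floored at `1/(n_perm + 1)` and never zero. A cluster-mass
variant forms clusters where |t| exceeds the 90th percentile of the pooled
permutation |t| distribution and compares the summed |t| per cluster to
the max-mass null. Safety-cue series are averaged over adjacent trial
pairs *before* series construction whenever the threat series consists of
the unreinforced trials only, so both series have equal length.

## Summaries

Time bins are equal contiguous splits of a phase's unreinforced-trial
sequence — early/mid/late thirds for acquisition, early/late halves for
extinction and re-extinction (boundaries unstated in common practice;
configurable, flagged for sensitivity). Paired contrasts report
`t = mean(d) / (sd(d)/√n)`, df `n−1`, two-sided p, and Cohen's d. The SCR
similarity index computes, per participant, Pearson correlations over
lagged trial pairs within the same CS+ stream — reinforced trial t0 to the
next unreinforced presentation (UR-CR) and t+1 to t+2 (CR-CR) — pooling
triplets across that participant's CS+ streams, since value updating is
cue-specific; participants with fewer than three triplets are flagged
missing. Group comparison of similarity indices uses a two-sample test
(participants are not matched across experiments; a paired option exists
for matched designs). Ratings contrasts use two-tailed paired t tests on
threat>safety differentials (active vs. sham) and chi-square tests of
independence for categorical debriefing variables, with Fisher's exact
test whenever any expected cell count is below 5.

## Problem sizes used by the test suite

The suite validates at deliberately modest scales chosen to exercise every
code path with stable statistics: 100 seeds for schedule invariants; 1000
random instances for the RW oracle; 20 replicates of 25-participant
cohorts for learning-rate recovery (absolute bias of the group mean below
0.05, every fit below split-Rhat 1.1) and for emotional-state calibration
(95% interval covers a true zero bias in ≥90% of replicates; a planted
bias difference of 0.4 recovers the correct contrast sign in ≥95%); 200
replicates × 500 permutations for family-wise-error calibration at
α = 0.05 under Gaussian null data (accepted within [0.02, 0.09], the
binomial uncertainty band); and exhaustive 2^8 sign-flip enumeration
against Monte-Carlo sampling. Summary statistics are checked against
hand-computed oracles to 1e−10 or tighter.

## Known limitations

* The sampler is a fixed-length HMC, not NUTS; pathological posteriors
  outside the intended model family may need a larger `t_sim` or more
  warmup than the defaults.
* The extinction model drops the CR+UR branch, so it cannot be applied to
  phases containing reinforced trials (it errors instead).
* Scoring assumes isolated responses; overlapping-response decomposition
  (model-based deconvolution) is out of scope.
* The similarity index requires reinforced trials followed by two
  unreinforced same-cue presentations; schedules with extreme reinforcement
  clustering can leave too few triplets, and such participants are flagged
  rather than imputed.
* Mixed-effects modelling of SCRs (e.g. Kenward-Roger F tests) is out of
  scope; the pipeline prepares trial tables and paired contrasts instead.
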