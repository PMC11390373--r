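---
title: "Modelling the Mnemonic Similarity Task with a three-choice Linear Ballistic Accumulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Mnemonic Similarity Task with a three-choice Linear Ballistic Accumulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstlba)
```

## The task and the measure

The Mnemonic Similarity Task (MST) probes how finely people discriminate
memories. In its standard three-alternative test phase, subjects see
*Repeats* (items shown at study), *Lures* (similar but not identical
items), and *Foils* (novel items) in equal proportion, and label each as
repeat, lure, or foil. The standard behavioral index is the Lure
Discrimination Index,

$$\mathrm{LDI} = P(\text{lure response} \mid \text{lure trial}) -
               P(\text{lure response} \mid \text{foil trial}),$$

the lure hit rate corrected for the bias of calling genuinely novel items
lures. The LDI uses one response type and two trial types, and it is a
choice-only measure: it discards response times and cannot say whether a
low score reflects weak memory signal or a response-style bias.

## The model

`mstlba` decomposes MST choices *and* response times with a three-accumulator
Linear Ballistic Accumulator (LBA). Each response $r \in \{$repeat, lure,
foil$\}$ has an independent accumulator that starts a trial at evidence
level $k_r \sim \mathrm{Uniform}[0, \min(A_r, b)]$, accumulates noiselessly
at rate $d_r \sim \mathrm{Normal}(v_r, s)$ drawn once per trial, and
triggers response $r$ when it reaches the common boundary $b$. The observed
response time is the winner's crossing time plus the non-decision time
$\tau$ (perceptual and motor processing). Parameters have standard
psychological readings: $v_r$ is signal strength for response $r$ (how much
deliberative evidence accrues), $A_r$ is the predisposition or bias toward
response $r$, $b$ is response caution, and $\tau$ is time outside
deliberation.

Identifiability requires fixing the scale of evidence. Three constraints do
this: the drift SD is fixed at $s = 1$; the drift means satisfy
$\sum_r v_r = 1$; and the start-point bounds satisfy $\sum_r A_r = 1$. Both
3-vectors live on the open simplex, handled internally by a stick-breaking
transform (`simplex_forward()`), which is bijective on the interior and
round-trips to $10^{-10}$.

The single-accumulator first-passage distribution is *defective*: a trial
whose sampled drift is negative never finishes, so the CDF tends to
$\Phi(v_r/s) < 1$. Two conventions for this mass are supported everywhere
via a single `renormalize` flag. The default keeps the conventional
unnormalized defective likelihood; with `renormalize = TRUE` the likelihood
conditions on at least one accumulator finishing
($1 - \prod_r \Phi(-v_r/s)$), and the simulator correspondingly redraws
never-finishing trials instead of emitting missing responses. Whichever
convention is chosen, simulator and likelihood stay consistent — this
pairing is verified by simulation-vs-quadrature tests.

The model is deliberately blind to the stimulus condition: drifts and
start points vary per accumulator (response), not per trial type, so only
the observed (response, RT) pairs enter the likelihood. A trial-type-
conditioned drift is a natural extension but out of scope here.

### Numerical choices

- An RT at or below $\tau$ has likelihood zero, not an error; the
  log-likelihood returns $-\infty$ honestly rather than flooring it.
  Consequently every fitter bounds $\tau$ above by the subject's minimum
  RT (via a logit transform), since larger values have zero posterior
  mass anyway.
- The start-point truncation below the boundary is implemented as
  $\mathrm{Uniform}[0, \min(A_r, b)]$ — inert when $A_r \le b$, capping
  the start below the boundary otherwise — keeping the density
  normalizable.
- All 3-vectors, file columns, and summaries use the fixed canonical
  ordering repeat, lure, foil.

## Estimation

`fit_lba_mle()` maximizes the race log-likelihood on the unconstrained
scale (two stick-breaking coordinates each for $v$ and $A$, $\log b$,
logit-scaled $\tau$) by multi-start Nelder-Mead: short exploratory runs
from a heuristic start (response proportions seed both simplexes) plus
jittered restarts, then a long polish of the best. It is the workhorse for
recovery studies and pipeline runs.

`fit_lba_bayes()` samples the posterior with priors
$b \sim \mathrm{N}(0.5, 1)$ and $\tau \sim \mathrm{N}(0.5, 1)$ (truncated
to their supports, $\tau$ additionally to $[0, \min \mathrm{RT})$), and
element-wise $\mathrm{N}(0.5, 0.5)$ on the simplex components of $v$ and
$A$ with the stick-breaking volume correction. The second prior argument
is a standard deviation. Defaults are three chains of 7000 iterations with
3500 discarded as warmup ("7000" is read as the total per chain;
configurable in `fit_config()`).

The sampler is differential-evolution MCMC, the family standard for
accumulator-model posteriors. Each reporting chain is an interacting
population of 12 particles moving directly in the *constrained* space
(two free simplex coordinates each for $v$ and $A$, plus $b$ and $\tau$):
a particle's proposal steps along the difference of two other randomly
chosen particles, which aligns the proposal distribution with correlated
and ridge-shaped posteriors automatically, and simplex or positivity
violations are simply rejected. Sampling the constrained coordinates
matters: subjects whose posterior piles against a boundary (a start-point
bound near zero, or $\tau$ near the minimum RT) have bounded, well-scaled
densities there, whereas a logit-transformed parameterization stretches
the same mass into an infinite tail that random-walk samplers traverse
very slowly. On the simplex the element-wise $\mathrm{N}(0.5, 0.5)$
priors apply directly with no volume correction. Three further kernel
components are mixed in: a heavy-tailed (t, df 4) independence proposal,
initialized from the curvature at the MLE and re-estimated once from the
warmup population, which decorrelates particles wherever the posterior is
well approximated; occasional $\gamma = 1$ difference moves (mode
jumping); and a rare single-coordinate uniform refresh that teleports
across the flat likelihood shelves arising when $A_r$ exceeds $b$ (the
start truncation makes the likelihood insensitive to $A_r$ there).
Stuck outlier particles are purged during warmup only. The per-chain
iteration budget equals the configured totals (7000 particle-updates per
chain, half warmup), so three chains cost about $2 \times 10^4$
likelihood evaluations per subject.

On typical 192-trial subjects this yields split-chain
$\widehat{R}$ around 1.003-1.007 with effective sample sizes in the high
hundreds. Convergence is gated on $\widehat{R} < 1.01$ for every
parameter (the `converged` flag); ESS is reported but does not gate.
Non-convergence is reported, never raised as an error; the standard
remedy — extending the chains — usually resolves it, and the geometries
that resist (true $\tau$ essentially at the minimum RT; $A_r > b$
shelves) are exactly the ones a practitioner should want flagged.

## The synthetic population generator

All validation rests on `population_config()` / `generate_dataset()`,
which produce ground-truth-known populations with the structure the
analyses assume:

- **Trial structure.** Balanced, shuffled repeat/lure/foil types; 192
  trials per subject by default (108 for the short task variant).
- **Typical ranges** (the default, `ranges = "typical"`) center the
  population on subject-level estimates typical for this task — drift
  means near $(0.47, 0.23, 0.30)$ and start bounds near
  $(0.49, 0.12, 0.39)$ for (repeat, lure, foil), $b$ log-normal around
  0.8, $\tau$ around 0.55 s — with moderate heterogeneity (SD 0.4 on the
  stick-breaking scale, 0.2-0.25 on the log scales). Simulated median RTs
  then land in the empirically familiar 1-2 s range.
- **Broad ranges** (`ranges = "broad"`) spread subjects across the whole
  valid space (uniform simplex center, SD 1.0, wider $b$ and $\tau$).
  This is the appropriate design for parameter-recovery studies, which
  ask whether estimation tracks truth across the space rather than within
  a narrow cohort. At 192 trials per subject, true-vs-estimated
  correlations under broad ranges are roughly 0.86-0.99 for every
  parameter; under the narrow typical cohort the drift correlations drop
  to about 0.6-0.7 — an information limit of 192 trials at fixed $s = 1$,
  not an estimation defect, and worth remembering when interpreting
  individual-difference correlations on real cohorts.
- **Age structure.** An optional two-component age mixture (younger
  centered at 23, older at 65) with an additive non-decision-time shift
  (default +0.1 s) in the older group — the magnitude seen between
  younger and older adults' NDT estimates in lifespan samples.
- **Retest structure.** Optional second session with per-parameter-block
  within-subject correlations of the unconstrained coordinates
  ($\rho = 1$ holds a parameter fixed; $\rho = 0$ redraws it).
- **Connectivity.** Optional per-subject symmetric Fisher-z matrices in
  which a designated edge equals a coupling strength times the subject's
  standardized coupled parameter plus noise, remaining edges pure noise.
- **LDI coupling (misspecification mode).** With `ldi_coupling` set, the
  generated *response* is perturbed conditional on *trial type*: on lure
  trials a forced lure response occurs with probability
  $q_L = \text{base} + \text{gain}\cdot\tanh(\lambda z_i)$ and on foil
  trials with $q_F = \text{base} - \text{gain}\cdot\tanh(\lambda z_i)$,
  where $z_i$ is the subject's standardized lure drift. At $\lambda = 0$
  the two probabilities coincide and the LDI is centered on zero; at
  positive $\lambda$ the LDI varies across subjects in a way tied to a
  known parameter. This mode deliberately breaks the fitted model's
  trial-type blindness, mirroring the real-data situation in which the
  trial-type-agnostic LBA is fit to behavior that does depend on trial
  type. It is the default for analysis-pipeline tests; pure well-specified
  mode is the default for recovery tests.

What the generator does *not* emulate: response deadlines (simulated RTs
have an uncensored defective tail; real tasks truncate at a few seconds),
trial-order effects such as fatigue or learning, contaminant processes
(fast guesses, lapses), and any real anatomical structure in the
connectivity matrices. Passing tests therefore demonstrate internal
consistency and statistical power under the assumed structure, not
robustness to these real-data features.

## Statistical machinery

Individual-difference analyses use tie-corrected Kendall rank correlations
(`kendall_tau()`, exact p for small tie-free samples), with the
Bonferroni-Holm step-down correction applied to the family of all eight
LDI-parameter pairs within one experiment (`correlate_measures()`).
Competing correlation strengths (is the LDI more a measure of signal than
of bias?) are compared by resampling subjects and forming percentile 95%
intervals for $\tau_A - \tau_B$ (`bootstrap_tau_difference()`; BCa via a
flag; 5000 resamples by default). Under a constructed null with equal
population correlations, interval coverage is 93-96% in seeded
calibration runs. Group comparisons use the two-sided Wilcoxon rank-sum
test. Test-retest stability is reported as within-subject cross-session
Kendall correlations alongside median (IQR) session differences
(session 1 minus session 2), since a parameter can preserve ranks while
shifting in level.

Brain-behavior analyses consume precomputed symmetric Fisher-z
connectivity matrices (region sets are configuration data, not hard-coded
anatomy). `edge_behavior_correlation()` correlates each off-diagonal edge
with a behavioral measure (Pearson or Kendall), uncorrected at
$\alpha = 0.05$ for exploratory maps. Dependent overlapping correlations
sharing the edge variable are compared with the classical Pearson-Filon
$z$ (`pearson_filon_z()`); its type-I rate at $n = 62$ calibrates to
0.05-0.06 in Monte-Carlo runs. Corrected maps use Benjamini-Hochberg
step-up flags (`fdr_threshold()`): a deliberate substitution of a fully
formula-specified FDR procedure for local-FDR density estimators, which
trade testability for adaptivity; the `q` level and the p-value inputs
are exposed so alternative estimators can be plugged in upstream.

## Problem sizes used in validation

The shipped validation suite uses: 20 random parameter sets with $10^5$
simulated trials each for simulator/likelihood equivalence; 40 broad-range
subjects at 192 trials for MLE recovery with full-length Bayesian fits
spot-checked on 5 subjects; 500 seeded replications (n = 100 subjects,
500 resamples) for bootstrap null coverage; 2000 simulated null datasets
at $n = 62$ for Pearson-Filon calibration; and 62-subject populations for
the end-to-end sign-pattern and connectivity-detection checks, with 20
seeded repetitions of the latter. These sizes were chosen so each check
has enough resolution to detect the failure it targets while the whole
suite remains routine to run.

## Known limitations

- With $s = 1$ and 192 trials, drift-rate point estimates carry
  substantial sampling noise; correlations between estimated drifts and
  other measures are attenuated accordingly.
- The defective RT tail is heavy when all drift means are small; real
  tasks censor it with deadlines, which the likelihood does not model.
- The Bayesian sampler's efficiency leans on the posterior being
  unimodal and roughly Gaussian per subject, which holds at these trial
  counts but would need re-checking for very short experiments.
- The Pearson-Filon statistic is asymptotic; at $n = 62$ its type-I rate
  runs marginally above nominal (about 0.055).
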