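# mstlba

Evidence-accumulation decomposition of behavior in the three-choice
Mnemonic Similarity Task (MST).

The MST asks subjects to label test items as **Repeats** (seen at study),
**Lures** (similar but new), or **Foils** (new), in equal proportion. Its
standard score, the Lure Discrimination Index

```
LDI = P(lure response | lure trial) − P(lure response | foil trial),
```

is choice-only: it cannot say whether a low score reflects weak memory
signal or a response-style bias. `mstlba` fits a constrained
three-accumulator **Linear Ballistic Accumulator** (LBA) to choices *and*
response times to separate the two. Each response `r` has an accumulator
starting at `U[0, min(A_r, b)]`, rising at rate `N(v_r, s)` to a boundary
`b`; the first to cross determines the choice, and RT adds a non-decision
time `τ`. Drift means `v` index signal strength, start-point bounds `A`
index response bias. For identifiability, `s = 1` and both `v` and `A`
sum to 1 across the three accumulators (simplex constraints).

The package provides, per module:

- **Race model**: exact first-passage CDF/density, race likelihood
  (defective or renormalized), analytic choice probabilities, and a fast
  trial simulator (`plba_accumulator`, `dlba_race`, `lba_loglik`, `rlba`).
- **Fitting**: per-subject Bayesian posterior sampling with simplex-aware
  priors and an `Rhat < 1.01` convergence gate (`fit_lba_bayes`), plus a
  multi-start MLE for recovery studies (`fit_lba_mle`).
- **Behavioral metrics**: LDI, per-type accuracy, per-response median RTs
  and proportions, RT-binned choice profiles, age-group assignment.
- **Association statistics**: tie-corrected Kendall τ with Bonferroni-Holm
  families, bootstrapped τ-difference 95% CIs, Wilcoxon rank-sum
  comparisons, test-retest stability reports.
- **Connectivity analyses**: edge-wise correlation of Fisher-z RSFC
  matrices with behavioral measures, Pearson-Filon z comparison of
  dependent overlapping correlations, Benjamini-Hochberg FDR maps.
- **Synthetic data**: ground-truth-known populations (trials, ages,
  sessions, connectivity) for end-to-end validation (`population_config`,
  `generate_dataset`).

## Worked example

Simulate a 12-subject population whose LDI is coupled to the lure drift
rate, fit every subject, and inspect the LDI-parameter correlation family:

```r
library(mstlba)

cfg <- population_config(n_subjects = 12, n_trials = 192, seed = 42,
                         renormalize = TRUE,
                         ldi_coupling = list(strength = 1.5))
ds <- generate_dataset(cfg)

report <- run_pipeline(ds$trials, method = "mle",
                       config = fit_config(seed = 1, renormalize = TRUE))
print(report)
#> MST LBA pipeline report: 12 subjects, 12 fits (mle)
#>
#> LDI-parameter correlations (Holm-adjusted):
#>           pair    tau p_value  n p_adjusted
#> 1 ldi-v_repeat -0.382  0.0857 12      0.686
#> 2   ldi-v_lure  0.321  0.1489 12      0.893
#> 3   ldi-v_foil -0.168  0.4496 12      1.000
#> 4 ldi-A_repeat  0.107  0.6304 12      1.000
#> 5   ldi-A_lure -0.321  0.1489 12      0.893
#> 6   ldi-A_foil  0.351  0.1139 12      0.797
#> 7        ldi-b  0.229  0.3025 12      1.000
#> 8      ldi-tau  0.137  0.5362 12      1.000
```

Even at this toy size the construction shows through: the LDI correlates
positively with the lure drift rate (τ = 0.32) and negatively with the
repeat drift rate (τ = −0.38) — the planted signal-strength pattern —
though 12 subjects are far too few for significance after Holm
correction (`p_adjusted` near 1). At realistic cohort sizes (60+) the
same pipeline flags these pairs reliably; see the acceptance script.

Individual subjects can be fit fully Bayesian:

```r
sub <- ds$trials[ds$trials$subject == "S001", ]
fit <- fit_lba_bayes(sub, fit_config(seed = 7, renormalize = TRUE))
fit$converged      # all split-chain Rhat < 1.01
fit$summary        # mean/median/95% interval/Rhat/ESS per parameter
```

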