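---
title: "Farmland-fertility tuning of a CNN-GRU beat classifier: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Farmland-fertility tuning of a CNN-GRU beat classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
defaults matter, and where a genuinely open design choice was settled one
way rather than another. The README shows the pipeline end to end; here we
concentrate on the method.

## The pipeline

`ffatune` classifies fixed-length ECG beat windows. The pipeline is
deliberately small: per-position z-score standardisation, a hybrid
convolutional/recurrent classifier, and a population metaheuristic — the
Farmland Fertility Algorithm (FFA) — that tunes the classifier's
hyperparameters against cross-validated classification error. No
de-noising, resampling or multi-lead handling is attempted: the input
contract is "one beat per row, same length, finite amplitudes", whether the
rows come from the synthetic generator, a CSV file, or the WFDB adapter.

## Standardisation

`fit_standard_scaler()` computes the per-column mean and *population*
(divisor *n*) standard deviation, the convention of the usual
"standard scaler" found in machine-learning toolkits, and
`apply_standard_scaler()` maps `z = (x - mu) / sd`. Two numerical details:

* the standard deviation is computed from centred squares, not via
  `E[x^2] - mu^2`, because on noiseless synthetic data the latter can go
  negative by cancellation and produce `NaN`;
* a column whose sd falls below `1e-12` has its sd replaced by 1 (the
  "zero-guard"), so constant channels pass through centred rather than
  crashing a pipeline with a division by zero. This situation is real, not
  hypothetical: noiseless synthetic beats have constant columns wherever
  the two class templates agree.

Standardisation is idempotent at tolerance `1e-9`: re-fitting on already
standardised data gives mu ~ 0, sd ~ 1.

## The synthetic beat generator

`generate_dataset()` emits two-class (extensible to C-class) beat windows
built from a deterministic sum of Gaussian bumps laid out like a P-QRS-T
complex — small P bump, narrow tall R spike flanked by Q and S dips, broad
T bump — plus iid Gaussian amplitude noise. Class 1 differs from class 0 by
an R spike widened by a factor `1 + 0.35 * separation` and a T amplitude
scaled by `1 - separation`, so at `separation = 0` the classes coincide, at
1 the T bump vanishes and at the default 2 it is fully inverted. Defaults
(`window_length = 180`, `noise_sd = 0.05`, `separation = 2`) were chosen
once so that the classes are cleanly separable — a nearest-centroid rule
reaches 99%+ — while the noise is clearly visible against the 0.15–0.3
amplitudes of the P and T bumps; the desk-scale test runs shorten the
window to 64 samples to keep the recurrent sequence short.

What the generator emulates: fixed-length, class-dependent beat morphology
with additive noise, the statistical structure every downstream stage
needs. What it does not emulate: rhythm (RR-interval) context, baseline
wander, electrode artefacts, class imbalance of real arrhythmia databases,
inter-patient morphology drift. Passing tests on synthetic beats therefore
demonstrate that the machinery is correct and trainable, not that any
particular accuracy carries over to clinical recordings.

Class counts follow largest-remainder apportionment of
`n_beats * class_fractions` (ties toward the lower class index), which
agrees with plain rounding whenever rounding is consistent and always sums
to `n_beats`.

## The CNN-GRU classifier

`build_model()` assembles: 1-D convolutions (`conv_layers`, default 3;
`conv_filters`, default 32; ReLU) each optionally followed by width-2 max
pooling; the resulting length-L' sequence of filter vectors feeds
`gru_layers` (default 2) GRU layers of `gru_units` (default 64); the final
hidden state passes through a ReLU dense layer (`hidden_units`, default
64) with dropout (default 0.5) into a softmax output. Reference defaults
follow the three-conv / two-GRU / one-hidden-layer topology with 32
convolution filters and 64 recurrent units.

Points that were genuinely open and how they were settled:

* **Kernel size and pooling.** Kernel 5 with "same" zero padding and a
  width-2 max pool after each convolution (switchable off). Odd tail
  samples are dropped by pooling; a spec whose pooled length falls below 1
  is rejected as `architecture infeasible` at construction time.
* **Gate nonlinearities.** The recurrence uses the printed sigmoid/tanh
  update exactly as in `gru_step()` — reset gate on the carried state
  inside the candidate, `h_t = z ⊙ h_prev + (1 − z) ⊙ h̃`. ReLU is used in
  the convolutional and dense stages. The trainable layer is tested against
  the reference cell on random instances, including two-step sequences so
  the recurrence is exercised at a non-zero hidden state.
* **Optimiser and loss.** Neither is dictated by the architecture; we use
  Adam at the configured learning rate (default 0.01) with categorical
  cross-entropy, the standard pairing with a softmax output.
* **Gradient clipping.** Mini-batch gradients are clipped to a global
  L2 norm of 5 (`clip_norm`, configurable). Without it, learning rates
  near the top of the tuning range (0.1) train fine for the short
  cross-validation fits but can diverge mid-way through a longer final
  fit; clipping is the standard stabiliser for recurrent nets and keeps
  the tuned settings usable downstream.
* **Dropout site.** After the dense hidden layer, applied only during
  training (inverted dropout), drawn from the training seed so runs are
  reproducible.
* **Determinism.** `build_model(spec, seed)` draws Glorot-uniform weights
  from a seeded stream; `train_model()` seeds shuffling and dropout; two
  runs with identical inputs give bit-identical loss traces on a fixed
  platform.
* **Ties.** `predict()` breaks exact probability ties toward the lower
  class index.

The implementation is plain double-precision R built on BLAS matrix
products (im2col convolutions, batch-vectorised recurrence), with
gradients verified against central finite differences at `1e-5`.

## The Farmland Fertility Algorithm

`ffa_optimize()` minimises a black-box objective over a box. The
population of `N = k * n` solutions is partitioned *by array order* into
`k` sections of `n` (no sorting); each section's quality is its mean
fitness and the *worst* section is the argmax (ties toward the lower
index). Elitist memories hold the best `round(t_global * N)` solutions
globally and `round(t_local * n)` per section — rounding half away from
zero with a floor of one slot — merged and truncated every iteration, so
the memory heads (the global and section bests) never worsen.

Per iteration, three update phases, each followed by hard clipping to the
bounds and *greedy* keep-if-better replacement:

1. worst section: `x' = h (x - x_mem) + x`, `h = alpha * U(-1, 1)`,
   `x_mem` uniform from the global memory;
2. other sections: `x' = h (x - x_u) + x`, `h = beta * U(0, 1)`, `x_u`
   uniform from the current population;
3. combination: with probability governed by `Q > U(0,1)`,
   `x' = x + omega1 (x - best_global)`, otherwise
   `x' = x + U(0,1) (x - best_local)`; then `omega1 <- omega1 * Rv`.

Settled choices, with the reasoning:

* The two stochastic step scales are read as `alpha * U(-1, 1)` and
  `beta * U(0, 1)`: the worst-section move needs both signs to explore
  around `x`, the other-sections move is a one-sided blend.
* The replacement policy is greedy (keep only improvements). Nothing else
  guarantees the monotone best-so-far trace that the tests assert, and it
  makes the "fixed point" oracle exact: with `alpha = beta = omega1 = 0`
  and `Q = 0`, a population in which every section sits on its own best is
  left bit-identical by a full iteration.
* Exactly one worst section is updated per iteration.
* `omega1` multiplies only the global-best branch of the combination
  phase, and `Rv` (default 0.8) is a fixed configured decay constant.
* Memory sizes derive from `t_global` against `N` and `t_local` against
  `n`; both fractions are constrained to (0.1, 1).
* Out-of-bounds proposals are clipped to the nearest bound.
* `k` outside 2..8 raises a warning (the customary band), not an error.

Reproducibility has one subtlety: the objective itself may use the R
random-number generator (the cross-validation fitness seeds its own
training runs). `ffa_optimize()` therefore snapshots and restores the RNG
state around every objective call, so the optimiser's own draws — and
hence the whole run — depend only on its seed regardless of what the
objective does.

On the 2-D sphere over `[-5, 5]^2` with `k = 4`, `n = 5` and 200
iterations, the default configuration reaches fitness below `1e-2` in all
ten test seeds (typically ~`1e-14`).

## Cross-validated fitness and tuning

The tuner searches the continuous unit hypercube, one gene per
hyperparameter, and decodes: log-reals by interpolation in log10 space,
reals linearly, integers by `lo + floor(g * (hi - lo + 1))` capped at
`hi`, categoricals by index. This keeps the optimiser purely continuous
while supporting integer and categorical settings. The default space spans
learning rate (log, 1e-4..1e-1), dropout (0..0.7), batch size (4..64),
convolution filters (8..64), GRU units (8..128) and kernel size (3..9);
the ranges are an implementation choice, not a claim about any particular
study.

The fitness of a genome is the mean stratified k-fold held-out error
percentage (`error_rate()` = 100 x misclassified / total; folds default
3). Two design details:

* **Row-order invariance.** Folds are dealt from a seeded permutation of a
  canonical row ordering (label, then beat values), so shuffling the
  dataset does not change the fitness of a genome.
* **Per-evaluation reseeding.** Each fold's training seed is a hash of the
  global seed, the genome and the fold index, so two candidate genomes are
  not compared under accidentally shared initialisation noise.
* **Epoch cap.** Fitness evaluations train for `tune_epochs` (default 5)
  epochs regardless of the final-training epoch count (default 50): the
  tuner needs a cheap, consistent ranking signal, not fully converged
  models. The cap is config-exposed.

`ffa_tune()` returns the decoded best settings, their fitness, the
monotone FFA trace and the fitness of the initial population (useful as an
improvement baseline); optionally it retrains a final model on all data.

Metrics: accuracy, sensitivity and specificity as percentages from the
truth-by-prediction confusion matrix; binary rates are taken with respect
to a configurable positive class (default 1), C > 2 uses macro-averaged
one-vs-rest rates, and a rate with an empty denominator is reported as 0
with a warning flag rather than `NaN`. Accuracy and `error_rate()` are
exact complements.

## Problem sizes used by the tests

The test-suite and acceptance-script runs are sized for a single CPU:
synthetic datasets of 60–500 beats with 16–64-sample windows; classifier
sanity runs with one convolution layer (8 filters), one GRU layer (8
units) and 10–15 epochs; tuning runs over a compact four-entry space
(learning rate, dropout, 4–16 GRU units, 4–8 filters) with `k = n = 2`,
3 iterations, 3 folds and 3-epoch fits; FFA benchmarks at 200 iterations.
These sizes exercise every code path; they are stated here so that anyone
scaling the experiments up knows exactly what was run.

## WFDB adapter

`extract_beats_wfdb()` windows a record around its annotated beats: window
of `L` samples centred on the annotation (`half = floor(L/2)` before it),
symbols mapped to classes through an explicit `label_map`, unmapped
symbols and boundary-clipped windows dropped. The reader covers
single-segment records in signal formats 16 and 212 and MIT-format
annotation files (including SKIP intervals and AUX payloads). Window
length (default 180 samples), lead and label grouping are deliberately
explicit parameters: standard beat-classification protocols differ on all
three, so the adapter makes no silent choice.

## Known limitations

* The classifier is CPU-bound, double-precision R; it is meant for
  desk-scale experiments (hundreds to a few thousand beats), not for
  training on full Holter databases.
* The FFA handles box constraints only; no constraint handling beyond
  clipping, no parallel fitness evaluation.
* Synthetic results bound what the tests can show (see above); on real
  data the preprocessing, windowing and label-grouping choices exposed by
  the WFDB adapter will dominate performance.
* Multi-lead records are reduced to a single configurable channel.
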