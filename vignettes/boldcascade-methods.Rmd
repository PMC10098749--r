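---
title: "Methods: two-stage multitask classification of BOLD signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage multitask classification of BOLD signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Task-fMRI decoding asks the reverse of the usual question: given a 1-D BOLD
time series extracted from a region of interest, infer which stimulation
protocol produced it. `boldcascade` implements a two-stage answer. Stage I
assigns one of four task classes — emotion, memory, motor, resting. Stage II
then refines signals labelled emotion or memory into their sub-phases:
the three social-support levels (high / medium / low) of the emotion
paradigm, and the encode / recall blocks of the memory paradigm. Motor and
resting runs have no sub-phases, so Stage II is only ever reached through an
emotion or memory route; a signal misrouted at Stage I still receives
sub-phase predictions, which is deliberate — cascade error propagation
should be observable, not hidden.

## The feature fusion module

Both stages use the same feature fusion module (FFM), which concatenates
three complementary views of a signal of length $T$:

* **Frequency block** $f_F$: four FFT summary scalars (total non-DC power,
  spectral centroid in Hz, peak frequency in Hz, spectral entropy in bits)
  followed by the full multilevel periodized DWT coefficient vector
  (coarsest approximation first, then details). For $T = 600$ with the
  8-level Haar preset this block has $4 + 603 = 607$ entries.
* **Scalogram CNN block** $f_R$: the analytic-Morlet CWT magnitude over 64
  geometric scales is rendered as a 224x224 colour image (fixed viridis
  map, bilinear resize) and passed through a 50-layer bottleneck residual
  network; the spatial average of the final 7x7x2048 map gives 2048
  features.
* **LSTM block** $f_L$: the final time-step hidden state of a two-layer
  LSTM (150 then 100 units), i.e. a 100-vector.

The fused vector is always ordered $[f_L; f_R; f_F]$, giving
$100 + 2048 + 607 = 2755$ features at Stage I. Minimum-redundancy
maximum-relevance (MRMR) selection reduces this to 512 features, which feed
a two-layer fully-connected softmax classifier.

Stage II re-runs the FFM on 1x200 segments: emotion signals are cut into
equal thirds; memory signals contribute their annotated design blocks
(padded to 200 samples). At $T = 200$ an 8-level decomposition is no longer
meaningful, so the preset drops to 6 levels ($f_F$ has 207 entries) and the
MRMR target scales to 256. The Stage II LSTM uses dropout 0.2 and 0.1 after
its two layers, minibatches of 256 and nominally 500 epochs; Stage I uses
the same stack without dropout.

### Design choices in the FFM

Several details are genuinely open and were fixed as follows:

* **Composition of the 607-feature block.** The printed dimension
  constrains the sum, not the split. The package's preset — 4 FFT summary
  scalars plus the complete 8-level Haar periodized coefficient vector
  (603) — is the only configuration guaranteed to produce 607; both
  sub-blocks are independently configurable, and the preset is documented
  as an assumption.
* **DWT boundary handling.** Periodization keeps the coefficient count
  equal to the signal length plus the final approximation; odd-length
  levels are extended by one wrapped sample, which preserves exact
  invertibility (verified to 1e-8 in the tests) at the cost of a few
  redundant coefficients (603 rather than 600 for 8 levels).
* **FFT features exclude the DC bin** because pool conditioning forces a
  zero mean; the DC bin would carry padding artefacts only.
* **CWT parameters.** Analytic Morlet with centre frequency 6, 64
  geometric scales between the Nyquist period and half the record length;
  colour map and bilinear resize are fixed so rendering is byte-identical
  across runs.
* **CNN weights.** The residual network is used as a frozen feature
  extractor, never trained. The default `random-fixed` mode draws
  He-normal weights under a fixed seed: a deterministic random-projection
  embedding that requires no external weight files. ImageNet-pretrained
  weights can be supplied from a file for realism; all dimensional
  contracts are independent of the weight values. The pooled output is the
  standard global average pool of the last stage.
* **LSTM candidate cell.** The candidate is
  $\tanh(W_c [h_{t-1}, x_t] + b_c)$, the standard form; gates are logistic.
  Features come from a classifier-trained network: the stack is trained
  with a temporary softmax head on the labels, the head is discarded, and
  the final hidden state serves as the feature vector. Forget-gate biases
  initialise at 1, weights Glorot-uniform, training uses Adam with global
  gradient-norm clipping at 5.

## MRMR selection

Features are quantile-discretised into 8 bins (robust to heavy-tailed
feature distributions; inputs with at most 8 distinct values are treated as
categorical), and mutual information is the plug-in histogram estimator in
bits. Relevance of a set is the mean label MI; redundancy is the mean
pairwise MI over ordered pairs *including* the diagonal, matching the
literal double sum of its definition — the brute-force oracle in the test
suite uses the same convention. The greedy search picks the most relevant
feature first, then maximises the difference (MID, default) or quotient
(MIQ) of relevance against mean redundancy to the selected set, with ties
broken to the lowest index and zero-denominator MIQ candidates falling back
to their MID score. Caching the pairwise-MI sums keeps the cost at
$O(K m)$ MI evaluations; each step counts one feature's joint histograms
against all candidates with a single sparse cross-product.

## The synthetic generator

The authors' pool is private, so the generator emulates its block
structure: every signal is a boxcar stimulus convolved with a canonical
double-gamma HRF (shapes 6 and 16, unit rate, undershoot ratio 1/6, peak
normalised to 1), plus AR(1) noise (coefficient 0.3, innovation sd 0.4)
and a random quadratic drift (coefficient sd 0.6). Defaults per class:

* resting — 180 samples at TR 3 s, noise only;
* motor — 200 samples at TR 2 s, ten repeats of 20 s rest / 20 s
  finger-tapping;
* emotion — 600 samples at TR 3 s, three sequential 200-sample support
  phases; each phase is a train of reward events whose rate and amplitude
  follow the support level (16 events at amplitude 1.0, 8 at 0.8, 3 at
  0.6). Event-rate coding matters: pool conditioning removes the
  best-fitting line of the whole signal, and a monotone three-level
  staircase is almost entirely linear trend, so plateau-level coding alone
  would be erased. Distinct event rates leave a per-phase variance and
  frequency signature that survives detrending;
* memory — 600 samples at TR 3 s, rest / sustained 200-sample encode block
  / rest / recall event train (ten 10-sample events at amplitude 1.2),
  giving the two sub-phases distinct amplitude and frequency signatures.

Per-signal response gains are jittered in U(0.8, 1.2) to mimic
inter-subject variability; subjects are assigned round-robin within each
class so every subject sees every class (required for leave-subjects-out
folds). Everything derives from one seed. Noise levels were chosen once so
that single-branch classifiers are strong but imperfect on desk-scale
pools. The generator does **not** emulate physiological confounds
(cardiac/respiratory cycles), scanner drift nonstationarity, spatial
structure, or inter-session variability — passing tests demonstrate that
the pipeline recovers the designed class structure, not that it would
reach any particular accuracy on real scanner data.

## Evaluation

`kfold_partition()` provides plain k-fold (test folds of exactly
`floor(n/k)`, remainder always retained in training — the only rule
consistent with a 17620/1601 split of 19221 samples at k = 12) and
grouped by-subject folds, the scientific default, in which no subject spans
train and test. `evaluate_system()` compares the fused model against its
LSTM-only and CNN-only ablations on shared folds: the training-independent
branch features (spectral block, fixed-weight CNN embedding) are extracted
once per signal, while the LSTM branch, the MRMR selection and the
classifier are refitted per fold on training rows only. The fitted LSTM
features are shared between the LSTM-only model and the fused model within
a fold, which keeps the comparison paired. Metrics are per-class precision,
recall, F1 and overall accuracy (percentages); model complementarity is
summarised by 2x2 diversity tables (both hit / one hits / both miss),
whose cells always sum to the evaluated sample count.

The packaged benchmark runs at desk scale: the default synthetic pool is
4 classes x 150 signals with 12 subjects, evaluated on the first fold of a
by-subject 3-fold plan, with the LSTM trained for 8 epochs and the
classifier head for 150, in minibatches of 100 — problem sizes chosen so
the whole suite runs on a single CPU in minutes. The sub-phase stage is nominally a five-way
problem (three emotion plus two memory classes), but the two families are
reported separately (3-class and 2-class heads) because a signal's family
is already decided at Stage I; this mirrors the separate per-family result
tables and avoids an artificial five-way competition between phases that
can never co-occur.

## Numerical conventions and degenerate inputs

* FFT magnitudes use the unnormalised DFT convention (DC bin = sum of
  samples); Parseval holds as `sum(x^2) = sum(|X|^2)/T`.
* An all-zero signal yields the zero FFT summary `(0, 0, 0, 0)` by
  convention, a zero spectral block, and a zero scalogram rendered as a
  uniform image.
* Signals longer than a padding target raise an error — never silent
  truncation; the same applies to phase splits that do not divide the
  length.
* Detrending removes the least-squares line; it is idempotent to 1e-9.
* All stochastic fits (LSTM, classifier head, fold shuffling, generator)
  take explicit seeds and restore the caller's RNG state, so identical
  seeds give bit-identical models, and prediction never mutates a fitted
  system.

## Known limitations

* Random-projection CNN features are weaker than pretrained ones; they
  suffice for the synthetic benchmark but are not a substitute for real
  transfer learning on scanner data.
* The plug-in MI estimator is biased upwards at small sample sizes; the
  selection oracle uses the same discretisation, so agreement checks are
  exact, but absolute MI values at n below a few hundred should be read
  with that bias in mind.
* Memory sub-phase extraction relies on design metadata; signals without
  it fall back to equal halves, which is only correct for the default
  generator layout.
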