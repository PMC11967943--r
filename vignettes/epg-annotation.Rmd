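---
title: "Automatic annotation of EPG recordings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic annotation of EPG recordings: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgkit)
```

## The problem

Electrical penetration graph (EPG) recording wires an aphid and its host
plant into a low-voltage circuit; as the insect's stylet penetrates plant
tissues, the measured voltage traces out characteristic waveforms that
encode behaviour. Seven classes are standard: **NP** (non-probing, stylet
outside the plant, near-flat around 0 mV), **C** (pathway phase through
epidermis and mesophyll, a complex mid-frequency mixture), **pd**
(potential drop, a brief sharp intracellular puncture occurring only
during C), **E1** (phloem salivation), **E2** (phloem sap ingestion),
**F** (derailed stylet) and **G** (xylem ingestion). Manually annotating
an 8-hour session is slow and subjective; `epgkit` automates it with a
sliding-window pipeline:

1. **Initial segmentation** — the normalised recording is cut into
   consecutive windows of `d = 1024` samples (10.24 s at 100 Hz).
2. **Waveform classification** — each window is transformed into features
   and classified into one of the seven classes, producing a probability
   distribution per window.
3. **Label aggregation** — each window's predicted label is replicated
   across its `d` timesteps; concatenating and truncating to the
   recording length yields one label per timestep (2,880,000 for 8 h at
   100 Hz), and run-length encoding yields the predicted annotation track.

Two evaluation tasks follow the same split: *Task 1* scores held-out
segment classification (overall accuracy, macro F1 from the 7x7
confusion matrix), *Task 2* scores whole-recording annotation by the
**overlap rate** (OR) — the fraction of timesteps at which predicted and
true labels agree — on recordings never segmented into the training pool.

## The synthetic data generator

Real annotated aphid EPG corpora are not redistributable, so the package
ships a generator that plays the role of the data: a semi-Markov
behavioural grammar over episodes, plus per-class signal archetypes.

**Grammar.** Episode transitions respect the biology: probing must pass
through C before any E1/E2/F/G activity; pd occurs only as an
interruption strictly inside a C episode (a pd interval is always
preceded and followed by C); NP alternates with probing bouts. The next
episode class is drawn among allowed successors with weights proportional
to each class's remaining deficit against its target time share, and
episode durations are stretched or shrunk (clamped to [0.3, 2] of the
drawn value) toward the same targets, so recordings self-correct toward
the configured class balance. Default targets are `NP 0.30, C 0.24,
pd 0.015, E1 0.04, E2 0.29, F 0.04, G 0.075`. The six episode classes
follow the class balance reported for combined multi-species corpora;
pd is deliberately a small *time* share, because pd events are 3-8 s
punctures that occur frequently but occupy little clock time — corpus
tables quoting pd fractions of 0.1-0.3 describe segment databases after
pd oversampling (which this pipeline reproduces), not time on the clock.
The pd insertion rate per second of C defaults to the value that makes
the pd/C time ratio match the targets given the mean pd duration.

**Archetypes.** Each class renders as baseline + oscillation + Gaussian
noise, with per-interval frequency jitter inside a declared dominant
band: NP is a 0.05-0.8 Hz drift of 0.05 mV around 0 with sparse spikes;
C sums 2-3 sinusoids in 4-8 Hz around a 1.5 mV baseline; pd is a sharp
1.5-2.1 mV negative excursion with a 7-11 Hz plateau ripple; E1 and E2
are periodic with harmonics at 1.6-2.6 Hz and 0.7-1.3 Hz; F and G are
regular high-amplitude oscillations at 13-17 Hz and 9-11 Hz. A 0.1 s
linear cross-fade keeps boundaries continuous up to noise. All constants
are package conventions chosen once to make classes separable but
overlapping; they are *not* measurements.

**What passing tests do and do not show.** The generator emulates the
label grammar, class balance, stationarity within intervals and the
qualitative frequency structure of the classes. It does not emulate
electrode drift, emf/resistance components, species- or plant-specific
waveform morphology, or annotation noise. A high benchmark score on
synthetic data therefore validates the *pipeline machinery* — feature
extraction, training, aggregation, metrics — not field performance on any
particular species.

Everything is a pure function of the configuration: `sample_behavior_sequence()`
and `render_recording()` derive their RNG streams from `config$seed`, and
`generate_dataset(n, config)` uses seeds `seed, seed + 1, ...`.

## Preprocessing conventions

* **Normalisation** is per recording, before segmentation: affine min-max
  scaling to [0, 1]. A constant recording maps to zeros with a warning.
* **Trailing window**: the last window of a recording is padded by
  repeating the final value; surplus labels are truncated at aggregation,
  so label counts are conserved exactly.
* **Segment labels** are the majority per-timestep truth label within the
  window span, ties broken by the canonical order
  `NP < C < pd < E1 < E2 < F < G`.
* **Midpoint padding**: a waveform occurrence `[i, j)` shorter than `d`
  becomes the length-`d` window of the *parent recording* centred on
  `m = floor((i + j) / 2)`, shifted minimally at recording boundaries —
  padding borrows true signal context, it never fabricates values.
  Occurrences of length `>= d` get a centred crop (the identity at
  exactly `d`).
* **pd oversampling**: each pd occurrence yields `2d/s + 1` windows of
  length `d` (17 at the defaults `d = 1024`, `s = 128`), taken at offsets
  `k * s` from the double-width anchor `m - d + 1`. The count law forces
  the emitted windows to span a triple-width context `[m - d + 1, m + 2d]`;
  windows are clamped to the recording. Oversampling is applied to the
  training portion only, to keep validation and test sets free of
  augmented windows.
* **Split**: about 10% of recordings (at least one) are held out intact
  (Subset 2); the remaining recordings are segmented, shuffled with the
  seed and divided 70/10/20 into train/validation/test (Subset 1).

## Feature extraction

Three vector representations feed the classical models: 13 statistics of
the raw window, 13 of its Fourier magnitude spectrum (`d/2 + 1`
non-negative-frequency coefficients), or 52 wavelet statistics (13 per
band of the 3-level symlet-4 decomposition, bands `A3, D3, D2, D1`).
The 13 statistics are mean, RMS, SD, variance, skewness, the
0.05/0.25/0.5/0.75/0.95 quantiles, zero-crossing rate, Shannon entropy
and permutation entropy. Conventions the package fixes:

* **ZCR** counts sign changes after mean-centering (normalised signals
  live in [0, 1] and would otherwise never cross zero), divided by
  `length - 1`.
* **Shannon entropy** uses the normalised squared magnitudes
  `p_i = v_i^2 / sum(v^2)` as the probability model, natural log.
* **Permutation entropy** uses order 3, delay 1, ties broken by index
  order, normalised by `log(3!)` to [0, 1].
* **Degenerate inputs**: a numerically constant vector (relative range
  below 1e-10 — e.g. the detail bands of a flat signal, which are zero up
  to round-off) gets skewness, ZCR and both entropies 0, with a warning.
  The standalone `shannon_entropy()` keeps its definitional value
  (`log n` for a uniform-magnitude vector); the zero convention applies
  only inside the 13-feature vector.

Image representations feed the 2-D CNN: the **spectrogram** (Hann window
128, hop 14, no centering — exactly 65 frequency bins x 65 frames for
`d = 1024`; pixels are `log10(max(|X|, 1e-10))`); the **Morlet
scalogram** (analytic Morlet, centre-frequency parameter 6, 64
geometrically spaced scales spanning pseudo-frequencies 0.1-50 Hz, time
axis block-averaged to 64 columns); and the **GASF** (piecewise aggregate
approximation to 64 points, min-max rescale to [-1, 1], polar angle
`phi = arccos(x)`, pixels `cos(phi_i + phi_j)`). A constant window
rescales to its own maximum (all angles 0, all pixels 1), which keeps the
image well defined. The scale grid and the PAA target are package
choices; only the window/hop geometry and the 64/65 output sizes are
fixed by the method.

**Feature selection.** `correlation_select()` links features with
absolute Pearson correlation above 0.8 and keeps the first-declared
member of each connected group (zero-variance columns correlate with
nothing and stay). On the 52 wavelet features the documented drop-list —
the five quantiles, the variance and the RMS of each resolution, which
duplicate the median and SD — leaves the 24 core features returned by
`wt_core_features()`: mean, SD, skewness, ZCR, Shannon and permutation
entropy of `A3, D3, D2, D1`. (Descriptions of this selection sometimes
state that the median is retained; the enumerated 24-feature list, which
excludes it, is taken as authoritative here.)

## Classifiers

Six families share one interface, `epg_train()`, returning an
`epg_model` with `predict()`/`print()`/`summary()` methods and a stored
feature contract so `annotate_recording()` can re-derive the right
representation. Class order is fixed to the canonical seven labels and
probability rows always sum to 1; argmax ties resolve to the earlier
class.

* **gbt**: gradient-boosted trees via xgboost, baseline
  `{100 trees, eta 0.3, depth 6}`, single-threaded and seeded.
* **rf**: random forest, 100 trees, unlimited depth.
* **logreg**: multinomial logistic regression (softmax) with a light L2
  penalty (`decay = 1e-4`), mirroring the common library default of a
  weakly regularised baseline.
* **cnn1d / resnet1d / cnn2d**: built on the package's own conv-net
  engine (im2col convolutions, batch normalisation, max pooling, dropout,
  Adam, cross-entropy). The 1-D CNN stacks three convolutions with 64,
  128, 64 channels (dilation 3, stride 2, ReLU + batch norm each),
  max-pools with size 3, and ends in dropout 0.5 and a dense layer to 7
  logits. The residual network uses three blocks (64, 128, 128 channels),
  each three same-padded convolutions with an identity or 1x1-projection
  shortcut added before the block's batch norm, followed by max pooling
  3/3; block internals (kernel sizes, normalisation placement) are
  under-determined by the published description, and the choices here are
  configuration, not asserted facts. The 2-D CNN uses two conv(16, 3x3) +
  pool(2/2) stages and two dense layers with dropout 0.5, accepting
  64x64 or 65x65 single-channel images. Flatten widths come from shape
  arithmetic, so non-default `d` still builds.

Training choices the method leaves open, fixed here: the optimiser is
Adam (standard for the quoted learning rates; momentumless SGD would need
different rates), He fan-in initialisation from a seeded generator, no
early stopping (fixed epoch count), neural baseline
`{batch 256, lr 1e-4, kernel 9, 100 epochs}`. Divergence (non-finite
loss) aborts with a diagnostic rather than returning garbage. The
backward pass is verified against central finite differences in the test
suite; conv biases that feed a batch norm sit in a null direction of the
loss and are excluded from that comparison.

`grid_search()` implements both documented tuning strategies: exhaustive
`4 x 4 x 4 = 64` runs over trees/eta/depth for gbt, and the sequential
one-factor schedule (batch sizes, then learning rates, then kernel sizes,
then epochs: `6 + 4 + 3 + 3 = 16` scheduled runs, repeats served from a
cache) for the 1-D CNN, selecting on validation accuracy with ties to the
earlier configuration.

## Evaluation

`confusion_matrix()` is 7x7 with rows = truth; "normalised" views divide
rows by their sums, so the diagonal is per-class accuracy (recall).
Per-class F1 combines precision `TP/(TP+FP)` with recall `TP/(TP+FN)`
(printed formulations occasionally repeat the precision denominator for
recall; the standard definition is used). Macro F1 averages over classes
present in the ground truth, warning about absent ones — datasets with
virtually no F or G would otherwise be dragged to zero by classes that
cannot be scored. The overlap rate is per-timestep agreement over a whole
recording; computed over the same labels, OR and overall accuracy
coincide by construction, which the tests assert.

`kfold_evaluate()` folds at the segment level by default, matching the
shuffled-segment protocol; because segments from one recording are
correlated, a `groups` argument switches to recording-level folds, which
is the stricter design when transfer matters. OR for whole recordings is
computed before the padded tail would be truncated — truncation-first is
what makes an 8 h annotation exactly 2,880,000 labels.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen for a single CPU: the end-to-end benchmark simulates
20 recordings of 30 minutes at 100 Hz (about 3,500 segments), trains
gradient-boosted trees on the 52 wavelet features of the plain Subset-1
segment database, and evaluates segment accuracy on the test split and OR
on two intact held-out recordings; grammar validity is checked on 1,000
sampled 10-minute tracks; oracle equivalences use a few hundred random
instances each. The benchmark deliberately trains without pd
oversampling: with the generator's pd density, the 17 context windows per
event would flood training with pd-labelled pure-C windows and measure
the augmentation's label noise (the well-known C/pd confusion) rather
than classifier quality; the augmentation itself is exercised and tested
separately. Reproducibility is strict: every stochastic step derives its
stream from a user seed, and repeated runs are bit-identical.

## Known limitations

* Synthetic realism is bounded by the archetypes; no claim is made about
  accuracy on real recordings of any species.
* Window-aligned aggregation cannot place boundaries inside a window, so
  short events (especially pd) are systematically missed or snapped to
  the 10.24 s grid; OR on tracks not aligned to the grid is bounded below 1
  even for a perfect segment classifier.
* The neural engine is plain R and suitable for the package's problem
  sizes, not for training at full-corpus scale.
* Variable-length segmentation and sequence-to-sequence annotators are
  out of scope.
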