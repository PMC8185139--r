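---
title: "Multimodal feature graphs for EEG + eye-tracking classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal feature graphs for EEG + eye-tracking classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazegraph)
```

## The problem and the model

Screening studies for autism spectrum disorder (ASD) increasingly record
two complementary bio-signals: resting-state EEG, which reflects internal
neural dynamics, and eye-tracking during structured stimulus tests, which
reflects overt attentional behavior. Neither signal has an explicit
sample-by-sample correspondence with the other — EEG is recorded before
the eye-tracking session, at a different rate — so fusion has to happen at
the feature level.

`gazegraph` implements a graph-based fusion. Each *sample* is one 4 s EEG
segment together with its subject's eye-tracking summary. From it we build
a 14-node graph:

* nodes 1–7: EEG features of that segment — mean amplitude (µV), STFT
  spectral entropy, mean pairwise Pearson channel correlation, approximate
  entropy, sample entropy, normalized permutation entropy, wavelet
  entropy;
* nodes 8–14: the subject's total valid fixation duration (ms) on each of
  the seven stimulus tests (native/exotic stranger faces, joint attention,
  gaze following, social interaction), repeated across all segments of
  that subject.

Node *attributes* are the (training-fold-standardized) feature values.
*Edges* are shared by all samples: on the training fold we compute the
feature covariance matrix — correlation, after standardization — and
connect features `i, j` when `|cov(x_i, x_j)| > tau`. The rationale is
that features which co-vary strongly across samples, within or across
modalities, form meaningful message-passing routes; a pair that is
uninformative about each other stays disconnected.

Per-sample graphs are batched block-diagonally, renormalized with
self-loops (`Ã = D̃^{-1/2}(Â + I)D̃^{-1/2}`), and classified by the
two-weight-matrix graph convolutional network

$$Z = \mathrm{softmax}\!\left(\tilde A\,\mathrm{ReLU}(\tilde A X W^0)\,W^1\right),$$

with cross-entropy loss over labeled nodes. Because the batch adjacency
is block-diagonal, no information flows between samples during the
forward pass — a property the test suite asserts numerically.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| segment length | 4 s, no overlap | trailing partial windows discarded |
| ApEn/SampEn embedding `m` | 2 | standard biosignal choice |
| ApEn/SampEn tolerance `r` | 0.2 × SD of the series | relative, so both entropies are affine-invariant |
| permutation entropy | order 3, delay 1 | normalized by `log(3!)` to `[0, 1]` |
| wavelet entropy | `db4`, 5 levels | Shannon entropy of relative detail-band energies |
| STFT | 1 s Hann window, 0.5 s hop | entropy over all (time, frequency) bins, channel-averaged |
| channel reduction | mean | median available via `eeg_feature_config(reduce=)` |
| fixation validity threshold | 60 ms | shorter dwells are treated as unconscious gazing |
| adjacency threshold `tau` | 0.3 on \|correlation\| | see below |
| GCN | hidden 16, lr 0.01, 200 epochs, momentum 0.9 | full-batch gradient descent |
| split | 8:2, stratified, segment-level | subject-level mode available |

None of the entropy/STFT defaults is forced by the data model; they are
conventional values, all exposed in `eeg_feature_config()` and
`pipeline_config()`.

## The synthetic cohort generator

Clinical recordings of this kind are not publicly distributable, so the
generator ships as first-class, tested code. Each group is described by a
`group_spec`; each EEG channel is an AR(1) process plus a 10 Hz in-band
oscillation plus white noise, with a shared latent AR(1) driver mixed into
all channels:

$$x_t = \phi\, x_{t-1} + A \sin(2\pi \cdot 10\, t / f_s) + \epsilon_t + w\, z_t.$$

The design gives one knob per extracted feature family: $\phi$ controls
regularity (complexity entropies), $A$ the spectral concentration (STFT
and wavelet entropies), $w$ the channel coupling (Pearson
synchronization), and the per-test fixation mean/SD the eye features.
Fixation logs contain events of at least 60 ms partitioned from a
truncated-normal per-test total, plus Poisson-rate sub-60 ms events so the
validity threshold is actually exercised. Per-subject seeds derive
deterministically from the master seed and subject index, so enlarging a
cohort never reshuffles existing subjects.

The default `default_group_specs()` cohort is *deliberately
well-separated* (each effect several pooled SDs at the subject level):
its purpose is end-to-end validation of the pipeline under conditions
where near-perfect classification is achievable, not simulation of
realistic clinical effect sizes. Directions of the contrasts: the case
group is more regular (higher $\phi$: lower approximate/sample/permutation
entropy), has a weaker 10 Hz rhythm (higher STFT and wavelet entropy),
identical coupling (no synchronization contrast), identical zero-mean
amplitude (no mean-value contrast), and shorter fixations on every test.

What the generator does *not* emulate: 1/f spectral background, artifacts
(ocular, muscular — artifact removal is out of scope), non-stationarity,
inter-subject EEG variability beyond sampling noise, saccade dynamics or
AOI geometry. Passing tests on synthetic cohorts therefore demonstrate
the correctness and calibration of the machinery, not clinical
performance.

## Numerical choices

* **Sample entropy degenerate counts.** When no template pairs match
  (`A = 0` or `B = 0`), the estimator is undefined; we return a finite
  documented cap — the log of the number of possible template pairs —
  so feature vectors never contain `NaN`/`Inf`. Constant and strictly
  periodic series yield 0 through the regular formula.
* **Approximate entropy** includes self-matches (the classical
  definition), so a constant series gives exactly 0.
* **Permutation entropy ties** are broken by order of appearance: on
  equality, the earlier sample ranks lower. A constant series is one
  pattern, entropy 0.
* **Wavelet transform.** Orthonormal periodized pyramid (`db4` default);
  series are truncated to a multiple of `2^levels`. Energy conservation
  (Parseval) is asserted in the tests against an explicit-matrix oracle.
* **Zero-energy inputs.** STFT entropy of an all-zero segment is defined
  as 0; a zero-variance channel is an error naming the channel, as is a
  zero-variance feature under standardization.
* **Softmax** is computed with the row-max subtracted; zero predicted
  probabilities at labeled classes are clamped at machine epsilon inside
  the loss.
* **Gradient scale.** Training descends on the per-labeled-node mean of
  the summed cross-entropy, which makes the default learning rate
  insensitive to batch size; the reported loss trace is the raw sum.
* **Prediction ties** go to the lower class index, deterministically.
* **Weight initialization** is seeded uniform Glorot scaling; all
  stochastic steps (splits, forest, weights) derive their seeds from the
  single pipeline seed.

## Design decisions on genuinely open points

* **`tau` and thresholding mode.** No principled universal threshold
  exists for feature-covariance graphs. We standardize features,
  interpret covariance as correlation, and default to `tau = 0.3` on the
  absolute value — treating strongly anti-correlated features as related,
  since both directions carry information. The literal "covariance
  greater than threshold" reading is available as `mode = "signed"`, and
  `edge_density_profile()` prints edge density against `tau` so users can
  match a target density.
* **Two weight matrices, one hidden representation.** The model has
  exactly two learnable matrices ($W^0$, $W^1$), i.e. one hidden layer of
  width 16 between two graph-convolution steps. Deeper variants are out
  of scope.
* **Self-loops before normalization.** Without them, isolated nodes
  (which legitimately occur at high `tau`) have zero degree and the
  normalization is undefined.
* **Node-label training, mean-pool inference.** The loss is defined over
  labeled *nodes*; we let every node of a training graph inherit the
  graph's label, and at inference average node probabilities within a
  graph before the argmax. A pure mean-pool-then-loss mode
  (`pooling = "mean_pool"`) is provided as an alternative; both are
  exercised in the tests.
* **Channel reduction by averaging.** Per-channel statistics collapse to
  one node value by the channel mean (median optional). Keeping 8
  per-channel copies would change the graph size; the 14-node design
  wants one value per feature.
* **Eye-feature ranking kept at 7.** The random-forest importance step is
  computed (on training subjects only) and reported, but the default
  `keep_k = 7` retains all features, because the 14-node graph has one
  slot per test. Lower `keep_k` shrinks the graph accordingly.
* **STFT "entropy" reading.** We take the Shannon entropy of the
  normalized magnitude-squared spectrogram over all time–frequency bins;
  other readings (per-frame entropy averaged over time) differ by little
  and are not exposed.
* **Split unit.** The default 8:2 split is segment-level and stratified,
  mirroring the common protocol in this literature. Note that
  segment-level splits put segments of the same subject on both sides;
  since eye features are constant within a subject, a model can match a
  test segment to its subject rather than to its group. The
  subject-level mode (`split_unit = "subject"`) avoids this leakage and
  is the methodologically safer choice for new studies; the statistical
  null-calibration test uses it for exactly this reason.
* **Problem sizes.** The default synthetic recording length is 60 s per
  subject (15 segments), which keeps a full 21 + 21-subject pipeline run
  in the tens of seconds while leaving every stage non-trivial; the
  generator accepts any duration (e.g. the 6 min typical of clinical
  protocols). Statistical suites use smaller cohorts: 4 s recordings for
  the 200-replicate t-test calibration, 16 s for the null-pipeline runs.

## Limitations

* Node attributes are scalars, so the GCN's first layer is a map from one
  diffused scalar per node; the architecture relies on the graph
  structure and the nonlinearity for expressiveness. This matches the
  14-node design but would be restrictive for richer node features.
* The shared adjacency is recomputed per training fold from that fold
  only; whether a published adjacency was computed on all data or
  training data is generally ambiguous, and a flagged non-default option
  would be needed to reproduce an all-data matrix.
* Synthetic-cohort accuracy (including the near-perfect default-cohort
  results the acceptance checks compute) demonstrates pipeline
  correctness under favorable, well-separated conditions and segment-level
  splitting; it is not evidence about clinical discriminability.
* EDF support covers plain continuous 16-bit EDF with one sampling rate
  across signals; EDF+ annotations are not parsed.
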