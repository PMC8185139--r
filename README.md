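# gazegraph

Joint analysis of resting-state EEG and eye-tracking recordings for
two-group classification studies — the setting is autism spectrum disorder
(ASD) screening cohorts, where neither modality alone carries enough
signal. `gazegraph` fuses the two at the *feature* level: multi-domain EEG
features and per-test fixation-duration features become the nodes of a
small **feature graph**, edges connect feature pairs whose covariance
across training samples exceeds a threshold, and a graph convolutional
network (GCN) classifies each sample's graph.

Because clinical EEG/eye-tracking cohorts are rarely public, the package
ships a seeded synthetic cohort generator with controllable group effects,
so the entire pipeline is testable and reproducible without any data
download.

## The method

**Nodes.** Each sample (one 4 s EEG segment paired with its subject's
eye-tracking features) yields a 14-node graph:

* 7 EEG features per segment — mean amplitude, STFT spectral entropy,
  mean pairwise Pearson correlation across channels (synchronization),
  approximate entropy, sample entropy, normalized permutation entropy, and
  wavelet entropy (per-channel features averaged over channels);
* 7 eye-tracking features per subject — total valid fixation duration (60
  ms validity threshold) on each of seven stimulus tests, ranked by a
  random-forest importance step.

**Edges.** Features are standardized on the training fold and the binary
adjacency is
`A(i,j) = 1  iff  |cov(x_i, x_j)| > tau` (default `tau = 0.3`; one shared
adjacency for all sample graphs).

**Classifier.** Per-sample graphs are stacked into a sparse block-diagonal
batch adjacency `Â`, renormalized with self-loops as
`Ã = D̃^{-1/2}(Â + I)D̃^{-1/2}`, and pushed through the two-weight-matrix
GCN

```
Z = softmax( Ã · ReLU(Ã X W0) · W1 )
```

trained with the cross-entropy loss `L = -Σ_{l∈y_L} Σ_f Y_lf ln Z_lf`
(every node of a labeled graph carries the graph's label). At inference a
graph is scored by mean-pooling its node probabilities.

## Worked example

```r
library(gazegraph)

specs  <- default_group_specs()                       # well-separated ASD/TD
cohort <- simulate_dataset(specs$case, specs$control,
                           n_a = 6, n_b = 6, seed = 42, duration_s = 20)
res <- run_pipeline(cohort, pipeline_config(seed = 42))
res$metrics
#> accuracy 1.0000  precision 1.0000  recall 1.0000  f1 1.0000
head(res$ttests, 5)
#>        feature statistic  p_value
#> 1   mean_value    -0.573 5.79e-01
#> 2 stft_entropy    12.429 2.45e-07
#> 3     pcc_sync     0.363 7.28e-01
#> 4      appr_en   -12.789 1.52e-06
#> 5      samp_en   -20.991 2.78e-09
```

The t-test table reports subject-level group contrasts per feature: the
synthetic case group has lower complexity entropies (negative statistics),
a higher STFT spectral entropy (its 10 Hz rhythm is weaker, so spectral
energy spreads), and — by design — no contrast in mean amplitude or
channel synchronization. On this cohort the 12 held-out segments are all
classified correctly; with 6 + 6 subjects at 20 s each the split is 48
training / 12 test samples and the shared graph keeps 66 of 91 possible
edges at `tau = 0.3`.

Single-modality ablations use the same interface:

```r
run_pipeline(cohort, pipeline_config(modality = "eeg", seed = 42))$metrics
run_pipeline(cohort, pipeline_config(modality = "eye", seed = 42))$metrics
```

A command-line front end with `simulate`, `extract-eeg`, `extract-eye`,
`build-graph`, `train`, `evaluate` and `run-all` subcommands lives at
`inst/cli/gazegraph.R` (installed under `system.file("cli", package =
"gazegraph")`).

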