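# seizegraph

Patient-specific seizure prediction from scalp EEG, with each 60 s window
modeled as a weighted graph and classified by a compact graph convolutional
network (GCN).

Seizure *prediction* (as opposed to detection) asks whether the brain is in
the **preictal** state — here, the hour ending 5 minutes before an annotated
onset, the 5 minute gap being the intervention horizon — or the
**interictal** baseline, at least 4 hours from any seizure. The package is
aimed at researchers who want a complete, inspectable, dependency-light
reference pipeline for graph-based EEG classification: every stage from raw
multi-channel recordings to cross-validated sensitivity/AUC tables is
implemented here, and a bundled synthetic-EEG cohort generator makes the
whole pipeline runnable and testable without access to clinical data.

## The model

Nodes are the 18 longitudinal bipolar derivations (Fp1-F7, F7-T7, …,
Cz-Pz). Each node carries node features — by default the six
wavelet-packet band energies (delta, theta, alpha, lower/higher beta,
gamma) plus the three Hjorth parameters (activity, mobility, complexity),
so F = 9. Edges fuse a spatial prior with a functional measurement:

    A = w_s * exp(-d_ij^2 / sigma^2) + w_f * C_ij

where `d_ij` is the geodesic (great-circle) angle between node positions on
a spherical head model and `C_ij` is the 1–40 Hz magnitude-squared
spectral coherence of the two channels in that window. Graph convolutions
use the first-order propagation rule with the renormalization trick,

    H^{l+1} = sigma( D~^{-1/2} (A + I) D~^{-1/2} H^l W^l ),

with batch normalization and LeakyReLU after each of three conv layers
(9 → 32 → 64 → 128), global average pooling over the 18 nodes, and a
fully connected head 128 → 32 → 16 → 1 ending in a sigmoid:

```
> describe_gcn()
GCNConv 1:    9 ->   32  (BN + LeakyReLU)  params 320
GCNConv 2:   32 ->   64  (BN + LeakyReLU)  params 2112
GCNConv 3:   64 ->  128  (BN + LeakyReLU)  params 8320
GlobalAvgPool over 18 nodes -> 128
FC 1:  128 ->   32  (LeakyReLU + dropout 0.50)  params 4128
FC 2:   32 ->   16  (LeakyReLU + dropout 0.50)  params 528
FC 3:   16 ->    1  (sigmoid)  params 17
total trainable parameters: 15425 (15.43 k)
```

The 15.4 k-parameter footprint is the point: the architecture targets
wearable-scale deployment rather than server-scale accuracy.

Training follows the clinical evaluation protocol: per-subject
leave-one-seizure-out cross-validation (each fold holds out one seizure's
preictal segments together with its associated interictal segments), SMOTE
oversampling of the minority class, a gradient-harmonizing (GHM) weighted
cross-entropy, Adam with learning rate 0.01 decaying 10% per epoch, and
dropout 0.5 on the fully connected head. The forward/backward passes,
SMOTE and GHM are implemented in the package (gradients are verified
against numerical differentiation in the test suite).

## Worked example

A complete experiment — simulate a cohort, preprocess, extract node/edge
features, train per-subject leave-one-seizure-out folds, evaluate — runs
from one configuration. A desk-scale version (one subject, two seizures,
short records via a scaled-down labeling config):

```r
library(seizegraph)
res <- run_experiment(list(
  seed = 7, out_dir = "runs/demo",
  synthetic  = list(n_subjects = 1, seizures_per_subject = 2,
                    record_s = 760, onset_s = 700, delta = 2, rho = 0.8),
  preprocess = list(preictal_len_s = 600, horizon_s = 60,
                    interictal_margin_s = 600),
  training   = list(epochs = 4, early_stop_patience = Inf)
))
res$summary
#>   subject n_folds sensitivity_mean sensitivity_sd  auc_mean    auc_sd
#> 1   sub01       2             0.95     0.07071068 0.9461538 0.0326357
#> 2     AVG       2             0.95     0.00000000 0.9461538 0.0000000
```

Each row summarizes one subject's folds (mean ± SD of segment-wise
sensitivity at threshold 0.5 and of ROC AUC); the `AVG` row aggregates
subjects. Here the generator's preictal signature (delta/theta band-power
tripled and inter-channel synchrony raised on the frontal channels) is
strong, so the two folds separate well even at 4 epochs: AUC 0.95 means
nearly every held-out preictal window outranks every held-out interictal
window, and sensitivity 0.95 says 95% of preictal windows exceed the 0.5
threshold.
`runs/demo/` also receives per-fold metrics, ROC points, a train/test
feature-distribution overlap report, model checkpoints and a manifest.

At full scale (the defaults: 3 subjects, 4 seizures each, 4020 s records)
the same call reproduces the package's acceptance experiment; with the
preictal effect enabled the cohort-average AUC is ≈ 1.0, and with the
effect disabled (`delta = 0`, `rho = rho0`) it stays at chance — the
null-world check that guards against record-identification leakage (see
the methods vignette).

Individual stages are exported too: `apply_bipolar_montage()`,
`filter_signal()`, `minmax_normalize()`, `label_and_segment()`,
`assemble_node_features()`, `coherence_matrix()`, `build_adjacency()`,
`train_fold()`, `roc_auc()`, `plot_chord()`, … A thin command-line wrapper
(`exec/seizegraph`) exposes `simulate`, `describe` and `run`.

## Acceptance script

`scripts/acceptance.R` recomputes the externally checkable quantities from
scratch with the installed package — it instantiates the default
architecture and counts its trainable parameters (closed form and by
enumerating the weight tensors), and applies SMOTE to a seeded 170:10
imbalanced training set and measures the resulting class ratio — then
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
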