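---
title: "Graph-convolutional seizure prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional seizure prediction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Patient-specific seizure prediction asks, for every 60 s window of scalp
EEG, whether the patient is in the *preictal* state (here: the hour that
ends 5 minutes before an annotated seizure onset — the 5 minute gap is the
prediction horizon that makes an alarm actionable) or the *interictal*
baseline (at least 4 hours from any seizure). `seizegraph` treats each
window as a weighted graph:

* **Nodes** are the 18 longitudinal bipolar derivations (double banana plus
  the midline pair). Each node carries a small feature vector; the default
  is the six wavelet-packet band energies (delta 1–4, theta 4–7.5, alpha
  7.5–13, lower beta 13–16, higher beta 16–30, gamma 30–40 Hz) plus the
  three Hjorth parameters, so F = 9. Five further feature families
  (higher-order crossings, first/second difference magnitudes, Gaussian
  differential entropy, and Higuchi/Katz/Petrosian fractal dimensions) can
  be switched in through `feature_config()`.
* **Edges** combine a static spatial prior with a functional measurement:
  `A = w_s * exp(-d^2 / sigma^2) + w_f * C`, where `d` is the great-circle
  angle between node positions on a spherical head model and `C` is the
  1–40 Hz band-averaged magnitude-squared coherence of the two channels in
  that window. There is no canonical rule for fusing spatial and functional
  edges; we default to equal weights and set `sigma` to the mean off-diagonal
  geodesic distance; both are configurable. The spatial part depends only
  on the montage and is cached across segments.

The classifier is a deliberately small graph convolutional network using
the first-order propagation rule with the renormalization trick,
`Ahat = D^{-1/2} (A + I) D^{-1/2}`, whose spectrum lies in [−1, 1] (the
package keeps the graph Fourier transform only as a test oracle for this
spectral view). Three graph-conv layers widen the node features
9 → 32 → 64 → 128, each followed by batch normalization and LeakyReLU;
global average pooling over the 18 nodes gives a 128-vector; a fully
connected head 128 → 32 → 16 → 1 with dropout ends in a sigmoid. The whole
model holds 15,425 trainable parameters — inside the 15.52 k budget that
motivates the architecture (a wearable-scale model).

The head's width sequence 128/32/16 admits two readings: a 128-wide first
hidden layer would blow the parameter budget, so 128 is read as the pooled
input width. Batch-norm scale/shift parameters
are disabled by default for the same reason (`bn_affine = TRUE` restores
them and `param_count()` tracks the difference). LeakyReLU slope (0.01),
conv biases (present), and dropout placement (after both hidden FC
activations) are free choices fixed to these common defaults.
Note that with batch normalization the conv biases are mathematically inert
(the mean subtraction cancels them); they are kept because the budget counts
them and removing them would change checkpoint shapes.

# Training protocol

Evaluation is per-subject leave-one-seizure-out: each fold holds out one
seizure's preictal segments together with the interictal segments whose
nearest seizure it is. Within a fold:

1. node-feature columns are z-scored with statistics computed on the
   training portion only (a deliberate design choice: it prevents leakage);
2. SMOTE balances the classes by convex interpolation between a minority
   sample and one of its k = 5 nearest minority neighbours, operating on
   the flattened node features concatenated with the adjacency upper
   triangle so synthesized graphs stay symmetric with zero diagonal;
3. Adam (default moments) minimizes a gradient-harmonizing (GHM-C)
   weighted binary cross-entropy: per-example gradient norms |p − y| are
   binned into 10 equal bins, bin densities are momentum-smoothed (0.75),
   and weights proportional to the inverse density are normalized to mean
   one — if every example falls in one bin the loss is exactly the plain
   mean cross-entropy;
4. the learning rate starts at 0.01 and decays by 10% per epoch; default
   50 epochs with early stop after a 10-epoch training-loss plateau
   (disable with `early_stop_patience = Inf` for bit-reproducibility).

The forward and backward passes are implemented in the package (no deep
learning framework exists in this R stack); the backward pass is verified
against numerical differentiation to 1e-4 relative tolerance in the tests.

# Numerical choices

* **Filters.** The 1 Hz high-pass is a 4th-order Butterworth, the 50/100 Hz
  notches are biquads with Q = 30; all are applied forward–backward
  (zero phase, squared magnitude response) with odd-symmetric edge padding.
  Only the cutoffs are essential to the pipeline; the realizations are the
  standard engineering choices.
* **Wavelet packets.** db4, level 6 at 256 Hz gives 64 terminal bins of
  nominally 2 Hz; periodic extension keeps the analysis orthonormal so the
  bin energies sum to the signal energy. Packet nodes reached through a
  high-pass branch cover mirrored frequency halves after decimation; the
  implementation tracks this explicitly and assigns each bin to the band
  containing its midpoint. The 7.5 and 13 Hz band edges therefore snap to
  8 and 12 Hz; the realized mapping is delta 0–4, theta 4–8, alpha 8–12,
  lower beta 12–16, higher beta 16–30, gamma 30–40 Hz.
* **Coherence.** Magnitude-squared coherence from averaged 256-sample Hann
  windows at 50% overlap, averaged over 1–40 Hz. Printed definitions of
  spectral coherence vary in where they put the squares; the standard
  magnitude-squared form is used.
* **Degenerate inputs.** Constant channels normalize to all zeros (flagged);
  zero-variance signals get Hjorth mobility/complexity 0, differential
  entropy capped at −20 nats, fractal dimensions (1, 1, 1), zero-power
  channels coherence 0 — each with a warning rather than NaN.
* **Ties.** Classification threshold 0.5 predicts ties positive; ROC/AUC
  groups tied scores, making the trapezoid AUC exactly the midrank
  Mann–Whitney statistic. Summary tables use the sample SD, with 0 for a
  single fold.
* **Hjorth/Petrosian derivatives** are plain first sample differences with
  no sampling-rate scaling; all recordings share fs = 256 Hz (other rates
  are an error, not a resampling trigger).

# The synthetic cohort: what it emulates, and what a green test shows

No clinical data ships with the package; every stage is exercised by a
generator (`cohort_spec()`, `generate_recording()`, `cohort_plan()`) whose
defaults are the package's stated experimental world:

* background: per-electrode 1/f (pink, beta = 1) noise plus a 10 Hz alpha
  rhythm realized as narrowband noise (Gaussian spectral bump, SD 0.8 Hz)
  with a slow (~20 s) log-normal power envelope — real alpha is not an
  hour-long coherent sinusoid, it drifts in phase and waxes and wanes;
  channels are weakly coupled through a shared source at mixing rho0 = 0.2
  whose per-electrode projection gain wanders slowly (1 + 0.35 x a ~60 s
  smoothed Gaussian) — the gain differences keep the shared source visible
  after bipolar differencing; finally a vigilance-like log-normal amplitude
  envelope (~40 s) modulates each whole channel;
* preictal signature, on six frontal electrodes (the four frontal montage
  nodes): delta/theta-band power multiplied by (1 + delta), delta = 1 by
  default, and shared-source mixing raised to rho = 0.6 during
  [onset − 3900 s, onset);
* ictal marker: a 30 s, 3 Hz high-amplitude burst (3 pre-clip SD);
* amplitudes are clipped at 4 theoretical SDs per channel (an
  ADC-saturation analogue) and scaled to a 50 µV-like unit.

Two generator decisions exist purely to keep the *null* world (delta = 0,
rho = rho0) honest under per-recording min-max normalization, which divides
every channel by its realized extreme value: (i) the clip pins raw-channel
extremes, and (ii) interictal records share the seizure-record duration
(4020 s), because the expected extreme of the *filtered bipolar* signal
grows with record length and unequal lengths would leak the record kind —
hence the label — into every amplitude feature. The ictal burst stays below
the background extremes so it never sets a record's range.

The timeline places one record per seizure (onset at 3960 s, so the full
preictal hour plus horizon fits) and one interictal record per seizure,
4 h after its offset and strictly nearer to it than to the next seizure.
A leave-one-seizure-out fold therefore holds out two *whole* records.

A methodological note worth spelling out, because it shaped several
generator decisions: with per-recording min-max normalization and only a
handful of records per subject, *any* per-record constant — a fixed alpha
phase pattern, fixed source-projection gains, the record's realized extreme
value, an asynchronous ictal burst that sets the range — becomes a record
fingerprint. A classifier trained on segments then learns to recognize
records instead of brain states, which inflates fold AUCs (we observed a
perfect null-world AUC from exactly this before the fixes). The generator
therefore (i) holds out whole records per fold, (ii) uses narrowband,
phase-incoherent alpha, wandering source gains and the vigilance envelope
so that would-be per-record constants become within-record variation, and
(iii) gives the ictal discharge one channel-common phase so it cannot set
the bipolar range. The same failure mode — segment-wise evaluation
rewarding record identification — is a well-known hazard in clinical EEG
benchmarks; the null-cohort check exists to catch it.

A green end-to-end test therefore establishes that the pipeline detects a
*band-power plus synchrony* contrast of the stated size under stationary
1/f background — and nothing more. Real scalp EEG adds artifacts (EMG, eye
movement, electrode pops), non-stationary drift between recording sessions
(the distribution-overlap report exists to quantify exactly this), montage
and annotation inconsistencies, and genuinely variable preictal
physiology. The generator makes no physiological-realism claim; it gives
both node features (band energy, Hjorth) and edge features (coherence)
discriminative signal because those are what the method consumes.

Desk-scale reductions used by the test suite, not by the defaults: the
end-to-end checks run at 20 epochs and thin interictal windows 2:1
(`interictal_stride`), both compute reductions that leave the labeled world
unchanged.

# Known limitations

* LOOCV leaves out one *seizure*, not one recording file; subjects with a
  single seizure are rejected rather than silently evaluated.
* Cross-file timelines must be supplied by the caller (`start_s`); preictal
  spans that straddle file boundaries are dropped whole, so a seizure
  contributes its complete hour or nothing.
* Event-based alarm metrics (false predictions per hour, horizon analysis)
  are out of scope; evaluation is segment-wise sensitivity and AUC.
* The EDF and HDF5 containers common in this field are replaced by
  plain-text equivalents (16-bit-quantized CSV + JSON sidecar; RDS caches),
  as no reader for the binary formats is available in this R stack.
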