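---
title: "Detecting error-related potentials from 2D EEG images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting error-related potentials from 2D EEG images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errpnet)
```

## The problem

An error-related potential (ErrP) is the event-related EEG response elicited
when feedback contradicts a person's expectation — for instance when a
brain–computer interface (BCI) executes the wrong command. Generated in the
anterior cingulate cortex, it appears on frontocentral scalp channels as a
triphasic complex: a positive deflection near 200 ms after feedback, a large
negative deflection near 250 ms, and a second positive deflection near
320 ms, strongest at FCz and attenuating toward neighbouring electrodes.
Detecting the ErrP on a single trial allows a BCI to catch and undo its own
mistakes, but single-trial EEG is dominated by background activity, and the
channels that carry the signature differ in reliability.

`errpnet` addresses this with three ingredients: a waveform-to-image
encoding that turns each single-trial channel trace into a small picture, an
attention CNN that classifies the picture, and a learned stacking ensemble
that fuses the per-channel decisions.

## The processing model

### Preprocessing

The chain is fixed in order — common average reference, band-pass, optional
ICA, epoching, normalization — and `preprocess()` records its settings in
the result.

* **Common average reference** subtracts the instantaneous mean across
  channels; it is idempotent and removes common-mode noise.
* **Band-pass**: a Butterworth filter designed by bilinear transform,
  applied forward and backward (zero phase; offline analysis permits
  non-causality). *Defaults: 1–10 Hz, order 3.* The low edge removes drift,
  the high edge keeps the sub-10-Hz energy where the triphasic complex
  lives. The upper band edge is configurable because sources in this
  literature differ on the exact value; the run metadata records what was
  used. Filtering starts from steady-state initial conditions, so even a
  pure DC input produces essentially zero output with no start-up transient.
* **ICA** (optional, off by default for clean synthetic data): a symmetric
  FastICA decomposition; a component is rejected when its time course
  correlates above 0.7 in absolute value with a 0.5–2 Hz low-passed frontal
  reference (mean of FZ/F1/F2). Blinks are frontal and slow, so this
  criterion targets the ocular subspace; the correlation threshold and the
  reference are both package choices, since no published criterion exists
  for this step.
* **Epoching** cuts −0.2 s to +0.8 s around each feedback event (512 samples
  at 512 Hz). Including 0.2 s of pre-stimulus baseline lets the classifier
  see stimulus onset. Events too close to a recording edge are dropped with
  a warning — never zero-padded, which would fabricate waveform shape.
* **Min–max normalization** maps each (trial, channel) trace to [0, 1]. The
  per-trial, per-channel scope is forced by the next stage: each trace
  becomes one image, so each trace must individually fill the image's
  amplitude axis. A constant trace (zero dynamic range) maps to 0.5 — a
  mid-gray horizontal line — with a warning, keeping rendering defined.

### Waveform images

`render_trace_image()` draws the normalized trace as a 224 × 224 binary
image: time maps left-to-right across all columns, amplitude bottom-up over
all rows, and the polyline between consecutive samples is rasterized with
1-pixel Bresenham segments. Trace pixels are 0, background 255, and nothing
else — no axes, no margins, no anti-aliasing. A plotting library would
produce intermediate gray values at the line edges; exact binarization is
the cleaner realisation of the black-line-on-white-page description, and is
documented here as a choice rather than claimed identical to any particular
plotting toolchain. An optional `baseline_row` parameter instead pins the
mid-amplitude value to a fixed row, mimicking plots whose origin sits
mid-axis, for compatibility experiments.

### The attention CNN

Four identical modules — 3 × 3 convolution (stride 1, same padding), ReLU,
batch normalization, 2 × 2 stride-2 max pooling — with 8, 16, 32 and 64
filters take the 224 × 224 × 1 input through 112²×8, 56²×16, 28²×32 and
14²×64. The published layer table places batch normalization *after* the
activation; this is unconventional (BN usually precedes the nonlinearity)
but is implemented faithfully. Same padding is likewise forced: it is the
only padding under which the table's preserved spatial sizes are
reproducible.

After the last pool, a convolutional block attention module (CBAM) refines
the 14 × 14 × 64 feature map. Channel attention pools the map globally by
average and by maximum, pushes both vectors through a shared bottleneck MLP
(reduction ratio `r`, ReLU between the layers), sums, and squashes with a
sigmoid; the resulting per-channel weights multiply the map. Spatial
attention then averages and maxes across channels, convolves the two planes
with a 7 × 7 kernel, and applies the sigmoid-squashed result per position.
Because every weight lies in (0, 1), the block can only attenuate:
|output| ≤ |input| element-wise, an invariant the tests assert.

The classifier head flattens the 14 × 14 × 64 map to 12 544 features and
applies fully-connected layers 12544 → 896 → 64 → 2 with ReLU and dropout
between the hidden layers and a softmax output (error / no error).

*Parameter defaults and why:*

| parameter | default | rationale |
|---|---|---|
| reduction ratio `r` | 16 | standard CBAM setting (bottleneck 4 at width 64); unstated in the source architecture, configurable |
| dropout | 0.5 after each hidden FC layer | the usual heavy-regularisation choice for large FC layers; rate unstated; none after the output layer |
| BN stabilizer `eps_bn` | 1e-5 | framework convention |
| input side | 224 px | fixed by the architecture table |

### Loss and training

Targets are label-smoothed **asymmetrically**: `y' = (1 − ε) y` with
ε = 0.1, exactly as printed in the source formulation — a positive label
becomes 0.9 while a negative label stays 0. Symmetric smoothing
(`y' = ε` for negatives) is available behind a flag but off by default; no
claim is made about which variant the original authors' code used. The loss
is the mean binary cross-entropy of the error-class softmax output against
the smoothed target, with predictions clamped at 1e-7 for stability.

Training uses Adam from lr₀ = 0.001 under a single non-restarting cosine
schedule `lr(t) = ½ lr₀ (1 + cos(π t / T))` over `T = max_epochs = 100`
(the "decay to zero" reading; restarts are the other possible reading and
were rejected as the less common one). The minority class of the *training
split only* is oversampled with replacement to parity — validation and test
distributions are never touched. Early stopping monitors the validation
loss with patience 20 and an improvement tolerance of 1e-5, and the weights
of the best validation epoch are restored on stop (the source protocol does
not say whether final or best weights were kept; best-weight restoration is
standard practice and is this package's choice). Batch size defaults to 32
and the train/validation split to a seeded stratified 80/20; both are
package choices where the protocol is silent.

One numerical subtlety is worth recording: inference-time batch
normalization uses exponential moving averages of the batch statistics
(momentum 0.1). Initialized at mean 0 / variance 1, these averages are
strongly biased toward their initialization during short trainings, which
measurably corrupted desk-scale runs. The running averages are therefore
debiased exactly as Adam debiases its moment estimates (division by
1 − 0.9ᵗ). With frozen learning rate (lr₀ = 0) the running statistics are
frozen too, so that "no learning" leaves the model genuinely unchanged.

### Multi-channel stacking

Each channel in the configured group gets its own expert CNN. Fusion is
two-stage stacked generalization: the training set is split into five
stratified folds; for every fold, per-channel models trained on the other
four folds predict the held-out fold; the assembled out-of-fold hard
predictions (an N × n binary matrix) plus the true labels form the
meta-dataset. A three-layer meta network — n inputs, ⌈n/2⌉ hidden ReLU
units, one sigmoid output thresholded at 0.5 — learns the fusion rule.
Hard 0/1 meta-features follow the published formulation ("binary
variable"); a probability mode exists but is off by default. For odd n the
"half" hidden width rounds up. After meta-training, the fold models are
discarded and one final base model per channel is retrained on the full
training set for use at prediction time (standard stacking practice; the
alternative — reusing fold models — is not described in the source and
retains k times the memory).

The baseline is majority voting: label 1 iff strictly more than half the
channels vote 1. Read strictly, a tie on an even channel count is *not*
"more than half", so ties go to the negative class; the canonical 9-channel
group D cannot tie. Majority voting weighs every channel equally and can
only express linear (threshold) fusion rules; the meta network can learn
non-linear interactions, and the test suite demonstrates the separation on
a constructed XOR scenario.

Channel groups: group D (F1, FZ, F2, FC1, FCZ, FC2, C1, CZ, C2) is
enumerated in the source; group A (FCz + Cz) is the classic pair. Groups B,
C and E are documented reconstructions growing the frontocentral grid
outward (3, 5 and 15 channels) and every function also accepts an explicit
channel vector, so the reconstructions are conventions, not constraints.

## The synthetic generator

`simulate_epochs()` / `simulate_recording()` produce the stated world the
tests run in:

* **Template**: sum of three signed Gaussian bumps at 200/250/320 ms with
  amplitudes +3, −6, +4 µV and widths 15/18/20 ms. No quantitative
  amplitudes are published for this waveform (figure axes only), so the
  amplitudes are free parameters chosen to look like a typical feedback
  ERP; the widths are narrow enough that the composite waveform's extrema
  stay on the nominal latencies despite bump overlap.
* **Topography**: gain 1 at FCz decaying as `exp(−d/0.35)` in schematic
  electrode-grid distance, zero beyond radius 0.8 (occipital channels see
  nothing). This matches the qualitative "weakens away from FCz"
  description; the decay constant is configurable.
* **Noise**: per-channel mixture of 1/f (pink) and white Gaussian noise,
  default half-and-half, SD 6 µV — putting the single-trial template peak
  at SNR ≈ 1 at FCz, a realistic regime. Desk-scale end-to-end tests use
  SD 2 µV (SNR 3) so that small training budgets suffice.
* **Labels**: i.i.d. Bernoulli(error rate); the emulated monitoring
  paradigms used 20% and 30%.
* **Artifacts** (optional): 0.3–1 s half-sine blink transients on frontal
  channels, for exercising the ICA stage.
* **Determinism**: a single seed streams all randomness, with per-trial
  sub-streams so that toggling artifacts or extending the trial count never
  perturbs earlier trials' noise.

What the generator does **not** emulate: real EEG spectra (alpha rhythms,
line noise), non-stationarity across a session, trial-to-trial latency
jitter of the ErrP, volume-conduction correlations between channels beyond
the shared template, and the visual paradigms themselves beyond their error
rates. A green end-to-end test therefore establishes that the pipeline
recovers a known frontocentral triphasic signature from realistic noise at
the stated SNR — not that any particular accuracy would be reached on real
recordings.

## Numerical and engineering choices

* The network forward/backward passes exist twice: a pure-R double-precision
  reference implementation, validated against nested-loop oracles of every
  equation and against central finite differences, and a fused
  single-precision RcppArmadillo engine used for actual training (one C++
  call per mini-batch: im2col + GEMM convolutions, fused BN/pool, CBAM, FC,
  Adam). The engines are tested to agree (inference within 1e-5; identical
  step loss within 1e-5). Dropout draws from R's RNG inside the engine, so
  results are reproducible under `set.seed()` regardless of backend.
* Max-pool backward routes gradients to the stored argmax; channel-max
  pooling in CBAM does the same across channels. Ties take the first
  maximum, deterministically.
* Epoch containers are plain text (TSV + JSON sidecar) and images export as
  plain-text PGM; no binary formats anywhere, and EDF support was left out
  because no EDF reader exists in the supported dependency set.
* Degenerate inputs have defined behaviour throughout: constant traces
  normalize to 0.5; a single-class meta training set yields a constant
  predictor with a warning; undefined sensitivity/specificity (zero
  denominators) are reported as `NA` with a warning, never silently 0.

## Known limitations

* Real-data performance is untested by construction; the published
  real-dataset numbers are not reproducible offline and are not claimed.
* The per-channel experts are independent CNNs; correlations between
  channels are exploited only at the decision level, not at the feature
  level.
* Training is CPU-bound and single-threaded; at full scale (100 epochs,
  nine channels, five folds) a desk run takes hours, which is why the test
  suite uses reduced budgets and documents them.
* The 1D reference variant of the classifier and transfer learning across
  sessions are out of scope.
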