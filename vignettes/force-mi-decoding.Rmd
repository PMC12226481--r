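---
title: "Decoding motor imagery of force-intensity variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery of force-intensity variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fnssir)
```

## The problem

A motor-imagery (MI) brain-computer interface that only distinguishes
*which* limb a user imagines moving can issue directional commands, but
rehabilitation robotics also needs *how much force* the user intends. When a
person imagines a movement whose force varies within a single trial — large
to medium, large to small, or medium to small (the three classes LMF, LSF
and MSF) — the EEG carries graded, partially overlapping signatures:

* **Event-related desynchronization (ERD).** Alpha (8–13 Hz) and beta
  (13–30 Hz) power over the contralateral sensorimotor cortex (electrode C3
  for right-limb imagery) drops below the pre-imagery baseline. Both the
  depth and the duration of the drop, and its spatial extent on the scalp,
  grow with the imagined force.
* **Movement-related cortical potentials (MRCP).** A slow negative
  deflection over frontocentral sites begins roughly 0.5 s after MI onset
  and peaks near 1 s; larger imagined force yields a larger negativity. It
  is a low-frequency, low-SNR signal that only becomes visible after trial
  averaging.

The paradigm modelled here presents two 5-s MI segments separated by a 2-s
preparation gap; a trial's class determines the force level of each segment
(LMF = large then medium, LSF = large then small, MSF = medium then small).
Epochs span 12 s from the first MI onset, preceded by 2 s of context so a
−2..0 s spectral baseline is available; trial-level baseline correction uses
the final pre-onset second. There are 42 trials per class (126 per subject)
at 100 Hz after preprocessing.

## The decoder

The classifier is a three-branch feature-fusion network trained end to end
with Adam (learning rate 0.001, batch size 7) and cross-entropy loss.

**Electrode plane.** The montage is embedded in an `H x W` grid (9 x 9 by
default) so 3D convolutions can exploit true neighbourhood topology: grid
rows follow the anterior-posterior 10–20 rows (Fp..O), columns the lateral
positions. Vacant cells inside the montage's convex hull are filled by
distance-based interpolation — inverse-distance weights over the `k = 4`
nearest electrodes — and cells outside the hull are zero. A trial becomes a
`1 x H x W x T` volume.

**Multi-scale spatial-temporal branch (MSSTCN).** Two units, each running
three parallel same-padded 3D convolutions with kernels (3,3,3), (5,5,5)
and (7,9,7) over (height, width, time). Small kernels capture local
electrode detail, large ones global spatial-temporal trends. Outputs are
batch-normalised per convolution, concatenated channel-wise, passed through
ReLU and average pooling ((3,3,5) after unit 1, (3,3,10) after unit 2), and
dropout (p = 0.5) follows the second pooling stage, as in the reference
layer table. With the 9 x 9 x 1200 input the plane collapses to 1 x 1 and
the time axis to 24 steps of 48 features (default 8/16 filters per branch).

**Convolutional auto-encoder branch (CAE).** Six electrodes spanning the
frontocentral/sensorimotor strip (FC3, FCz, FC4, C3, Cz, C4) are min-max
scaled to [0, 1] per trial and channel and passed through two (1,3)
convolutions with ReLU + (1,2) max pooling, then two (1,4) stride-(1,2)
transposed convolutions (ReLU, then sigmoid), restoring the original
length. The optional reconstruction term `lambda * MSE(recon, target)` uses
the ≤ 5 Hz low-passed input (on the same [0, 1] scale) as the target, which
gives the branch its denoising interpretation: the decoder output
emphasises exactly the MRCP band. The decoder output is split into the same
number of windows as the MSSTCN steps, each flattened (6 channels x window
length), to form the second sequence.

**LSTM with self-attention (LSTM-SA).** One LSTM per branch (40 units for
the spatial-temporal sequence, 80 for the auto-encoder sequence); per-step
concatenation gives 120 features, transformed by single-head scaled
dot-product self-attention (`softmax(QK'/sqrt(d)) V` with learned Q/K/V
projections, d = 120), flattened and classified by a fully connected layer.
The attention stage lets the classifier reweight time steps per trial,
absorbing individual differences in ERD onset and duration.

**Ablations.** `ablate()` removes one branch: without MSSTCN the CAE
sequence alone feeds LSTM-SA (attention width 80); without CAE the
spatial-temporal sequence alone (width 40); without LSTM-SA both sequences
are flattened straight into the classifier and the model has no recurrent
parameters.

## Readings of under-specified details

Several architectural details are not fixed by the reference description;
the package's choices are:

* Filter counts per 3D convolution (absent from the layer table): 8 per
  branch in unit 1 and 16 in unit 2, configurable.
* Same padding on all 3D convolutions, so the three branch outputs have
  equal extents and can be concatenated.
* The CAE electrode list names FC3 twice in the source description; the
  symmetric reading FC3/FC4 is used.
* Batch normalisation is applied per convolution (as in the layer table);
  since BN acts per channel this is the same partition as normalising the
  concatenation. Dropout appears once, after the second pooling stage.
* LSTM-A consumes the MSSTCN sequence and LSTM-B the CAE sequence; the
  attention width 120 is read as the concatenation 40 + 80.
* Transposed convolutions use stride (1,2) and padding (0,1), the unique
  choice that exactly doubles the time axis with a (1,4) kernel.
* A conv bias feeding training-mode BN is retained for structural fidelity
  even though its gradient is identically zero (BN absorbs it).

## The synthetic generator

`generate_dataset()` is a forward model of the paradigm's signatures, not a
biophysical simulation. Per trial it adds, on `1/f` Gaussian background
noise (RMS 5 uV, exponent 1):

* alpha (10 Hz, RMS 8 uV at C3) and beta (24 Hz, RMS 4 uV) carriers with a
  Gaussian spatial profile centred at C3 (sigma 2.5 grid cells), whose
  amplitude is multiplicatively suppressed during each MI segment. The
  suppression depth in power dB is −6/−4/−2 for large/medium/small force at
  C3, decaying spatially with force-dependent sigma (2.2/1.8/1.4 cells);
  its duration is the force-dependent fraction 1.0/0.8/0.6 of the segment,
  with 0.25-s raised-cosine edges.
* a raised-cosine MRCP transient per segment, onset 0.5 s and peak 1.0 s
  after the segment onset, peak −8/−5/−3 uV by force, centred spatially
  between FCz and C3 (sigma 2.2 cells).
* per-trial Gaussian onset/duration jitter (SD 0.1 s, clipped at ±0.3 s);
  `simulate_subjects()` adds subject-level onset shifts (SD 0.2 s) and
  duration scaling (SD 10%) for cross-subject protocols.

ERD is multiplicative amplitude suppression — matching the ERSP definition
of a power decrease relative to baseline — rather than an additive signal.
The oscillation amplitudes were chosen once so that the alpha carrier
dominates the in-band background at C3 (about 15 dB); with weaker carriers
the recovered ERD would be biased shallow by the noise floor. The injected
depths are not claims about real effect sizes; they are configurable study
conditions, and `effect_ground_truth()` echoes them for recovery tests.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction beyond smooth Gaussian topographies, non-stationary background
rhythms, electrode drift, or realistic cross-channel noise correlation.
Passing the bundled benchmarks therefore demonstrates that the pipeline
recovers the signatures it targets under controlled conditions — not that
any particular accuracy will be reached on real recordings.

## Analysis choices

* **Spectral estimator.** Complex Morlet wavelets implemented as
  frequency-domain Gaussians with unit gain at the centre frequency and
  `cycles = max(3, f/2)`; above 6 Hz this is a constant 2-Hz bandwidth, so
  broadband noise gives a flat profile across 8–30 Hz. Signals are
  mirror-padded by 1 s; the first/last 0.5 s remain the least reliable.
* **ERSP.** Trial-mean instantaneous power converted to
  `10 log10(P(f,t) / mean_baseline P(f))` with baseline −2..0 s (the raw
  power is available behind a flag). dB relative measures are invariant to
  global amplitude rescaling.
* **MRCP.** ≤ 5 Hz zero-phase FIR low-pass, per-class trial average,
  baseline corrected to the pre-onset mean.
* **Filters.** All FIRs are Hamming windowed-sinc designs applied with
  exact zero phase (symmetric taps, group delay compensated, reflection
  padding); the bandpass transition width defaults to the low edge.
  Downsampling applies an anti-alias low-pass at 80% of the new Nyquist
  before decimation.

## The scaled-down decoding benchmark

`benchmark_model_config()` defines the configuration used by the bundled
decoding benchmark and the acceptance script: an 18-channel sensorimotor
montage on a 6 x 6 plane, inputs anti-alias decimated to 25 Hz (T = 300;
alpha and MRCP survive, the 24-Hz beta carrier does not), 2/4 filters per
branch, pools (3,3,5)/(2,2,10) (six LSTM steps), and single-precision
convolution arithmetic. These sizes are the package's own choice of a
desk-scale problem: one 100-epoch training run takes on the order of a
minute on one CPU, so a full stratified 4-fold cross-validation with
repeats, a label-shuffle control, and the branch ablations can all be run
routinely. The compact montage fills its grid without vacant in-hull cells,
so the interpolation machinery is exercised by the default 9 x 9
configuration and its tests rather than by the benchmark.

On this benchmark the interesting contrasts are fine-grained: LMF and LSF
share the large-force first segment and differ only in the second segment's
medium-versus-small force (2 dB of alpha ERD, 1 s of ERD duration, 2 uV of
MRCP), so ceiling accuracy is not expected.

The benchmark training protocol uses `lambda_recon = 1` (the package-wide
default stays 0.1): at desk scale the auto-encoder's reconstruction
otherwise converges too slowly for the branch to contribute within 100
epochs. Branch ablations are evaluated on a 300-trial freshly generated
test set so the comparison is not dominated by the 3%-per-trial counting
noise of a 32-trial split. An empirical caveat worth stating plainly:
under these scaled synthetic conditions, removing the spatial-temporal
branch collapses the decoder to chance and removing the LSTM/attention
stage consistently costs several points, but removing the auto-encoder
branch does not measurably hurt — the MRCP-band information it denoises is
also available to the 3D-convolutional branch from the raw plane, so the
auto-encoder's value only emerges at full scale and realistic noise, not
in this reduced setting.

## Numerical and reproducibility notes

* All randomness (generator, fold assignment, weight init, shuffling,
  dropout) is seed-controlled through private RNG scopes that restore the
  caller's state; identical seeds give bitwise-identical datasets and loss
  traces.
* Stratified folds deal each shuffled class round-robin, so per-class fold
  counts differ by at most one; fold disjointness is asserted on every run.
* The repeated-CV report exposes both the maximum repeat mean (the
  optimistic convention) and the grand mean; the latter is recommended.
* Argmax ties in evaluation break toward the lowest class index.
* The paired t-test refuses zero-variance differences and attaches an
  advisory Shapiro-Wilk normality warning rather than a gate.
* Batch-norm uses batch statistics in training and running statistics at
  inference; with full-batch training, zero learning rate and no dropout
  the loss trace is exactly constant, which the tests exploit.

## Known limitations

* No EOG/artifact removal is included; real recordings must be cleaned
  upstream (the optional EDF import is deliberately minimal).
* The electrode coordinate table is the schematic equal-angle 10–20
  construction, adequate for grid building and spatial profiles but not a
  measured digitisation.
* Single-head attention only; multi-head variants and pretrained weights
  are out of scope, as are the comparison baselines (CSP+SVM, EEGNet and
  relatives).
* Training is CPU-only and single-threaded; the default-size model
  (9 x 9 x 1200, 8/16 filters) trains slowly at full scale and is intended
  for method study rather than high-throughput experiments.
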