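---
title: "Contrastive representation learning for auscultation audio: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive representation learning for auscultation audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SoundCLR)
```

# The problem

Labelled heart- and lung-sound recordings are scarce because annotation
requires clinical expertise, while unlabelled recordings accumulate
cheaply from digital stethoscopes.  SoundCLR implements a contrastive
self-supervised framework for this setting: an encoder is pre-trained on
unlabelled spectrograms so that "positive" pairs of views land close in
an embedding space and other in-batch views ("negatives") land far, and
the resulting representation is then evaluated on a binary
normal-vs-abnormal diagnosis task with a small labelled subset.

Two families of positive pairs are supported.

* **Augmentation schemes** (`split`, `time_mask`, `freq_mask`,
  `spec_mask`, `spec_mask_split`): the two views are independent
  stochastic transforms of one recording's spectrogram.
* **Metadata schemes** (`pos_sim_age`, `neg_sim_age`, `neg_sim_sex`,
  `neg_sim_age_sex`, `pos_same_loc`, `pos_dif_loc`,
  `pos_same_loc_neg_same_loc`): the two views are two *different
  recordings of the same patient* — no augmentation — optionally
  constrained by auscultation location, and, for the `neg_*` schemes,
  with batch generation modified so that every batch member shares the
  negative-selection trait (age band, sex, their combination, or
  location).  Sharing the trait makes the in-batch negatives *harder*:
  the anchor must be distinguished from patients that resemble it on
  exactly the attribute that correlates with disease.

# Objectives

Projected embeddings are compared with cosine similarity at temperature
$T$ (default 0.5).  For an anchor $i$ with a single positive $j$ and
candidate set $A(i)$ (all other views in the batch), the NT-Xent loss is

$$\ell_i \;=\; -\log\frac{\exp(\mathrm{sim}(z_i,z_j)/T)}
{\sum_{a\in A(i)}\exp(\mathrm{sim}(z_i,z_a)/T)}.$$

When a weak label admits several positives $P(i)$ (scheme
`pos_sim_age`, with the age band as the weak label), the
supervised-contrastive form averages the similarity ratios **inside**
the logarithm:

$$L_i \;=\; -\log\Bigl\{\tfrac{1}{|P(i)|}\sum_{p\in P(i)}
\exp(\mathrm{sim}(z_i,z_p)/T)\,\big/\,
{\textstyle\sum_{a\in A(i)}\exp(\mathrm{sim}(z_i,z_a)/T)}\Bigr\},$$

which reduces exactly to NT-Xent when $|P(i)|=1$.  The batch loss is the
mean over all $2B$ anchors (both views of a pair serve as anchors).
Both losses and their exact analytic gradients (including the Jacobian
of the row normalisation) are implemented in `contrastiveLoss()`; the
test suite checks them against independent term-by-term scalar oracles
and against central finite differences.  The monotonicity property that
motivates metadata negatives — raising any negative's similarity
strictly raises the loss — is asserted numerically.

# Spectrograms and the pad/crop rule

Waveforms are transformed with a Hann-window STFT followed by a
triangular mel filterbank and log compression
(`10*log10(power + 1e-10)`).  Window, hop and mel-band count are
configurable (`stftConfig()`); the full-scale default is a 25 ms window,
10 ms hop and 64 mel bands, and the desk-scale front end
(`deskStft()`) uses 64 ms / 32 ms / 32 bands so that whole experiments
run in minutes.

Recording lengths vary widely, so all spectrograms are centre
padded/cropped to a common frame count: the 75th percentile of the
cohort's frame-count distribution (linear-interpolation quantile,
rounded half-up).  Conventions are fixed for bit-reproducibility: an odd
padding deficit puts the extra zero frame on the right, an odd cropping
excess drops the extra frame on the right.  The `Spectrogram` class
records `padLeft`/`padRight` exactly, defining the *data region*;
every augmentation is confined to it and padding cells are never
modified.  The quantile is applied to spectrogram frame counts rather
than raw durations (equivalent up to hop size, and the frame count is
what the model consumes).

# Masking calibration

Band counts follow the stated scheme — five time bands, two frequency
bands — but band widths and an overlap policy have to be chosen.  Bands
are placed independently and uniformly at random (overlaps allowed), and
widths are calibrated so the *expected* masked fraction of the data
region hits the 50% target.  For $k$ bands of integer width $w$ on an
$n$-cell axis the expected union coverage (edge effects included) is

$$C(w,k,n) = \frac1n\sum_{c=1}^{n}\Bigl[1-\bigl(1-\tfrac{m_c}{n-w+1}\bigr)^k\Bigr],
\qquad m_c = \min(c, n{-}w{+}1)-\max(1, c{-}w{+}1)+1,$$

which `calibrateBandWidths()` inverts over integer widths on a reference
grid (64 × 200 by default).  For combined time-and-frequency masking the
per-axis coverage $a$ solves $a + a - a^2 = 0.5$ (so
$a = 1-\sqrt{0.5} \approx 0.293$), and the integer widths bracketing the
balanced solution are searched for the pair whose exact combined
coverage $A + B - AB$ is closest to the target.  The 50% target is
applied per scheme (time-only, frequency-only, and combined each target
50%), and the two views of a positive pair use independent augmentation
draws.  A Monte-Carlo check over 1,000 random spectrograms recovers the
target within ±2 percentage points (the acceptance script reports this
number).

# Networks

The encoder contract is pluggable (`registerEncoder()`); the bundled
desk-scale backbone `tiny_cnn` is two 3×3 same-padding convolutions with
ReLU and 2×2 max pooling, followed by per-(row, channel) **time-pooled
mean and max** statistics and a linear map to the embedding (length
`N`, default 32 at desk scale).  Time pooling makes the embedding
invariant to *where* in a recording an acoustic event falls, which
matters because transient adventitious sounds occur at arbitrary
offsets.  A full-scale residual backbone can be registered by the user
under its own key; requesting an unregistered key is an error naming the
available backends.  All forward/backward passes are implemented in
plain R and verified against hand-unrolled oracles and finite
differences.

Three heads sit on the encoder:

* a linear **projection head** to the contrastive space (length 256 at
  full scale, 32 at desk scale), used only during pre-training;
* a single sigmoid unit (**linear evaluation**) trained on frozen
  embeddings — encoder weights are bit-identical before and after, which
  the tests assert;
* the two-layer **SSL online evaluator** (linear `N→N`, batch
  normalisation, ReLU, linear `N→1`, sigmoid) trained end-to-end with
  the encoder for fine-tuning.  Batch statistics are used in training
  (a batch of one is an error), running statistics in evaluation.

# Training pipelines and hyper-parameters

The `"full"` profile of `runConfig()` carries the full-scale settings:
batch size 16, learning rate 1e-5, L2 penalty 1e-6 (pre-training) and
1e-2 (downstream), 5,000 linear-evaluation epochs, 25 fine-tuning
epochs, 500/1,000 baseline epochs for heart/lung data, and 20 or 5
parallel replicate models at the 10%/100% label fractions.  The
optimiser is not named at full scale; Adam is used with the L2 penalty
added to the gradient, and this choice is recorded in the config.  No
early stopping or schedule is applied; the validation split is reserved
for monitoring.

The `"desk"` profile is the package's own reduced configuration, sized
for one CPU: the compact encoder, learning rate 1e-3, 60 pre-training
epochs, 400 linear-evaluation epochs, 200 baseline epochs, and a
**separate fine-tuning learning rate of 2e-4**.  The smaller fine-tuning
rate is the desk-scale analogue of the full-scale regime, where a single
very small rate (1e-5) serves all pipelines: end-to-end fine-tuning
updates pretrained features and a freshly initialised evaluator head
together, and an aggressive rate lets the head's initial gradients
destroy the pretrained features before the head becomes informative.  At
full scale both rates coincide.

"Trained in parallel" replicate models are implemented as independent
replicates with distinct seeds whose AUROCs feed the paired comparison.
Splits follow the published arithmetic: class-balanced test and
validation sets (200 + 200 each at full scale), the remainder as the
pre-train set, and a class-balanced fine-tune subset drawn *within* the
pre-train set — the pre-train set is consumed unlabelled, so this
containment leaks nothing into the held-out sets.  Because of that
containment, the split-hygiene assertion checks that test and validation
never intersect anything else, rather than literal four-way
disjointness.

# Evaluation

AUROC uses the Mann–Whitney form with ties counted one half.
Uncertainty comes from a percentile bootstrap (1,000 replicates, 2.5/97.5
percentiles); replicates that lose a class are redrawn and counted, with
a warning above a 10% redraw rate.  The percentile method is the
simplest consistent with a plain "bootstrapped CIs" description; BCa was
deliberately not used.  Model pairs are compared with a classical paired
t test; the pairing unit is the bootstrap replicate on a shared test set
(the same resample indices for both models), with per-replicate-model
pairing available as an alternative when parallel models are trained.
Zero-variance differences are an explicit error rather than an infinite
statistic.

# The synthetic cohort

`cohortSpec()` defines the benchmark generator.  Its defaults are the
package's study conditions and were fixed once:

* **120 patients**, 40% children, 50% female, three recordings per
  patient at locations drawn (with replacement) from the seven-site
  vocabulary, so repeat sites occur as in real respiratory databases.  120 patients keeps every age×sex cell large enough to
  fill trait-constrained batches of 16.
* **Label model**: logit(p) = −1.2 + 1.8·child + 0.6·female, mirroring
  cohorts in which childhood (and, more weakly, sex) correlates with
  abnormality.  This is the correlation the metadata-negative schemes
  exploit.
* **Acoustics**: every recording is a harmonic stack at a
  patient-specific fundamental (110–190 Hz) under a slow breathing
  envelope, plus a patient-specific tone (300–550 Hz, shared across the
  patient's recordings and scaled by `patientEffect`), a fixed
  location-specific spectral tilt, a random per-recording gain
  (probe-pressure variation), and white noise.  **Abnormal** recordings
  gate the harmonics into crackle-like bursts at a patient-specific rate
  (6–10 Hz) with raised-cosine edges.  The gate is applied as a
  *zero-mean log-amplitude envelope*, so the mean log-power of every
  spectrogram cell matches the sustained (normal) class exactly and the
  class difference lives in temporal texture rather than pixel level.
  `signalEffect` (default 0.8) interpolates the gating depth; at 0 the
  classes are acoustically identical.
* **Durations** are log-normal (median 2 s, σ = 0.35 on the log scale),
  right-skewed so the 75th-percentile rule both pads and crops.

This construction realises the gap the method needs: a logistic model on
flattened spectrogram pixels sees (in expectation) no per-pixel mean
difference between classes and stays near chance at desk-scale label
budgets, while the burst texture is readily captured by a convolutional
encoder — and, crucially, patient discrimination under the
metadata-negative schemes *requires* texture, because the narrow pitch
ranges prevent the contrastive task from being solved by pitch alone.
Narrow fundamental ranges are also the physiologically realistic choice.

What the generator does **not** emulate: real adventitious sound
morphology (crackle/wheeze waveforms), inter-site recording-device batch
effects, heart-cycle structure, multi-class diagnoses, or label noise.
Passing the benchmark therefore shows that the pipelines implement the
method's mechanics and orderings, not that they reach any particular
performance on real auscultation data.

# Numerical and degenerate-input choices

* Band widths round half-up; a band as wide as the data region is
  saturation (allowed), wider is an error.
* The split augmentation keeps `floor(D/2)` frames (minimum 1), with the
  offset uniform over all admissible starts, and re-centres the result
  so batch tensors stay rectangular.
* Softmax computations subtract the row maximum before exponentiation.
* Chained-equation imputation runs five sweeps of per-field multinomial
  regressions (age band and sex at patient level, location at recording
  level), initialised at the per-field mode; a patient with no observed
  metadata receives the mode outright, and a field missing for the whole
  cohort is an error.  Ties in the mode break deterministically in
  sorted order.
* All stochastic components consume the R session RNG; every pipeline
  seeds it from its `RunConfig`, so a checkpoint plus its config
  reproduces a run exactly.

# Desk-scale problem sizes

The test suite and the worked examples use the benchmark cohort (120
patients, 360 recordings), reserved sets of 60 + 60 recordings, a
40-recording labelled fine-tune subset, five replicate seeds for the
ordering comparisons, 1,000 bootstrap replicates for intervals, 1,000
Monte-Carlo draws for masking coverage, and 500 simulations for bootstrap
coverage — sizes chosen so the complete suite runs on a single CPU in
minutes while keeping the sampling error of each check well inside its
assertion band.

# Known limitations

* The bundled backbone is deliberately small; nothing in the package has
  been demonstrated on real heart/lung datasets, and full-scale claims
  are out of its scope.
* Percentile bootstrap intervals are slightly anti-conservative for
  AUROC at small test sizes.
* The chained-equation imputer uses only the three metadata fields as
  predictors of one another; with richer metadata a dedicated
  imputation package would be preferable.
* Batch sampling is with replacement across batches (within-batch
  patients are distinct), so an "epoch" is a step count, not a
  permutation of patients; small trait cells could not fill batches of
  16 otherwise.
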