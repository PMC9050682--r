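---
title: "Methods: simulation and inference in attnmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and inference in attnmvpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`attnmvpa` is a pipeline for time-resolved decoding of feature-based
attention from EEG, built so that every stage can be validated end to end
on synthetic data with a known ground truth. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and the design decisions that were genuinely open — in enough detail that a
reader can judge what a passing test suite does and does not establish.

## The experimental design being emulated

Each stimulus overlays blue and orange line gratings at fixation. The four
analysable orientations are 22.5°, 67.5°, 112.5° and 157.5°; the two
colours are always rotated 45° from one another, which yields exactly eight
stimulus types and — crucially — makes the cued and uncued orientations
orthogonal: whichever orientation pair the classifier discriminates, the
other colour's orientation is exactly balanced across the two classes
(`audit_fold_orthogonality()` asserts the exact count equality in every
training fold).

A sequence contains 104 analysable non-target presentations, exactly
balanced over ISI (13 frame-locked values in the varied condition, one in
the constant condition) × 8 stimulus types. One or two target events
(the 0°/90° task orientation in the cued colour) and one or two foils (the
same orientation in the uncued colour) are inserted at uniformly chosen
non-adjacent positions, each wrapped in 3 + 4 padding presentations, with 4
more padding presentations at each sequence boundary; everything but the
104 non-targets is excluded from analysis. A session holds 64 sequences,
counterbalancing cued colour (2) × target orientation (2) × ISI condition
(2) × event counts (4) exactly twice each. Stimulus duration is 100 ms
(6 frames at 60 Hz); all timing lives on the integer frame grid internally
and is only converted to milliseconds at the interface, so no floating-point
drift can accumulate along a sequence.

Two points the design source leaves open were resolved as follows. Padding
stimuli are drawn *without replacement within each padding block* (blocks
have at most 4 elements, so this is always feasible, whereas drawing
without replacement across all padding of a sequence would be impossible —
there are more padding draws than stimulus types). Event positions are
uniform over the interior gaps of the non-target stream, subject to
non-overlap; sessions smaller than one 32-cell replicate (used only for
miniature fixtures) take a prefix of a cell ordering arranged so any prefix
remains near-balanced over ISI condition and cued colour.

## The forward model

The simulator is deliberately simple plumbing with a precisely stated
structure, not a biophysical claim:

- **Spatial patterns.** Each orientation has a fixed channel pattern: four
  seeded Gaussian random vectors, orthogonalised (QR) and unit-normalised.
  Target/foil orientations (0°, 45°, 90°, 135°) get their own four patterns;
  they matter only through response overlap, as those trials are excluded.
- **Temporal kernel.** A raised-cosine bump supported on [80, 400) ms,
  peaking at 170 ms. The 80 ms onset mirrors the earliest latencies at
  which orientation information typically becomes decodable; the support
  makes at most two presentations overlap at a 300 ms onset asynchrony.
- **Attention gain.** Before the divergence latency τ (default 230 ms after
  each stimulus onset) the cued and uncued orientations of a presentation
  carry identical gain 1 — the ground truth of *equal early coding*. From τ
  the cued orientation carries `g_att` (default 1.0) and the uncued
  `g_unatt` (default 0.4). A step rather than a ramp is the simplest
  mechanism that produces a detectable onset; both the latency and the
  gains are configurable.
- **Gain handoff at the next onset.** The modulation applies only while a
  presentation is the most recent one: at the next stimulus onset the
  residual response reverts to the common gain. This mirrors the view that
  each new stimulus captures processing (the masking logic inherent to
  rapid serial designs), and it is what makes the ground truth clean:
  without the handoff, the attention-modulated tail of every presentation
  leaks into the *following* epochs, where the sequence-level exact balance
  induces weak dependencies between neighbouring labels, and the classifier
  picks up a small (~1%) spurious cued–uncued difference at pre-τ
  timepoints. With the handoff, no analysis window contains attention
  information about any stimulus other than its own.
- **Noise.** Spatial covariance from a rank-8 random factor model plus a
  diagonal, normalised to unit channel variance; temporal AR(1) with
  φ = 0.95; `noise_sd` is the stationary per-channel SD. The defaults
  (amplitude 1 µV, `noise_sd` 3 µV) were calibrated once, by a sweep over
  `noise_sd` ∈ {1.5, 3, 5, 8}, so that peak pair-averaged decoding lands in
  the 60–80% range typical of published EEG decoding; they were not
  adjusted afterwards.
- **Between-participant variability.** Per-participant amplitude drawn from
  Normal(1, 0.25) truncated at zero, plus independent patterns and noise
  covariance per participant. 0.25 is a generic moderate heterogeneity
  choice; nothing downstream is sensitive to it except the width of
  group-level intervals.

What the simulator does *not* emulate: eye and muscle artefacts, electrode
drift, volume-conduction structure of a real head, latency jitter across
trials, or any systematic difference between ISI conditions (the forward
model is ISI-independent by construction, so the expectation contrast is a
true null in simulation). Passing tests therefore demonstrate that the
*analysis* behaves correctly under its stated assumptions — not that real
EEG satisfies those assumptions.

## Preprocessing

The chain is: Hamming-windowed FIR band-pass 0.1–100 Hz on the continuous
1000 Hz recording → average re-reference → downsample to 250 Hz →
epoch −100 to 800 ms (226 timepoints). Numerical specifics:

- FIR design is windowed-sinc with the common transition-bandwidth
  convention min(max(cutoff/4, 2 Hz), cutoff), length 3.3/Δf, forced odd;
  filters are applied zero-phase in a single delay-compensated pass with
  zero padding at the edges. The 0.1 Hz high-pass is 33,001 taps at
  1000 Hz — its ±16.5 s response is why filtering happens on the continuous
  recording, never on epochs.
- The high-pass and low-pass kernels are combined by convolution and
  applied as one FFT multiplication. The pipeline wrapper
  `preprocess_recording()` additionally folds the anti-alias low-pass of
  the downsampling step into the same kernel and evaluates only every 4th
  output sample via spectral folding (subsampling in time is aliasing in
  frequency). This is algebraically identical to the sequential operation
  chain except within one anti-alias filter half-width (~66 ms) of the
  recording edges; the simulator's lead-in and tail keep all epoch windows
  away from that region, and a test asserts agreement with the sequential
  chain to ~1e-10 on the resulting epochs.
- No baseline correction: with 200–400 ms onset asynchronies the
  pre-stimulus window contains the previous presentation's response, so a
  baseline would inject structured signal. Epoch windows of successive
  stimuli overlap by design; leave-one-*sequence*-out cross-validation is
  what prevents any train/test contamination from that sharing.

## Decoding

Per timepoint, features are the channel vector at that sample. The
classifier is two-class LDA with the pooled within-class covariance
(unbiased, n−2 denominator) shrunk by `λ·mean(diag(S))·I`, λ = 0.01 — the
convention of the MVPA toolbox family this pipeline follows; the exact
constant is not critical and all acceptance properties are
λ-insensitive. If the covariance is exactly zero (noise-free synthetic
corner), an absolute 1e-12 ridge keeps the solve defined. Folds are
sequences; accuracy is pooled over folds (with balanced folds this equals
the mean of fold accuracies). The per-timepoint, per-fold loop runs in
C++ (RcppArmadillo), using per-sequence sufficient statistics subtracted
from totals; a pure-R reference implementation (`fit_predict_lda()`) is
exported and the tests require exact agreement between the two, plus
agreement with an independently hand-coded closed-form oracle.

Each physical epoch is used once in a cued-orientation task and once in an
uncued-orientation task (same trials, orthogonal labels); the two analysis
groups are averaged, giving a 50% chance level. Derived contrasts follow
the analysis plan: attention effect = cued − uncued per ISI filter;
expectation effect = constant − varied averaged over roles; interaction =
the attention effect's varied − constant difference.

## Group inference

For each timepoint, the group sample is the per-participant accuracy
(against 0.5) or paired difference (against 0). The Bayes factor compares
the point null against a Cauchy(0, 0.707) prior on the standardised effect
size with the interval (−0.5, 0.5) excluded — half-Cauchy (positive tail
only) for all directional contrasts, both tails for the interaction. The
integral over the truncated prior is computed by adaptive quadrature after
the substitution δ = 0.5 + u/(1−u), to relative tolerance 1e-8; a fixed-grid
Simpson oracle in the tests bounds the error at 1e-6. One numerical subtlety:
R's noncentral t density carries an absolute error floor of roughly 1e-12,
which ruins relative accuracy when the data strongly oppose the prior (t far
on the wrong side of the excluded interval). Whenever the dt-based integral
falls below 1e-4 the package recomputes it with a log-space density derived
from the chi scale-mixture representation of the noncentral t, which is
relatively accurate at any magnitude. Onsets are
the second of the first two consecutive post-stimulus timepoints with
BF₁₀ > 10, exactly the sustained-evidence rule of the underlying analysis
tradition; evidence categories use the conventional 1/10, 1/3, 3, 10
thresholds. Confidence intervals are percentile bootstrap over participants
(default 10,000 resamples, seeded).

One behaviour worth knowing: per-participant *differences* of
cross-validated accuracies are heavier-tailed than the t model assumes, so
isolated single-timepoint BF₁₀ spikes (occasionally above 10) occur under
the null at a rate of roughly 1–2% of timepoints — we measured this
directly on noise-only simulations. This is a property of decoding
statistics generally, and it is precisely why the onset rule requires two
consecutive suprathreshold points: in our null runs the spikes are
isolated and no onset is ever declared by chance in the large majority of
replicates. Single-timepoint Bayes factors near threshold should be read
with this in mind.

## Parameter recovery and problem sizes

The end-to-end validation simulates 20 participants × 16 sequences at 32
channels (a size chosen to exercise the full pipeline while keeping the
suite fast): the detected attention-effect onset falls within τ ± 40 ms of
the simulated 230 ms divergence (232 ms in the runs reported by the test
suite), at least 90% of timepoints in [0, τ − 40] show BF₁₀ < 3, and with
equal gains no onset is detected in at least 9 of 10 replicate runs at the
same size. The chance-level calibration
(`scripts/acceptance.R`) uses 10 participants × 8 sequences with the
signal amplitude set to zero and recovers the 50% chance level to well
within two Monte-Carlo standard errors.

## Known limitations

- The simulator's gain step and handoff are idealisations; real attention
  effects presumably ramp and interact with masking in more graded ways.
  Recovered onsets inherit the kernel's shape near τ.
- The expectation contrast is a designed null here; the pipeline can detect
  ISI-condition differences but the generator never produces any.
- The Bayes factor treats accuracies as approximately normal across
  participants; see the heavy-tail note above.
- Exact FIR lengths of any particular lab pipeline differ; none of the
  package's conclusions depend on them.
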