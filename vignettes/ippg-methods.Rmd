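---
title: "Methods: contactless pulse extraction and PRV analysis with ippg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless pulse extraction and PRV analysis with ippg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ippg)
```

## The measurement model

Imaging photoplethysmography treats every skin pixel of a face video as
a weak optical pulse sensor: with each cardiac cycle the dermal blood
volume rises, absorption increases, and the reflected intensity drops
by a fraction of a percent.  Averaging over the skin pixels of a face
region concentrates this tiny modulation into a three-channel trace
`c0(t) = (r0(t), g0(t), b0(t))`, with the green channel carrying the
largest pulsatile amplitude.  All downstream analysis is built on that
trace; the single substantive question is how to combine the three
channels into one pulse signal in the presence of illumination drift
and motion, and how faithfully pulse-rate-variability statistics
derived from that signal track a contact reference.

## ROI and trace extraction

The face is localized as the largest connected skin-coloured blob and
followed with a Kanade–Lucas–Tomasi tracker: Shi–Tomasi corners are
selected inside the initial box, displaced frame-to-frame by iterative
Lucas–Kanade flow, and the box translates with the median displacement.
When fewer than half of the seeded corners survive, the face is
re-detected and the corners re-seeded; if that also fails the last
valid box is carried forward and the frame flagged, rather than
aborting a whole recording for one bad frame.

Skin pixels are classified by the classical combined rule in three
colour spaces simultaneously — RGB inequalities, a hue interval, and
CbCr chrominance bounds.  The published bounds for this family of skin
models are defaults; every threshold is exposed in
`skin_thresholds()` because the literature varies and no single set is
canonical.  The channel mean is taken after eroding the mask by 2 px:
pixels at the skin boundary mix skin and background colour in
proportions that depend on sub-pixel face position, so leaving them in
modulates the spatial mean with motion rather than with blood volume.

Choices here follow the practical constraints of the problem: the
whole-face rectangle is used as ROI (forehead-only regions are often
occluded by hair), boxes are 0-based and half-open, and channel order
is R, G, B regardless of the container's native order.

## Preprocessing

Each raw channel passes through three linear stages:

* **Smoothness-priors detrending.**  The trend is
  `(I + λ² D₂ᵀD₂)⁻¹ z` with `D₂` the second-difference operator,
  solved sparsely; subtracting it removes constants and ramps exactly
  while leaving the pulse band intact.  `λ = 300` puts the implied
  high-pass corner near 0.06 Hz at 30 fps — an order of magnitude below
  the slowest admissible pulse (0.65 Hz).  The corner frequency scales
  with the sampling rate, so `λ` is exposed in `filter_config()`.
* **Moving average**, 5 samples at 30 fps (≈ 0.17 s): suppresses
  frame-rate noise while remaining shorter than the 4 Hz pulse-band
  period.  Edge windows shrink symmetrically instead of padding, which
  would fabricate edge trends.
* **Band-pass**, zero-phase (forward–backward) Butterworth of order 4
  over 0.65–4 Hz (39–240 bpm).  The residual numerical DC of
  finite-length filtering is subtracted so the chain output is exactly
  zero-mean.

The chain is linear by construction, a property the test suite asserts
directly (`chain(αx + βy) = α·chain(x) + β·chain(y)`).

## The eight extraction methods

GRD and AGRD are fixed channel combinations; AGRD normalizes each
channel by its raw counterpart and scales by the Euclidean norm of the
raw channels (the printed source formula squares that norm, which we
read as a typo — a squared norm would give the signal intensity-squared
units).  CHROM and POS project onto chrominance combinations that
cancel intensity-like distortions and tune the residual with the ratio
of running standard deviations over trailing 1.6 s windows; the first
window's values are reused for the initial samples, and windows with a
degenerate denominator produce zero output with a warning.  This
package implements the running-std formulations exactly; the original
overlap-add variants are out of scope.

PCA and ICA decompose the standardized channel matrix (principal
components; deflationary fixed-point ICA with the cubic nonlinearity,
tolerance 1e-6, up to 500 iterations, seeded and retried from three
alternative initializations before erroring).  LE builds a mutual
k-nearest-neighbour graph (k = 9, Mahalanobis metric with the
covariance estimated from the whole trace, binary edge weights) and
takes the generalized Laplacian eigenvector of the second-smallest
eigenvalue.  SPE refines a random one-dimensional map by stochastic
pair updates with a learning rate decreasing linearly from 1.0 to 0.01
over 20 cycles of 10·T steps.  Two numerical safeguards matter in
practice: the Mahalanobis whitening floors the covariance spectrum at
1e-6 of its largest eigenvalue (noise-free traces are numerically
rank-1, and unregularized whitening amplifies floating-point residue
into a meaningless metric), and the LE neighbour count grows
geometrically until the graph connects, with the final k logged.

For every decomposition the pulse component is the one whose
periodogram peak lies inside the pulse band with the largest ratio of
in-band peak power to total component power (ties go to the lower
index).  Because decompositions are sign-ambiguous, all outputs are
oriented against the negated green channel — green is pulse-down in
reflection, so systolic peaks end up pointing upward.  LE and SPE
embeddings keep the temporal order of samples; the embedding coordinate
indexed by frame number is the pulse signal.

## Postprocessing

The extracted signal passes through: (1) an adaptive two-step wavelet
filter — a Morlet CWT (centre frequency 6, 32 log-spaced scales
covering 0.5–5 Hz) is weighted by a Gaussian window in scale (SD one
octave) centred on the per-sample energy ridge averaged over a 15 s
running window, the weight map is then smoothed with a second Gaussian
along time (SD 2 s), and the signal is rebuilt by delta reconstruction;
(2) the same band-pass as preprocessing (the band is reused, 0.65–4
Hz); (3) empirical mode decomposition (Cauchy stop criterion SD < 0.3,
at most 10 siftings per mode and 10 modes) with selection of the mode
whose spectral peak is in band — when none is, the band-passed input
passes through unchanged with a warning; (4) a final moving average.
None of the wavelet parameters is canonical; all are exposed with the
defaults above.

## From pulse signal to PRV features

Systolic peaks are local maxima whose *topographic prominence* (height
above the higher of the two saddles separating them from higher
neighbours) exceeds 0.3 × the rolling 90th-percentile amplitude over
10 s, at least 0.25 s apart (the 4 Hz ceiling).  Prominence rather than
raw height is essential: the dicrotic bump rides more than 0.25 s
behind the systolic peak at slow pulse rates and would otherwise be
counted as a beat.

Interbeat intervals deviating more than 30% from the running
five-interval median, or outside 250–1540 ms, are treated as ectopic
and replaced by cubic-spline interpolation — a documented, deterministic
approximation of interactive artifact-correction tools, not a clone of
any.  More than 20% flagged intervals aborts with a corrupt-signal
error.

Time-domain features use the N−1 variance convention throughout; PR is
the mean of the instantaneous `60000/NN` (per-interval rate averaged,
matching the definition of the average PR as the mean of per-cycle
inverse durations).  The triangular index uses the conventional 1/128 s
histogram bin; TINN minimizes the squared error of a bin-aligned
triangular fit by exhaustive search.  Frequency features spline-resample
the NN series at 4 Hz on the beat-time axis and integrate a Welch
spectrum (Hann, ≤ 32 s segments, 50% overlap) over 0.0033–0.04,
0.04–0.15 and 0.15–0.4 Hz; the VLF band is taken from the feature
definition table (0.0033 Hz lower edge) rather than the looser "below
0.04 Hz" phrasing, and is flagged unreliable for recordings shorter
than ~300 s, which cover barely one VLF cycle.  TINN is reported in ms
(the feature-table unit); sources quoting values near 0.035 for TINN
are implicitly in seconds.  Poincaré SD1/SD2 use the exact
rotated-coordinate identities; a zero SD2 yields an undefined (`NA`)
ratio, not an error.

## Agreement statistics

Across subjects, each feature is compared between estimate and
reference by Spearman rank correlation (average ranks for ties,
two-sided p), range-normalized RMSE, and Bland–Altman bias with
`± 1.96·SD` limits of agreement (the 1.96 constant exactly, not a
t-quantile; N−1 SD).  Pairs with an undefined member (e.g. SD1/SD2 on
a constant series) are dropped pairwise with a recorded count.  A
one-sample Kolmogorov–Smirnov check against a fitted normal is provided
to justify the nonparametric choice; because its parameters are
estimated from the same sample it is conservative and is reported as a
diagnostic, not a formal test.

## The synthetic-data generator

The generator emulates a webcam acquisition of a seated adult: 30 fps,
8-bit RGB, about one minute.  Intervals follow
`NN_i = 60000/PR + a_LF sin(2π f_LF t_i) + a_HF sin(2π f_HF t_i) + ε_i`
with defaults `PR = 72` bpm, LF mode (0.1 Hz, 40 ms) in the Mayer-wave
band, HF mode (0.25 Hz, 25 ms) at a typical respiratory rate, and
white jitter of 10 ms — values in the middle of resting-adult HRV
ranges.  The waveform is a two-Gaussian beat template (systolic peak at
30% of the cycle plus a dicrotic bump), time-scaled per interval, which
keeps the ground-truth peak location unambiguous.  Channels couple the
pulse negatively (more blood, more absorption) with green-dominant
gains (0.4, 1.0, 0.6) intensity units, on a skin-tone baseline
(200, 140, 110) that satisfies the default skin thresholds.

Sensor noise defaults to SD 0.05 intensity units *at the trace level*:
per-pixel sensor noise of a few intensity units is attenuated by
spatial averaging over the ~4·10³ skin pixels of a typical face ROI
(`3/√4000 ≈ 0.05`).  A slow two-tone illumination drift (amplitude 2)
and optional step-like motion events (identical offsets on all
channels — exactly the distortion POS/CHROM are designed to reject)
complete the model.

Truth bookkeeping distinguishes the *realized* series from the
*ensemble*: for a given finite series the true SDNN is, by definition,
the standard deviation of its intervals, and that is what
`generate_nn()` reports as truth; the closed-form ensemble expectations
(`a²/2` variance per sinusoidal mode, jitter variance spread uniformly
to the beat Nyquist) are reported separately as `*_expected`, and the
two agree within a few percent at 300 beats — an agreement the test
suite checks as a calibration property.

What the generator does *not* emulate: real skin reflectance spectra,
photorealistic appearance, non-rigid facial motion, compression
artifacts, and illumination colour changes.  Passing tests demonstrate
correctness of the algorithms under the stated acquisition model, not
performance on any particular real dataset.

## Problem sizes and determinism

Validation runs use 60 s recordings at 30 fps (1800 samples) for the
extraction chain, 250 s NN series (~300 beats) for PRV recovery, and
10 s rendered clips (160×120 px) for the video path — sizes at which
every property of interest is already expressed.  All stochastic
components (jitter, sensor noise, ICA initialization, SPE pair
sampling) are seeded; identical seeds give bit-identical results, and
changing only the seed changes noise realizations but not ground-truth
structure.

## Known limitations

* The blob-based face detector assumes a single face on a non-skin
  background; cluttered scenes need an external detector feeding
  `track_face()` directly.
* The Lucas–Kanade tracker is single-level (no pyramid) and handles
  the moderate translations of seated subjects, not fast head motion.
* One-minute recordings make VLF power statistically fragile (flagged
  in the output) and push LE/SPE towards their small-sample regime.
* Beat times are quantized to the frame grid; at 30 fps this adds
  ~`1/(30·√12)` s of uniform timing noise per peak, which inflates the
  purely short-term features (RMSSD, SD1) while leaving PR and the
  slower features (SDNN, LF power) nearly untouched.  Higher frame
  rates or sub-frame peak interpolation would reduce it; the package
  reports what the frame grid supports.
* The ectopic-correction rule is deliberately simple and deterministic;
  it is not a replacement for interactive beat editing in clinical
  work.
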