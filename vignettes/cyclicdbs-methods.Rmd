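---
title: "Methods: quantifying cortical after-effects of cyclic beta-band DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cortical after-effects of cyclic beta-band DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Deep brain stimulation of the subthalamic nucleus at beta frequencies
(10-30 Hz), applied cyclically (5 s ON, 3 s OFF), modulates cortical beta
oscillations recorded at the MEG sensor level. Two questions drive the
analysis this package implements:

1. Does the stimulation **boost** cortical beta power in the stimulated
   hemisphere, and does the boost **outlast** each stimulation train (an
   after-effect), or is it mere electromagnetic artifact (which vanishes
   the moment the stimulator switches off)?
2. Is the boost an **induced response** (a power increase without phase
   alignment to the pulse train) or **entrainment** (phase-locked
   oscillation at the stimulation frequency)? The two make different
   predictions: entrainment raises intertrial coherence and tracks the
   stimulation frequency; an induced response does neither.

The package couples this electrophysiological question to behavior: a
finger-tapping task whose tap rate is tested against the hemispheric
balance of beta power.

## Core quantities

**Lateralization index.** For band-limited power aggregated over a
left-hemisphere sensor region of interest (ROI) and its mirror image
across the posteroanterior midline,

    LI = (Left - Right) / (Left + Right),

positive when the left (stimulated) hemisphere dominates. The index is
dimensionless, confined to [-1, 1], antisymmetric under hemisphere
exchange, and invariant under global power rescaling; the test suite
checks all three properties.

**After-effect spectra.** The immediate post-train window is 5-160 ms
after the last pulse; the 5 ms margin keeps the pulse artifact out. A
155 ms segment has the natural discrete-Fourier grid k / 0.155 s =
k x 6.45 Hz, which is why the after-effect LI is reported on bins at 6.45,
12.9, 19.4, 25.8, ... Hz and why a beta effect spans bins k = 2-4
(12.9-25.8 Hz). Segments are Hann-tapered; the taper suppresses the edge
discontinuity left by residual evoked fields at the window start. The mean
removed before tapering is the *taper-weighted* mean: this removes exactly
the DC component the taper would otherwise reintroduce, and gives zero
weight to the (artifact-prone) edge samples.

**Normalized LI.** The after-effect LI minus the LI of the DBS-OFF
baseline recording, processed identically except that epochs are cut as
consecutive 7 s segments (there are no train offsets to align to; 7 s
matches the duration of the offset-aligned epochs).

**Morlet transform.** Power and intertrial coherence (ITC) come from
convolution with complex Morlet wavelets on a 5-60 Hz, 1 Hz grid.
"Wavelet length" is a fixed temporal support in seconds at *every*
frequency (Gaussian sigma = length / 6, support about +/- 3 sigma), not a
fixed cycle count. The fixed support is what makes the leakage argument
work: with 300 ms wavelets, activity confined to the ON period cannot
reach samples later than 150 ms after the offset, which is why the
statistical windows start at 0.155 s. Wavelets are zero-mean corrected
(essential below ~8 Hz at 300 ms length) and unit-energy normalized;
outputs within half a wavelet of an epoch edge are flagged invalid and
excluded from statistics. ITC is the magnitude of the trial-mean unit
phase vector; bins with zero magnitude are excluded, bins with fewer than
two trials flagged.

## Statistics

**Cluster-level paired test.** Per-channel paired t statistics between a
post-offset window mean (T1: 0.155-0.31 s, T2: 0.31-0.465 s, T3:
0.465-0.62 s; band 10-23 Hz) and the stimulation-pause mean (0.155-2.845
s), thresholded at the two-sided paired-t critical value at alpha = 0.05
(the threshold is configurable; the choice is conventional, not
data-driven), clustered by sensor adjacency, with cluster mass the sum of
member t values. The null is the maximum |mass| over subject sign flips:
exhaustive when 2^n <= 16384, Monte Carlo otherwise with
p = (b + 1) / (m + 1) so p is never zero. Clusters are spatial-only
within each window — each window's mean map is tested separately — and
BH-FDR is applied across the window x condition family. Two pause-window conventions are in circulation for this protocol
(0.155-2.845 s and 0.275-2.725 s); the package defaults to the former and
both are configurable.

**tmax test.** The normalized LI per frequency bin is tested against zero
with a one-sample sign-flip permutation t test; family-wise error across
bins is controlled by the null distribution of the maximum |t|. With
exhaustive enumeration the smallest attainable two-sided adjusted p is
2 / 2^n (sign flips come in +/- pairs of equal |t|). The group test runs
on session-averaged profiles; per-condition testing is available by not
averaging.

**Mixed models.** The LI-by-frequency model is
`normalized_li ~ dbs_frequency + (1 | participant)`, REML, with a
Satterthwaite F test (lme4/lmerTest). A singular fit (zero participant
variance) falls back to the fixed-effects one-way ANOVA, which is also
the closed-form verification anchor of the test suite. Tap counts use a
Poisson GLMM with log(exposure / 60) offset (so effects live on the
taps/min scale), DBS state coded ON = +0.5 / OFF = -0.5, sum-coded
frequency factor, their interaction, and a participant random intercept;
each term is tested by a type-III likelihood-ratio chi-square (full model
versus the model with that term's design columns removed, all other
columns kept). ROI selection replaces the visual sensor
screening used in practice with a deterministic criterion: a left channel enters the ROI when its
pulse-locked evoked amplitude (peak 5-30 ms post-pulse) exceeds 4 noise
SDs, the noise reference being an identically constructed average over
pulse-free pause windows.

## The synthetic generator

No public recordings accompany the protocol, so every stage is verified
by parameter recovery on synthetic cohorts. Per channel the generator
sums:

- **aperiodic background**: Gaussian 1/f^1.5 noise (slope typical of
  sensor-level cortical spectra below 40 Hz), flattened below 0.5 Hz,
  RMS 4.5;
- **narrowband beta**: band-pass filtered Gaussian noise, 15 +/- 2 Hz,
  one coherent source per hemisphere, RMS 1 per unit amplitude. With
  these defaults the beta peak rides a factor ~2-4 above the background
  at 15 Hz, a typical sensorimotor signal-to-background ratio. Filtered
  noise (4th-order Butterworth, applied forward and backward, realized
  spectrally) rather than a sinusoid keeps the beta envelope and phase
  stochastic, so the ITC-based entrainment discrimination is non-trivial;
- **pulse artifact**: 1-sample biphasic impulses at the stimulation
  frequency during ON phases, projected onto posterior right "wire path"
  channels (emulating the subcutaneous cabling topography), amplitude 75;
- **evoked fields**: a compact gamma-shaped kernel (peak ~6 ms, smoothly
  zero by ~18 ms, amplitude 10) on the left sensorimotor channels after
  every pulse. Cortical DBS-evoked responses are over within tens of
  milliseconds; keeping the kernel inside ~18 ms also keeps the tapered
  after-effect segment clean, which is the same role the 5 ms margin of
  the analysis window plays;
- **response**: in *induced* mode the left-ROI beta envelope is
  multiplied by 1 + A exp(-t / tau) after each train offset (A = 0.6,
  tau = 0.15 s, so the power boost falls below the background by roughly
  400 ms); in *entrainment* mode a decaying sinusoid at the stimulation
  frequency is added instead, phase-continuous with the final pulse. The
  response term is strictly post-offset; a separate `on_gain` parameter
  boosts left beta *during* ON phases and is used for tapping-session
  simulations, where the behavioral coupling needs a during-stimulation
  effect.

Cohorts draw per-subject after-effect gains from N(0.6, 0.35) truncated
at zero. The large spread (CV ~ 0.6) encodes the strong between-patient
heterogeneity of stimulation responses that any cross-subject
brain-behavior correlation implicitly relies on. Baseline hemispheric
asymmetry is drawn as a baseline LI ~ N(0, 0.1) mapped to per-hemisphere
amplitudes at constant total power.

**Tapping.** Seven blocks of 10 s red (withhold) + 15 s green (tap as
fast as possible). Inter-tap intervals are gamma renewals with shape 4 —
real repetitive tapping is considerably more regular than a Poisson
process — at rate `base - coupling x LI(state)` with base 120 taps/min
(about 2 taps/s, typical for fast index-finger tapping), between-subject
SD 15, and coupling 20 taps/min per unit LI. With the default gains this
yields a mean DBS-induced slowing of order 10 taps/min, the same order as
published observations. The renewal process restarts at segment
boundaries, which costs (shape - 1) / (2 shape) of a tap per segment;
the count-recovery test accounts for this small deficit. For the type-I
calibration of the Poisson count model, intervals are switched to
exponential (shape 1), the generative match of the model under test;
shape-4 counts are underdispersed and make the Poisson test conservative.

**What the generator does not emulate.** Volume conduction and field
spread (channels are either coherent within a hemisphere or independent),
environmental interference and its tSSS removal, eye/muscle/cardiac
artifacts beyond a simple amplitude-burst model, head movement, tremor,
electrode localization, and any biophysics of the basal ganglia. Passing
recovery tests therefore demonstrates that the *analysis chain* is
correct and calibrated under the stated signal model — not that the model
captures every property of patient MEG.

## Numerical choices

- Time windows are closed on the left, open on the right, in seconds.
- Segment spectra require an integer sample count for the 155 ms window;
  the working sample rates are multiples of 200 Hz. The package default
  simulation rate is 1000 Hz; all analysis parameters are in seconds, so
  results are rate-independent.
- Exhaustive sign-flip enumeration is used up to 2^14 = 16384 flips
  (n <= 14 subjects); beyond that, seeded Monte Carlo.
- Exhaustive permutation p values include the identity flip, making them
  exact multiples of 1 / 2^n; Monte Carlo p values use (b + 1) / (m + 1).
- The 16 Hz condition is excluded from the 14-18 Hz tapping-band analysis
  (its artifact falls inside the band); ON-state tapping power starts
  0.5 s after train onset to skip stimulator transients.
- Degenerate inputs: LI with zero total power is flagged NA; trial
  rejection refuses to drop more than half the data; empty ROIs raise an
  error advising a threshold reduction; mirror maps refuse non-bijective
  pairings.

## Problem sizes used in verification

Unit tests run single subjects at 200 Hz with 2-4 channels per
hemisphere and 6-60 trains. The cohort-level recovery checks use the
protocol's condition-defining values — 14 subjects, 480 s resting blocks
(60 trains), A = 0.6, tau = 0.15 s, 50 replicate cohorts for the
after-effect recovery and its null — with 2 channels per hemisphere
(ROI and mirror), one or more stimulation conditions per cohort as each
check requires, and 100 simulations for the tap-rate model recovery and
calibration. The persistence check averages 14 subjects at doubled beta
amplitude ("high SNR") because the ~400 ms bound concerns the
group-average time course. These sizes are the package's verification
design; all are configurable.

## Known limitations

- Sensor-space only; no source modeling, no forward model.
- The ROI criterion is deterministic but threshold-dependent; at very low
  evoked-field SNR it returns an empty ROI rather than guessing.
- The after-effect persistence estimate depends on the noise floor of the
  averaged power trace (the crossing time of a decaying exponential
  against a threshold grows with the logarithm of the averaging factor);
  it is reported for the stated averaging design.
- The LME/GLMM contracts delegate optimization to lme4; convergence
  warnings on tiny unbalanced tables are possible and surfaced as such.
- On simulated cohorts with strong between-subject effect heterogeneity,
  the per-subject measurement noise of the normalized LI scales with the
  subject's gain, violating the LME's homoscedasticity assumption; the
  frequency F test is then mildly anticonservative. The test-suite size
  calibration uses homoscedastic data, where the test is exact.
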