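---
title: "sleepkit: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sleepkit: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sleepkit implements the signal-analysis stack of a rodent sleep-physiology
experiment: spectral scoring features, online (closed-loop) REM detection,
phasic theta event detection, EMG-derived heart rate, pupillometric eye
movements, bootstrap statistics on laser-aligned brain-state transitions, and
fiber-photometry / miniscope calcium pipelines. This vignette explains the
underlying models, the tunable parameters, and the choices made where a
design question was genuinely open. It states no empirical result beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## Coordinate system and data model

Everything hangs off the hypnogram: brain states (`W`ake, `N`REM, `R`EM,
`U`ndefined) on a uniform 2.5 s epoch grid, matching the half-overlapping 5 s
spectrogram windows used for scoring. Epochs are half-open intervals
`[t, t + 2.5)`; signal sample *i* (1-based) maps to time `(i - 1)/fs`; all
timestamps are 0-based seconds. `U` epochs never enter statistics.

Episode segmentation (`episodes()`) returns maximal runs of one state. For
NREM only, wake interruptions up to 10 s ("microarousals") may be bridged:
the flanking NREM runs merge into one episode whose duration includes the
gap. Bridging is an analysis-time convention for inclusion rules (episode
duration thresholds, long-bout selection) and never mutates the stored
hypnogram.

EDF and a plain-text `.hypno` format (header `epoch_s=2.5`, one state letter
per line) are the on-disk forms. EDF channel labels are matched
case-insensitively by substring since label dialects vary between amplifiers.

## Spectral features

All power estimates come from Welch's method: half-overlapping 2 s Hann
segments, per-segment mean removal (so electrode DC offsets do not leak into
the delta band), no zero-padding, one-sided density scaling in uV²/Hz.
The spectrogram evaluates one Welch PSD per half-overlapping 5 s window
(2.5 s hop, matching the epoch grid); incomplete trailing windows are
dropped rather than padded to avoid edge bias in trial averages. Band powers
are midpoint Riemann sums over the PSD bins whose center frequency falls
inside the band (delta 0.5–4.5 Hz, theta 6–9.5 Hz, sigma 10–15 Hz, gamma
50–90 Hz); the EMG amplitude is the square root of the 5–100 Hz integral.

Laser-triggered spectrograms normalize each frequency row by its temporal
mean over the recording *excluding* laser intervals, then average trials
aligned at laser onset. Note that a band time course of the normalized
spectrogram is a sum over normalized bins: a narrowband oscillation riding on
a broadband floor is diluted by the floor bins, so only band-wide power
changes scale the course by the full power ratio.

## Closed-loop REM detection

The online detector works on a causal feature stream: every 2.5 s it
computes delta power, theta/delta ratio and EMG amplitude from the trailing
5 s of data only. The decision rule is hysteretic: detection starts when
delta power and EMG amplitude are below their thresholds and theta/delta
exceeds a *hard* threshold; it ends when theta/delta drops below a *soft*
threshold or EMG exceeds its threshold. Between those events the detector
stays on, so ratios dipping between soft and hard never re-trigger.

The thresholds are calibrated from a previously scored recording of the same
animal. How to derive them is not a settled convention, so the calibration is
parameterized and documented: `delta_max` = mean NREM delta power;
`emg_max` = mean NREM EMG amplitude + k₁·SD (k₁ = 1); `thdelta_hard` = mean
REM theta/delta − k₂·SD, floored at the NREM 95th percentile of the ratio;
`thdelta_soft` = f·hard (f = 0.6). The theta/delta ratio is strongly
right-skewed (delta power in the denominator), so a small k₂ parks the hard
threshold near the REM *median* and halves sensitivity at REM onset. The
default k₂ = 1.2 places the hard threshold near the REM 5th percentile
instead; the NREM-percentile floor, the delta veto and the EMG veto are what
protect against false triggers, and the validation report
(`validate_rem_detection()`) quantifies per-bout hit rate, onset latency and
false onsets against a scored hypnogram.

## Phasic theta events

Within each REM episode the parietal EEG is band-passed to 5–12 Hz
(4th-order Butterworth, applied forward–backward so trough timing is not
displaced). Troughs are local minima of the instantaneous (analytic-signal)
phase below −3 rad — the phase is 0 at a waveform peak and ±π at a trough —
at most one per cycle. The inter-trough interval sequence is smoothed with an
11-element box filter (shrinking windows at episode edges, applied per
episode since the sequence is per-episode). Candidate events are maximal runs
of smoothed intervals strictly below the 10th percentile spanning at least
900 ms from first to last trough; a candidate is accepted if its minimum
smoothed interval is below the 5th percentile and its mean instantaneous
theta amplitude exceeds the mean over all REM sleep. Percentiles use linear
interpolation and are pooled across the episodes of one session — the
non-laser episodes when a laser train is supplied — and can be frozen and
reused across conditions so laser-on episodes are scored against laser-off
thresholds.

Timing gates depend only on trough times, so they are invariant to amplitude
rescaling; the amplitude gate scales covariantly. Event spectra
(`phasic_metrics()`) include only events at least as long as the 2 s Welch
window; shorter events still count toward the events-per-minute frequency.

## Heart rate from the nuchal EMG

R-waves of the ECG bleed into the nuchal EMG as sharp negative deflections,
usable during REM atonia. Whether they are *isolable* is decided per episode
from the threshold curve: counting, for thresholds rising from −100 to 0 uV
in 1 uV steps, the negative peaks of the 10–100 Hz band-passed EMG below
each threshold (with a 50 ms refractory gap — the ~1200 bpm physiological
ceiling for a mouse). Clean R-waves produce a rise to a plateau (all R-waves
counted) followed by a late surge when the threshold reaches the noise
peaks; an episode is accepted iff the curve has a concave-to-convex
inflection inside (−60, 0) uV. Operationally: counts are smoothed with a
5-point moving average, the inflection is the first sign change of the
second difference inside the range, and plateau evidence requires a nonzero
count at −60 uV. The inflection threshold is then used for detection; the
instantaneous rate of each inter-beat interval is 60/interval, assigned to
phasic or tonic REM by the interval midpoint.

## Eye movements

The pupil is localized per video frame by inverting, Gaussian-smoothing and
binarizing the image and taking the centroid of the largest connected
component (a minimum-area floor marks blinks invalid). Speed is the
Euclidean displacement between successive frames, acceleration its
frame-to-frame difference, both on the native 30 Hz camera clock
(px/frame²). Rapid eye movements are positive acceleration peaks above twice
the SD of the acceleration over all REM samples of the recording — a
scale-free criterion — separated by at least 100 ms. The 100 ms refractory
is deliberately below the 250 ms burst gap so it cannot destroy burst
structure: bursts are transitive groups of events with consecutive gaps
strictly below 250 ms, and groups of one are not bursts.

## Transition probabilities and the bootstrap

Hypnograms are downsampled to 10 s epochs by majority vote over the four
2.5 s sub-epochs, ties broken with priority R > N > W so rare-state
transitions survive. For each laser trial, P(X→Y | t ≤ d) = q/p, where p
counts trials in X at laser onset and q those that entered Y within d
seconds (first entry, regardless of intervening states; the X→X
"maintenance" curve conversely ends at the first departure). The baseline
repeats the computation on the 120 s window preceding the onset, re-anchored
at its start; on the 10 s grid its final step reuses the epoch containing
the onset, which is what makes a 12-step horizon fit the 120 s window.
A consequence of first-entry semantics: a pair like W→R can be nonzero via
W→N→R chains even when direct wake-to-REM transitions are impossible.

The test statistic is the normalized area difference between the laser and
baseline cumulative curves (the 120 s × [0, 1] box is area 1). The
two-sided test resamples the m pooled trials with replacement B = 10,000
times, recomputes both curves per draw, and reports the 2.5–97.5 percentile
CI and the equal-tail P = 2·min(#{stat ≤ 0}, #{stat ≥ 0})/B, flagged as
below resolution (reported 1/B) when a tail is empty. Draws in which no
resampled trial is in X at an anchor are redrawn and counted. P-values are
not corrected for multiple comparisons. Resampling pools trials across
animals; a hierarchical variant is out of scope. The relative-change graph
reports AUC_laser/AUC_baseline per pair (1 = no change), omitting pairs
never observed at the anchor or never transitioning.

Two properties of this test are worth knowing. First, the percentile
bootstrap has a small-sample size distortion: with m = 100 trials its
measured type-I error in the package's calibration study is ≈ 0.08 at
nominal 0.05, shrinking to ≈ 0.056 at m = 200; the calibration studies
therefore run at m = 200 trials per dataset, a realistic pooled count
(tens of trials per session, several sessions and animals). Detecting a
doubled N→R hazard with only m = 100 pooled trials sits near the method's
resolution limit: doubling an exponential hazard changes the normalized AUC
by at most ≈ 0.2 (best case over the hazard scale), while the statistic's
sampling SD with ~55 at-onset trials is ≈ 0.07, so the achievable power at
α = 0.05 plateaus around 0.8 — the value the acceptance script's power study
reports. Second, the trial bootstrap assumes exchangeable trials: trials cut from one continuous
recording at 13–17 min spacing retain a small serial correlation through the
sleep cycle that the bootstrap cannot see, so the calibration and power
studies draw each trial from an independent chain realization
(`simulate_transition_trials()`), emulating pooling across sessions.

## Calcium imaging

**Motion correction.** Each frame is spatially high-passed (subtracting a
Gaussian-blurred copy of itself), cross-correlated with a high-pass
reference frame via the FFT, and the integer shift maximizing the circular
cross-correlation is inverted on the raw stack; shifts hitting the search
bound flag the frame instead of shifting it. Shifts are reported relative to
the reference (by default the first frame).

**Activity map.** Per frame the normalized deviation
(f − f̄)/(f̄ + f_avg) is smoothed with a 2×2 box filter and aggregated over
time by mean magnitude. The magnitude matters: the temporal mean of the
deviation itself is identically zero by construction, so a literal temporal
average would produce an all-zero map; the mean absolute value is the
minimal change that makes the map register temporal variance. The 2×2 box
is implemented as the mean of each pixel with its +x/+y neighbours, clamped
at the far edges.

**Traces.** F(t) is the ROI pixel mean; the neuropil trace F_np(t) is the
mean over a 10 um ring ~5 um outside the ROI perimeter (geometry converted
via the configured pixel size, 1.2 um/px by default), excluding all ROI
pixels with a small safety margin — somatic fluorescence bleeds slightly
beyond a neighbouring ROI's outline — as well as the blood-vessel and
off-lens regions. The session correction factor
c = (F_vessel − F_offlens)/(F_nearvessel − F_offlens) scales the
subtraction F_subt = F − c·F_np. The baseline B(t) is the affine fit to the
F_subt samples at or below the session 20th percentile (a sample-wise
quantile, not a windowed one), and dF/F = (F_subt − B)/B, so a linear bleach
with no transients yields dF/F ≈ 0 by construction.

**Subclasses.** Cells are classified on per-epoch mean dF/F: a one-way
ANOVA across W/N/R gates modulation at α = 0.05; for modulated cells
Tukey's HSD establishes the maximal state, and a cell receives a state
subclass only when the top-mean state differs significantly from *both*
other states — otherwise it stays unmodulated. This is the faithful reading
of "determining the maximal state by post-hoc test", and it keeps the false
labeling rate of truly state-independent cells strictly below α. REM-max
cells split into R>N>W vs R>W>N by their NREM vs wake means.

**Aligned statistics.** Transition-aligned activity uses z-scored dF/F
(each cell's full-recording mean/SD — the parameter-free choice), 10 s bins
over −60 to +30 s, and transitions whose preceding NREM/wake episode lasted
at least 60 s (NREM may include microarousals; REM→Wake requires 10 s of
REM). Per subclass a repeated-measures ANOVA over bins gates Holm-corrected
paired t-tests of each bin against the −60..−50 s baseline bin. The
time-normalized NREM→REM→Wake view divides each episode into 10 bins
(configurable) and splits REM at 30 s. Phasic-event contrasts compare each
event against the immediately preceding tonic interval of equal duration
(events with no room for a baseline are skipped) with a paired t-test per
subclass. Cross-correlations with band power use NREM bouts ≥ 120 s
(microarousal-bridged), a 2.5 s / 80 %-overlap spectrogram normalized per
frequency by its recording mean, dF/F averaged onto the same 0.5 s grid,
and the normalization by sd(s)·sd(d)·N after demeaning; the documented sign
convention is that a positive lag means dF/F leads the power.

**Photometry.** Both channels are low-passed at 2 Hz (4th-order
Butterworth, zero-phase), the 405 nm isosbestic channel is regressed onto
the 465 nm channel, and dF/F = (465 − fit)/fit; bleaching and shared motion
artifacts load on both channels and cancel.

## The synthetic-data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes together with ground-truth ledgers, and its defaults *are*
the study conditions of the test suite and the acceptance script.

* **Hypnogram** — a semi-Markov chain with exponential-plus-floor bout
  durations, implemented as a per-epoch competing-hazard chain (beyond the
  floor the exit hazard to each target state is constant). That equivalence
  is what makes a laser effect exact: multiplying one X→Y hazard during
  laser intervals is a one-line change of the competing rates. Defaults are
  light-phase mouse sleep: mean bouts 30/90/45 s for W/N/R with 10 s floors,
  exits W→N always, N→R 0.8 / N→W 0.2, R→W always (wake→REM forbidden).
* **EEG/EMG** — state-gated stylized spectra at 1 kHz: NREM delta
  (1.5–4 Hz, 60 uV RMS) with 10–15 Hz spindle bursts; REM theta as a
  phase-continuous frequency-modulated sinusoid (7.5 Hz tonic, 50 uV)
  stepping to 9 Hz at ×1.5 amplitude inside injected 1.5 s phasic events
  (3/min of REM, Poisson, clipped to REM), plus residual REM delta (15 uV
  RMS) so the theta/delta ratio stays bounded as in real EEG; wake
  broadband; white sensor noise (10 uV). EMG is white noise at state RMS
  (100/20/5 uV for W/N/R) plus a biphasic ECG template (−80 uV R-waves) at
  600 bpm rising to 660 bpm during phasic events.
* **Pupil** — 30 Hz; piecewise-constant gaze with 8 px saccade steps
  (12/min of REM, Poisson, center-biased so the gaze stays in frame) over a
  slow near-circular drift (0.5 px, 0.2 Hz). The drift is smooth by design:
  its acceleration peak factor stays below 2·SD, so a drift-only trace
  produces no detections, while saccades dominate the SD when present.
  Optional rendered frames (anti-aliased dark disk) feed the contour
  detector.
* **Calcium** — 20 Hz, 64×64 px, 1.2 um/px: Gaussian-footprint cells with
  per-subclass state-dependent transient rates (R>N>W, R>W>N, Wake-max,
  NREM-max at 0.5/0.15/0.03-style contrasts, unmodulated at 0.15 Hz),
  AR(1)-style exponential decays (0.8 s), a shared low-frequency neuropil
  fluctuation entering ROI pixels at the configured gain (0.7) and tissue at
  full strength, a dark vessel stripe and off-lens margin built so the
  mean-intensity calibration ratio equals the gain, white noise, and a
  bounded random-walk integer motion ledger anchored at zero for the first
  frame. Photometry pairs a bleaching trend plus population transient
  (465 nm) with bleaching plus shared artifact only (405 nm).

Every stage derives its own RNG stream from the master seed by stage name,
so regenerating one modality never perturbs another, and identical seeds
give bit-identical outputs.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: biophysical EEG (no cortical dipoles, no 1/f
continuum, no scorer ambiguity at state boundaries), EMG artifacts other
than ECG, non-rigid miniscope motion, overlapping cell footprints with
correlated activity, or pupil occlusion dynamics. Recovery results on it are
parameter-recovery checks of the implementations, not claims about in-vivo
performance.

## Numerical conventions and problem sizes

Percentiles use linear interpolation; "continuously smaller" gates use
strict inequality; detection refractories are 50 ms (R-waves), 100 ms (eye
movements) and half the fastest theta period (troughs). The analytic signal
is built in the frequency domain. Degenerate inputs are defined: a DC trace
has no theta troughs, an empty/flat EMG yields an all-zero threshold curve
(rejected), a constant 405 nm channel is an error, a pair with no trials in
X at the anchor is flagged undefined rather than zero.

The test suite and acceptance script run on one CPU in tens of minutes with
these problem sizes, chosen to keep every statistical check inside its
sampling tolerance: 1,000 random 20-trial fixtures for the curve oracle;
200 datasets × B = 2,000 (m = 200) for the bootstrap size study and 30–40
datasets (m = 100) for power; 1,200–1,500 s recordings for detector
recovery; one 64×64×6,000-frame movie plus a 150-cell trace-level study for
the calcium pipeline.

## Known limitations

The calibration formulas for the closed-loop thresholds and the
smoothing/inflection operator of the heart-rate criterion are operational
definitions of procedures whose exact form is not standardized; both are
parameterized and documented above. The ROI matcher searches rotations on a
grid with integer translations (no subpixel refinement). OASIS-style spike
deconvolution is not included; no downstream computation depends on it. The
bootstrap offers no hierarchical (animal-level) resampling; with few animals
and strong between-animal heterogeneity the pooled test is anticonservative.
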