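---
title: "Models and methods behind walkvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind walkvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(walkvep)
```

walkvep implements the analysis chain of a mobile-EEG experiment on visual
processing during free walking: participants fixate a central grating
flickering at 15 Hz (driving a steady-state visual evoked potential, SSVEP)
surrounded by a static grating at one of four contrast levels, while
standing still, walking slowly, or walking at normal speed. The pipeline
quantifies how the surround contrast suppresses the central SSVEP in each
movement state, how ongoing alpha oscillations co-vary with it, and how the
same manipulation shows up in target-detection behaviour. Because walking
EEG is dominated by movement artifacts, half of the pipeline is artifact
accounting: blink and saccade detection from the EOG, head-movement
detection from a gyroscope, and robust trial exclusion.

This vignette explains the models, the numeric choices, and what the
synthetic-data generator does and does not emulate.

## The experimental design encoded in the generator

A session has 21 blocks (7 per walking condition, random order). Each block
presents the four surround contrasts (0, 33, 67, 100%) for 35 s each, in
random order; during each 35-s period six detection targets appear between
5 and 31.5 s after period onset with onset asynchronies drawn uniformly from
3.5–6.5 s. This yields the design arithmetic the tests pin down: 84 contrast
periods, 504 targets, and 7 × 35 = 245 s of stimulation per condition ×
contrast cell. Target times are produced by rejection-sampling the five
asynchronies until they fit the 26.5-s window, which preserves the uniform
asynchrony distribution.

## The generative signal model

`synthesize_signals()` builds each EEG channel as a sum of:

* **1/f background noise** (spectral shaping of white Gaussian noise,
  exponent 1, 4 µV RMS per channel) — the coloured floor of resting EEG;
* **high-frequency noise** (flat 20–99 Hz), whose RMS grows with walking
  speed (1.0 / 1.6 / 2.2 µV) — the empirical "upshift" of the walking EEG
  spectrum; this is a statistical stand-in, not an EMG model;
* **an ongoing alpha oscillation** at the participant's peak frequency
  (drawn from 9–11 Hz), amplitude decreasing with walking speed
  (4.0 / 2.8 / 2.0 µV), with occipital scalp weighting;
* **the 15 Hz SSVEP** during contrast periods, with amplitude given by a
  condition × contrast map. The default map encodes the phenomenon the
  analysis is built to detect: amplitudes fall with surround contrast during
  walking but stay nearly flat while standing, and fall overall with speed.
  No µV-level ground truth exists for these source amplitudes, so the map
  is a free parameter of the generator;
* **gait components** at the step frequency (1 Hz slow, 1.75 Hz normal) and
  its first harmonic;
* **per-period amplitude fluctuations**: alpha and SSVEP amplitudes are
  jittered log-normally per period with correlation 0.5, emulating the
  positive trial-wise association between alpha and SSVEP power that the
  median-split and regression analyses are designed to recover.

EOG channels carry steeper (slope 1.5) background noise, 400-ms
raised-cosine blink templates (150 µV on the vertical difference, i.e. well
above the 20/40 µV detection rules), and a brief biphasic spike-potential
wavelet at saccade times on all six channels. The wavelet is a Ricker
function with σ = 4 ms, placing its spectral peak near 56 Hz — inside the
20–90 Hz band the detector filters to. Its trough amplitude is a quadratic
function of saccade size (22 + 12·s + 0.6·s² µV for s in degrees), the same
functional family the downstream calibration fits. The gyroscope carries
band-limited (≤ 10 Hz) baseline noise — head angular velocity is smooth, and
the smoothness matters: threshold detectors that mark points beyond
mean + 2.5 SD see far fewer spurious level crossings in slow noise than in
white noise of the same RMS — plus gait-locked rotation and 160 deg/s
head-movement bursts at 3 per minute.

The simulated observer detects each target with probability
Ψ(x) = (1 − λ)·Φ((x − θ)/σ), with per-cell thresholds chosen so that hit
probabilities mirror the qualitative behavioural pattern (high and flat
while standing, contrast-dependent decline while walking), slope σ = 0.1,
lapse λ = 0.02. Hits produce a button press after a shifted log-normal
reaction time (shift 200 ms), keeping most responses inside the 1-s hit
window; spontaneous false alarms occur at a per-condition Poisson rate.

**What the generator does not emulate:** real EMG spectra and their
non-stationarity, electrode impedance drift, eye-movement potentials other
than blinks and spike potentials, optic flow, or biophysical head-volume
conduction (scalp weights are a fixed topography vector). Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that it is robust to every failure mode of real walking EEG.

### Two generator paths

Full signal synthesis is the ground truth for every signal-level operation,
but statistical power studies need hundreds of simulated experiments.
`simulate_trial_power()` therefore draws per-trial referenced SSVEP power
directly from the generative model: expected referenced power of a sinusoid
of amplitude A under the package's Welch estimator is 0.666 × A²/2 (the
Hamming window's coherent/incoherent gain ratio 0.7337 times the
neighbour-referencing leakage correction 0.9076), scaled by a log-normal
participant gain and the per-trial fluctuation, plus additive estimation
noise. The equivalence of the two paths in expectation is itself a test in
the suite; the 100-experiment interaction-recovery study runs on the fast
path.

## Spectral estimation

`welch_psd()` averages Hamming-tapered periodograms over 1-s segments with
50% overlap, giving an exact 1 Hz grid and one-sided density scaling
(µV²/Hz): white-noise power integrates to its variance, and a unit sinusoid
concentrates at its bin (with the known ±1-bin Hamming leakage). SSVEP power
is the 15 Hz bin referenced by subtraction of the mean at 13, 14, 16, 17 Hz;
alpha power is the individual peak-frequency bin referenced to 10, 11,
12 Hz. Referencing removes broadband shifts (such as the walking noise
upshift) but leaves sinusoidal leakage: about 9% of the 15 Hz peak leaks
into the 14/16 Hz references, so referenced power is a fixed 0.91 fraction
of the raw peak above floor — irrelevant for all comparisons, which are
within-estimator. Note one documented oddity inherited from the method:
referencing alpha at the individual peak against 10–12 Hz can include the
peak bin itself in the reference set; the package implements the rule as
stated and flags it here.

Channel selection takes the 3 occipital-pool channels with highest mean
15 Hz power over all trials (ties broken by pool order). The peak alpha
frequency is estimated from still-condition trials only — the estimate
should not be degraded by walking noise, and the method leaves the
estimation context open.

The SSVEP amplitude envelope uses a fixed 1-s Hamming-window FIR band-pass
(14.5–15.5 Hz) followed by the analytic-signal magnitude; the first and
last 0.5 s are flagged as filter edges and excluded from statistics. The
target-evoked perturbation averages the envelope across targets aligned to
onset and summarises the post-target window either as the mean over
200–600 ms or as the (sign-reversed) minimum over 200–1000 ms; its baseline
is the mean envelope in the second before onset (a choice the source method
leaves open).

## Filtering

All broadband filtering is zero-phase windowed-sinc FIR with a Kaiser
window: 60 dB stopband, transition bandwidth 25% of the lower band edge with
a 1 Hz floor (the method names only the filter family; these are
conventional design values). The filter is applied once forward via FFT
convolution after symmetric edge reflection, and the integer group delay of
the odd-length kernel is removed, which is exactly zero-phase for
linear-phase kernels. Two deliberate exceptions: the blink channel's 0.2 Hz
drift high-pass is a 2nd-order zero-phase Butterworth (a 0.2 Hz sinc kernel
would span tens of seconds), and saccade detection uses the 6th-order
Butterworth 20–90 Hz band-pass that defines the method.

## Artifact detection and the 2.5 SD rules

Blinks: vertical EOG (above − below eye, left eye), 0.2–20 Hz; candidate
points cross 20 µV, candidates within 100 ms merge, and merged candidates
must reach a 40 µV peak and a 15 µV amplitude SD in a 400-ms window centred
on the peak (the window length is a package choice; the method does not
define it).

Saccades: the radial EOG (mean of the six EOG channels minus Pz) is
band-passed 20–90 Hz; its Hilbert envelope is thresholded at the block mean
plus 2.5 block SDs, supra-threshold points under 20 ms apart group into one
saccade, and detections within 100 ms of block edges are discarded as
filter warm-up. An 80-ms window of the filtered REOG centred on each
saccade's trough, divided by the block-mean envelope (correcting broadband
power differences between blocks), averages into the spike-potential
waveform; the normalised trough amplitude at time 0 feeds a second-order
polynomial calibration from amplitude to saccade size, evaluated only
inside the calibrated amplitude range (clamped and flagged outside), with
monotonicity checked rather than assumed.

Head movements: per block, points whose 3-axis rotational speed exceeds the
block mean by 2.5 SDs are marked, and marked points within a 2-s window form
one event.

These block-adaptive thresholds have a property worth stating: on purely
Gaussian, fast-varying noise, mean + 2.5 SD marks a fixed ~1% of samples
whatever the noise scale, so the detectors only behave well when genuine
events inflate the block SD above the noise tail — which is how both the
real signals and the generator defaults are structured.

## Trial exclusion

Pre-target trials are the 2-s half-open windows ending at target onset;
trials with a button press in the preceding 2.5 s are flagged, as are
targets less than 2 s after period start (a boundary case the method leaves
unspecified; flagged rather than dropped). Within each walking condition,
a trial whose 20–99 Hz power p satisfies |p − median(P)| × 0.6745 >
2.24 × median(|P − median(P)|) is excluded. The rule is scale-free and, when
the MAD is zero, flags any deviating trial; groups under 3 trials are left
untouched with a warning. "Noisy epochs identified through visual
inspection" become an explicit mask argument to `repair_epochs()`, which
replaces a flagged channel by the mean of its spatial neighbours — the
inspection result is an input, so the repair is reproducible.

## Staircases

The transformed up/down staircases converge to the level where the k-fold
hit probability is 0.5: 84.1% correct for 1-up-4-down, 79.4% for
1-up-3-down. The main-task titration uses 1-up-4-down with a fixed 3%
contrast step from a 0.8 start; simulated against a cumulative-Gaussian
observer its long-run proportion correct is 84% to within the stated
2-point band. The follow-up threshold procedure starts at 0% change,
steps 6% until the 4th reversal and 3% thereafter, stops at 13 reversals,
and estimates threshold as the mean of the last 10 reversal levels.
Averaging reversals of an equal-step staircase sits slightly below the
asymptotic point; with the package's observer (threshold 0.2, slope 0.1 —
realistic values for a contrast-change detection task) the recovered
threshold corresponds to 77–78% correct, a bias of about a tenth of the
final step in stimulus units. The package reports what the procedure
actually delivers rather than the textbook asymptote.

## Behavioural indices

A press is a hit if it falls within 1 s after a target; presses pair with
the earliest unassigned target (asynchronies ≥ 3.5 s make conflicts
impossible in-design, but the rule is still defined), and unassigned presses
are false alarms attributed to the active condition × contrast cell.

The target preference index is Σᵢ|T − tᵢ| / (6T) over the four per-location
detection rates tᵢ with mean T. The literal printed form of this index
elsewhere — absolute value of the *sum* of deviations — is identically zero
for any data, because deviations from a mean sum to zero; the
sum-of-absolute-values reading is the only one consistent with the stated
anchor cases (0 for uniform rates, 1 for single-location responding), and is
what the package implements. Its significance is assessed against 1,000
simulations distributing the observed number of detections uniformly over
locations, with p the fraction of simulated indices strictly larger than the
observed one — strictly, following the source's wording, which makes the p
mildly conservative at small counts where the index has atoms.

## Inference layer

The within-subjects ANOVA is computed directly from sums of squares, each
effect tested against its own subject-interaction error term. Sphericity is
assessed per effect with Mauchly's test (two-term chi-square expansion) on
the orthonormal-contrast covariance; when p < 0.05, the Greenhouse–Geisser
epsilon — (Σλ)²/(k·Σλ²) on the eigenvalues of that covariance — multiplies
both degrees of freedom. Effect size is partial eta squared. The suite
verifies F and p against `aov()` error strata to 1e-10 and epsilon/W against
`car::Anova()` and `stats::mauchly.test()`. Paired t tests (with Cohen's
d_z) and Benjamini–Hochberg control wrap the base R implementations, with
independent formula oracles in the tests.

The SSVEP–alpha median split divides each condition's trials at the median
raw SSVEP power (the median trial joins the weak group), then removes the
five lowest-HF trials from the weak and five highest-HF from the strong
group in the walking conditions, eliminating the high-frequency-power
confound; the trimming is skipped with a warning when either group would
fall below five trials. Count-matched averaging computes the measure within
each artifact-count stratum and takes the unweighted mean across strata. The
two-level regression z-scores trial SSVEP and alpha power within each
testing block ("normalised within each testing block" is read as z-scoring;
the source does not name the transform), fits ordinary least squares per
participant on alpha, blink and saccade counts, and tests each slope against
zero across participants; rank-deficient participants are skipped with a
warning.

## Problem sizes and reproducibility

All randomness flows from one seed; per-participant, per-stream sub-seeds
are derived deterministically and stay below 2³¹. The test suite exercises
full signal synthesis on 1–2-block sessions (≈ 440–880 s of 24-channel data)
and single-period sessions for spectral ground-truth sweeps; staircase
convergence uses 25–100 runs of 2,000 trials; the interaction-recovery study
runs 100 simulated 25-participant experiments on the trial-level fast path.
These sizes were chosen to estimate each quantity well inside its stated
tolerance while keeping a full run of the suite under a few minutes.

## Known limitations

* EDF output quantises to 16 bits over each channel's observed range; the
  round trip is exact only to that quantisation.
* The generator's amplitude maps are plausible but uncalibrated (no µV-level
  ground truth exists to calibrate against); conclusions from synthetic
  recovery are structural, not quantitative.
* The envelope band-pass (1-s kernel) smooths amplitude transients on the
  ~0.5 s scale; fast perturbations are attenuated accordingly.
* `rm_anova()` handles one or two within-subject factors with complete
  data; there is no mixed-design or missing-data support.
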