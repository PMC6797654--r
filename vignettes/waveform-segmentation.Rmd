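---
title: "Segmenting uncalibrated nystagmus waveforms for eye-tracker calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting uncalibrated nystagmus waveforms for eye-tracker calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nystcal)
```

## The calibration problem in infantile nystagmus

Infantile nystagmus (IN) is a continuous rhythmic oscillation of the
eyes. Standard eye-tracker calibration assumes the participant can hold
steady fixation on each target; with IN that assumption fails, and the
only moments when gaze is reliably on target are the brief low-velocity
*foveation* periods within each cycle. Identifying them by the classical
fixed criteria — speed below 4°/s, successive positions within ±0.5°,
duration at least 7 ms — is circular, because speed and position
thresholds in degrees are meaningless before the tracker is calibrated,
and a single fixed threshold fits individuals with very different
nystagmus intensities badly in any case.

`nystcal` therefore works entirely in the tracker's arbitrary units,
using only *relative* statistics of the signal, and defines the
foveation of each cycle adaptively: the window covering 10% of that
cycle's slow-phase duration with the lowest mean eye speed. Calibration
then maps the median foveation position per target onto the known target
positions.

## Pipeline and assumptions

**Preprocessing.** Tracking gaps of at most 25 ms are interpolated with
cubic splines fitted on the flanking valid samples (8 per side; an
interpolating cubic spline with free end conditions reproduces
polynomial signals up to cubic exactly, which is also how the behaviour
is unit-tested). Longer gaps are presumed blinks: 75 ms is invalidated
on either side, because lid closure corrupts the position signal before
the tracker reports data loss. Padded samples keep their raw values and
only lose their `valid` flag, which makes both operations idempotent.

**Filtering and differentiation.** Each axis is smoothed and
differentiated by a Savitzky–Golay filter (local least-squares
polynomial, order 3, window 21 samples at 1000 Hz, rescaled and kept odd
at other rates). The filter runs independently on each maximal valid
segment so blink artifacts cannot leak across gaps; segments shorter
than the window are passed through with speed masked. The literature on
generalized (adaptively parameterized) Savitzky–Golay differentiation of
eye movements does not pin down a single parameter set, so the order and
window are exposed in `pipeline_config()`; the defaults preserve
quick-phase dynamics at 1000 Hz while suppressing sensor noise.

**Detection speed.** The two raw axes have different unknown gains, so a
Euclidean speed in raw units would mix incommensurate quantities. The
default detection speed is the absolute smoothed velocity of the
*primary axis* — the axis with the larger position SD; IN is primarily
horizontal. A `magnitude` mode combining MAD-standardised axis
velocities is available for oblique nystagmus.

**Cycle splitting.** Cycle boundaries are successive peaks of the
primary-axis position. The peak finder is deliberately scale-free:
minimum separation is half the dominant period, estimated as the global
autocorrelation maximum over the physiological 0.5–10 Hz band, and
minimum topographic prominence is 20% of the position IQR. Consequently
cycle boundaries are invariant under any positive-gain affine transform
of the raw signal (a tested property). Whether foveations sit at the
peaks or the troughs of the trace depends on beat direction and on the
tracker's sign convention, so by default the polarity whose extrema show
the lower local speed is chosen automatically. Cycles own their samples
half-open, `[peak_i, peak_{i+1})`, so no sample belongs to two cycles; a
cycle is *complete* when every sample it spans is valid.

**Quick-phase detection.** The cited fuzzy saccade detectors for
uncalibrated signals are not reproducible from their published
summaries, so the package defines a contract-equivalent scale-free
detector: samples are saccade candidates when speed exceeds
median + 6·MAD of the valid-sample speed; candidate runs closer than
10 ms merge, runs shorter than 10 ms are dropped, and surviving runs
grow outward to the nearest local speed minimum to capture the full
saccade profile. Because the rule uses only order statistics of speed,
detection is invariant under rescaling of the raw units — the property
the original algorithm is cited for. A pure sinusoid never triggers it:
the speed of a sine has max/median ratio √2, far below the
median + 6·MAD threshold. Speeds at the rounding-error scale of the
position signal (relative 1e−9) are treated as exact zeros so that a
constant trace stays saccade-free. Slow phases are all valid samples not
inside a saccade.

**Foveation search.** For each complete cycle the window length is 10%
of the cycle's total slow-phase duration (slow runs are summed when a
cycle contains several), rounded to whole samples, discarded entirely if
shorter than 7 ms. Every candidate start position is evaluated (one
sample steps — "each possible window" is taken literally) and the window
with the lowest mean speed wins; ties go to the earliest start for
determinism. Two boundary rules matter:

* a window must lie within a *single* slow run — a window straddling a
  quick phase would average saccadic speed into the foveation score,
  contradicting the intent of the search;
* a window may extend up to one window length past the cycle's closing
  peak (foveations often sit at the cycle boundary, especially in
  pendular waveforms), and samples claimed this way become unavailable
  to the next cycle, so no sample is ever assigned to two foveations.

The implementation uses cumulative sums for the window means; its
equivalence to a naive exhaustive search is asserted test-by-test
against an independently written brute-force oracle.

**Point of regard and calibration.** The POR per target is the
per-coordinate median over all foveation samples within the target's
display interval, after skipping the first 300 ms (time to take up
fixation). The median is robust to the occasional badly placed window
and biases the estimate toward the slower portion of each window. The
default calibration model per screen axis is linear with a cross-talk
term, `deg = a0 + a1·x_raw + a2·y_raw`: three coefficients per axis,
solvable from the five-point grid (±5° horizontal, ±3° vertical) with
two degrees of freedom to spare, and algebraically exact for any
affine-plus-rotation raw mapping — the cross-talk coefficient absorbs
rotation of the calibration field such as head tilt. A full quadratic
(six terms) is available when at least six targets were shown; five
points cannot identify it, which is why `linear_xtalk` is the default
rather than a higher-order polynomial. Fitting is ordinary least
squares; a rank-deficient design (collinear targets, identical PORs)
fails loudly rather than silently extrapolating. Screen coordinates are
centred with rightward/upward positive.

**Drift correction.** Head movement during long sessions shifts the
mapping by an approximately constant offset. Given a short fixation on
one known target, the foveation pipeline locates the POR and a per-axis
additive constant is composed with the model so that this POR maps
exactly onto the target. Using the foveation POR rather than the
whole-trace median matters: on an asymmetric jerk waveform the trace
median sits well away from the fixation position.

## The synthetic session generator

No public IN recordings with ground-truth foveation marking exist, so
the package ships a seeded simulator whose defaults reproduce the
calibration protocol the method was designed for: five targets at
±5°H/±3°V shown 10 s each at 1000 Hz, with the first 300 ms of each
target excluded from analysis.

* **Jerk** cycles drift away from fixation with an accelerating
  exponential slow phase, `x(t) = x_f ± A·(e^{t/τ} − 1)/(e^{T_s/τ} − 1)`
  (τ defaults to half the slow-phase duration, giving a clearly
  accelerating drift), and return by a 30 ms minimum-jerk quick phase —
  a smooth profile with realistic peak velocity, so saccade detection
  faces a real signal rather than an instantaneous jump.
* **Jerk with extended foveation** prepends a stationary plateau at the
  fixation position.
* **Pendular** waveforms are pure sines, following the convention used
  when this algorithm family is demonstrated on pendular nystagmus.

True gaze passes through additive white Gaussian noise in degrees
(default SD 0.05°), then an unknown raw transform
`raw = diag(g)·R(θ)·deg + b` (defaults 30 and 25 units/°, offsets 1000
and 800, rotation 0° unless varied). One 150 ms blink per target is
inserted as an invalid run flanked by 20 ms position spikes, exercising
the 75 ms trimming. The ground truth includes per-sample gaze and phase
labels, true cycle boundaries and quick phases, and per-cycle true
foveations computed by exhaustive search over the analytic speed — so
the "gold standard" role played by expert hand-marking in the original
verification is played here by construction.

The simulator emulates the *geometry and dynamics* the algorithm relies
on; it does not emulate several features of real recordings:
cycle-to-cycle variability of amplitude and period, waveform transitions
(pseudocycloid, dual jerk), pupil-size artifacts, head-motion drift
within a target, or tracker-specific noise spectra. Passing tests
therefore demonstrate correctness of the segmentation logic and
robustness to noise, blinks and unknown affine/rotated unit mappings —
not clinical performance on any individual's waveform.

## Validation conditions and problem sizes

The validation suite (and `scripts/acceptance.R`) uses: a 3 × 3 grid of
amplitudes {2°, 4°, 8°} × frequencies {2, 3, 5} Hz at noise SD 0.05°;
50 seeded five-target sessions for POR recovery (median error as % of
amplitude, and the fraction of runs where the foveation-based POR beats
the nonselective whole-trace median — the control method that ignores
segmentation entirely); 20 seeds per amplitude for the 1°–6° amplitude
sweep, where the nonselective error grows with amplitude but the
algorithmic error stays near-flat; an 8 s pendular session for the
both-sides property; and exhaustive-search agreement over ≥ 100 cycles.
These sizes keep a complete run in a few minutes on one core while
giving stable medians.

## Numerical choices and degenerate inputs

* Window means by cumulative sum; tie-break earliest start.
* Median of an even number of samples: mean of the central pair, per
  coordinate independently.
* Fewer than two detected peaks → an empty cycle set, not an error;
  constant traces yield no cycles, no saccades and an empty (but valid)
  report.
* Sampling rates below 200 Hz are rejected outright — quick-phase
  dynamics are not resolvable — and timestamps must be uniform within
  10%.
* The data-capture check (< 85% valid) warns and flags rather than
  aborting: it was designed as a participant-exclusion criterion, not an
  algorithm gate.
* Calibration files store coefficients with 17 significant digits, so a
  write/read round trip is bit-lossless; explicit zeros (e.g. a zero
  cross-talk term) are preserved.

## Known limitations

* For pendular waveforms the POR lands on whichever side of the
  waveform contributed more foveations; from eye movement data alone the
  true side is unknowable, and no stronger claim is made or tested.
* The quick-phase detector is contract-equivalent to, not a
  re-implementation of, the fuzzy-logic detectors cited in this
  literature; its parameters (k = 6, 10 ms minimum, 10 ms merge) are
  exposed in `pipeline_config()`.
* Waveform-type classification, torsional movements, binocular
  calibration, and periodic alternating nystagmus are out of scope.
* The per-cycle foveation is *defined* as the slowest window; in
  waveforms where the physiological foveation is ambiguous (e.g.
  pseudocycloid), the algorithm still returns the slowest window.
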