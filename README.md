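# nystcal

Foveation-based eye-tracker calibration for infantile nystagmus, in R.

## The problem

Infantile nystagmus (IN) is a continuous, involuntary oscillation of the
eyes, usually horizontal, whose cycles contain a brief low-velocity
"foveation" period during which the fovea is actually directed at the
object of regard. Calibrating an eye tracker requires knowing where the
participant is looking while each calibration target is displayed — but
with IN the eyes never stop moving, and the classical foveation criteria
(speed below 4°/s, position within ±0.5°, duration ≥ 7 ms) cannot be
applied, because before calibration both speed and position exist only in
arbitrary tracker units.

`nystcal` solves this chicken-and-egg problem with an adaptive,
calibration-free segmentation of the waveform:

1. **Preprocessing** — gaps ≤ 25 ms are repaired with cubic splines;
   75 ms is discarded on either side of any remaining gap (blink
   artifacts); each axis is smoothed and differentiated with a
   Savitzky–Golay filter, applied per valid segment.
2. **Segmentation** — the oscillation axis is the one with the larger
   position SD; cycles are split at waveform peaks found by a
   scale-free peak detector (separation from the autocorrelation-derived
   dominant period, prominence relative to the position IQR); quick
   phases are detected from relative speed statistics
   (median + 6·MAD), so no calibration is needed. Slow phases are
   everything that is not a saccade.
3. **Foveation detection** — in each complete (blink-free) cycle, the
   window lasting 10% of the cycle's total slow-phase duration with the
   *lowest mean speed* is the foveation; every candidate start position
   is evaluated, windows may extend up to one window length past the
   cycle's closing peak, and windows shorter than 7 ms are discarded.
4. **Calibration** — the per-target point of regard (POR) is the median
   gaze position over all foveation samples; a per-axis least-squares
   polynomial with a cross-talk term,

   `x_deg = a0 + a1·x_raw + a2·y_raw` (and likewise for y),

   maps raw units to degrees, absorbing any rotation of the calibration
   field (head tilt) exactly. Drift correction re-anchors the intercepts
   from a single fixation target.

A seeded simulator of jerk (accelerating exponential slow phase),
jerk-with-extended-foveation, and pendular (sine) waveforms — with
measurement noise, blinks, and an unknown affine + rotation mapping to
raw units — provides ground truth for every stage, standing in for
expert hand-marked recordings.

## Worked example

```r
library(nystcal)

spec    <- waveform_spec("jerk", amplitude_deg = 4, frequency_hz = 3)
session <- simulate_session(spec, seed = 42)   # 5 targets x 10 s at 1000 Hz
cal     <- calibrate_session(session$recording, session$manifest)

cal$log
#> # A tibble: 7 × 3
#>   stage            count detail
#>   <chr>            <int> <chr>
#> 1 capture          49250 98.5% valid
#> 2 interpolate_gaps     0 samples filled
#> 3 trim_blinks        750 samples trimmed
#> 4 filter           50000 axis horizontal
#> 5 split_cycles       147 142 complete
#> 6 quick_phases      4533 quick-labeled samples
#> 7 foveations         142 windows

glance(cal$model)
#> # A tibble: 1 × 4
#>   order        n_targets rms_resid_deg max_resid_deg
#>   <chr>            <int>         <dbl>         <dbl>
#> 1 linear_xtalk         5        0.0243        0.0300

analyze_recording(session$recording, cal$model)$metrics
#> # A tibble: 1 × 4
#>   amplitude frequency_hz intensity n_cycles
#>       <dbl>        <dbl>     <dbl>    <int>
#> 1      4.04         2.96      12.0      147
```

The run log shows the 50 s session parsed into 147 cycles (142 without
blinks), each contributing one foveation window; the five-point fit
recovers the unknown 30/25 units-per-degree transform with a worst
per-target residual of 0.03°, and the post-calibration metrics recover
the simulated amplitude (4°), frequency (3 Hz) and intensity
(amplitude × frequency = 12°/s) to within a few percent.

`plot_segmentation(cal)` draws the labelled waveform (slow/quick phases,
foveation windows, cycle boundaries); `autoplot(cal$model)` shows the
calibration residual field. `tidy(cal$model)` returns the coefficients.
A command-line wrapper for `simulate`/`calibrate`/`apply`/`analyze`
lives at `inst/scripts/nystcal.R`.

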