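---
title: "Segmenting the Agility T-test from trunk-worn sensor data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the Agility T-test: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codseg)
```

## The problem

The Agility T-test is a ten-yard T-shaped shuttle: forward sprint,
90° side step, left shuffle, 180° split step, right shuffle, 180°
split step, left shuffle, 90° turn, backward sprint. Photocells time
the whole trial but say nothing about the four changes of direction
(CODs) or the five displacement phases (DPs) individually. `codseg`
reconstructs that fine structure from a single trunk-worn GNSS-IMU
unit: 200 Hz tri-axial acceleration for event detection, 10 Hz GNSS
ground speed for the completion time.

The physical signal model is simple: every ground contact hammers a
transient into the antero-posterior (AP) trunk acceleration, and the
braking + push-off of a COD produces a *large positive* AP impulse —
the time-integral of AP acceleration between the minima flanking a
stance (the *acceleration impulse*, AI) is several times larger during
a COD (≈5–7 m/s) than during ordinary steps (≈1–3 m/s). Detection is
therefore a matter of finding impact minima reliably and ranking the
intervals between them by AI.

## Pipeline and assumptions

1. **Start.** Zero-phase 2nd-order Butterworth low-pass at 10 Hz; the
   first two local maxima above 4 m/s² are taken as push-off and
   first-step impact, and the local minimum immediately before them is
   the start. Assumes the athlete stands roughly still beforehand and
   that the sensor frame is aligned with the body frame (tight vest).
2. **Macro analysis.** The AP signal is band-limited to 0.5–15 Hz by
   stationary-wavelet reconstruction (below), the signal mean is
   re-added, and local minima with prominence > 15 m/s² falling below
   the adaptive threshold `T_MA = mean(qualifying peaks)/4` are
   collected. Consecutive-minima intervals are integrated
   (trapezoidal) and the four time-ordered, non-overlapping pairs with
   the largest AI become the COD segments; angle classes are assigned
   by protocol order (90, 180, 180, 90).
3. **Micro analysis.** Boundary refinement per COD and boundary
   (defaults in parentheses): M0 keep macro; M1 nearest minima of a
   0.5–5 Hz reconstruction; M2 (180° CODs) move the start one minimum
   earlier when a large peak precedes it — capturing the penultimate
   foot contact — and push a positive-valued end forward to the next
   negative minimum — the second toe-off; M3 nearest sub-g sample of
   the acceleration norm (flight phase); M4 advance the COD 1 end past
   a trailing push-off peak. Default map: COD1 (M0, M4), COD2/COD3
   (M2, M2), COD4 (M0, M0).
4. **Completion time.** The end instant `T` solves
   `∫ v_GNSS dt = L_DP5 − L_AR` from the detected COD 4 end, with
   `L_DP5 = 9.14` m and arm reach `L_AR = 1.42` m (95th-percentile
   male). Cumulative distance is interpolated linearly inside the
   final 10 Hz interval; at 10 Hz the sub-sample root otherwise
   dominates the error budget. Completion *duration* is reported
   relative to the detected first-step start — a known bias source
   when athletes cross the start line before or after their first
   step.
5. **Validation.** Signed errors reference-minus-estimate (events in
   ms, completion in s), absolute (ms) and relative (%) duration
   errors, Bland–Altman bias ± 1.96·SD limits of agreement with a
   difference-vs-mean trend slope, per-participant shift flags
   (|mean| > SD), and normality tests (Kolmogorov–Smirnov for pooled
   event errors, Shapiro–Wilk for completion errors).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `start_peak_height_mps2` | 4 | m/s² | start maxima threshold |
| `prominence_mps2` | 15 | m/s² | ground-contact peak/trough prominence |
| `macro_band_hz` | 0.5–15 | Hz | COD detection band |
| `micro_band_hz` | 0.5–5 | Hz | M1 refinement band |
| `lowpass_fc_hz`, `lowpass_order` | 10, 2 | Hz, – | start-detection filter |
| `L_dp5_m`, `L_arm_m` | 9.14, 1.42 | m | completion-time integral bound |
| `large_peak_window_s` | 0.3 | s | M2 lookback / M4 lookahead |
| `refine_window_s` | 0.5 | s | M1/M3 neighbourhood; max boundary move |
| `step_min_prominence_mps2` | 2 | m/s² | noise floor for "one minimum" steps |
| `edge_exclude_s` | 0.25 | s | extrema ineligible near signal edges |
| `analysis_window_s` | 15 | s | manual-cut window convention |

The first six are method constants; the remaining ones are design
choices this package declares (the method descriptions leave them
open). `step_min_prominence_mps2` exists because "move one local
minimum" must not land on a noise wiggle of the band-limited signal;
2 m/s² is several times the in-band noise ripple at the default
simulation noise level while far below any impact trough. Reusing the
15 m/s² prominence for M2's "large peak" keeps one fewer free
parameter.

## Wavelet band reconstruction

The reconstruction uses an undecimated (stationary) Daubechies-4
filter bank with time-reversed synthesis filters, computed exactly in
the frequency domain on a symmetric extension of the signal: each
detail level contributes the squared-magnitude response of its filter
cascade, so the operator is zero-phase by construction and all levels
plus the approximation sum identically to the input. Requested band
edges snap to the nearest dyadic edge `fs/2^j`: at 200 Hz, 0.5–15 Hz
keeps detail levels 4–8 (≈0.39–12.5 Hz) and 0.5–5 Hz keeps levels 5–8
(≈0.39–6.25 Hz). This dyadic mapping is a declared approximation of
the nominal band — the mother wavelet, depth and boundary handling are
not pinned down by the method description — chosen for shift
invariance and zero phase, which is what boundary placement needs. A
minimum of `2^8 = 256` samples (1.28 s at 200 Hz) is required.

## Threshold-side and pairing conventions

Three ambiguities in the macro step are resolved as follows, each
selectable or at least visible in the output:

* *Which minima qualify.* A minimum qualifies when its value is below
  `−T_MA` (primary rule) **or** when it is the immediate flanking
  minimum of a qualifying maximum (fallback, for asymmetric impacts
  that leave a bounding minimum positive — e.g. between the two push
  peaks of a 180° turn). The `minima` table records which rule fired.
* *Which peaks feed `T_MA`.* All maxima with prominence > 15 m/s²
  inside the analysis window, including COD-region peaks.
* *Pairing.* Pairs are consecutive qualifying minima; selection is
  greedy by descending AI under a no-shared-minimum constraint, ties
  to the earlier pair, then re-sorted by time.

For M2's end rule the two available descriptions of the method
contradict each other (shift when the end value is "less than 0"
versus "bigger than 0"). The implementation follows the physically
coherent variant — an end minimum still *above* zero means the macro
step stopped between the two push-offs, so the end is pushed forward
to the next negative minimum (the second toe-off). The legacy variant
remains selectable via `m2_end_rule = "negative"` for sensitivity
analysis.

## The synthetic world

`simulate_trial()` generates the stated measurement conditions, not a
biomechanical simulation:

* **Geometry/timing.** Ten-yard T (9.14 / 4.57 m legs). Phase peak
  speeds (6.5, 4.6, 5.6, 4.8, 5.0 m/s), COD entry/exit speeds
  (2.2/1.8/1.8/1.9 m/s) and cone minimum speeds (1.3/0.5/0.5/1.2 m/s)
  were chosen once so the default completion time lands near 9.8 s,
  inside the 9.1–9.3 s range reported for elite cohorts; durations
  follow from the distance constraint, never the other way around.
* **AP signal.** Raised-cosine impact transients (sharp rise, slower
  decay) with flanking troughs; step impulses calibrated to
  2 m/s (defaults within the stated 1–3 m/s band, cadence 3.3 Hz);
  COD bursts whose positive lobes are scaled so the integral between
  the flanking ground-truth minima equals the target impulse
  (defaults 5.5–6 m/s, within the stated 5–7 m/s band) — this
  calibration is part of the generator's contract, not a tuning knob.
  180° bursts carry distinct penultimate/final-contact peaks and a
  positive inter-push minimum, so the macro step genuinely
  mis-detects the inner pair and M2 has real work to do; COD 1 carries
  a trailing push peak for M4; COD 4 is a merged unimodal pivot.
  The backward sprint mirrors the step pattern's sign at reduced peak
  speed. White noise (SD 0.8 m/s²) and >15 Hz damped post-impact
  ringing exercise the band-limiting.
* **GNSS.** The along-path speed is sampled on a phase-offset 10 Hz
  clock; its integral over the trial equals the total path length to
  within the post-finish decay (<2%), and the trunk has exactly
  `L_DP5 − L_AR` left to cover at the COD 4 end, so the completion
  estimator is unbiased in this world — the real-world photocell
  placement bias is deliberately absent.
* **Labels.** Ground-truth events are jittered by a uniform integer
  number of 60 Hz frames (±3 by default) and snapped to the 1/60 s
  grid; the photocell time is copied unperturbed. The reference
  timeline for duration validation combines jittered COD labels with
  the true start/end, mirroring a photocell-synchronised video
  reference.

What the generator does **not** emulate: crossed-leg technique faults,
full 3D kinematics, gravity leakage into the AP axis, soft-tissue
artefact, GNSS multipath, or AP momentum conservation over the trial
(positive impulse bursts are not balanced by matching negative area —
detection only uses local structure). A green benchmark therefore
establishes that the pipeline implements the method correctly and that
its error budget under the stated conditions is dominated by the 60 Hz
reference quantization; it does not establish field accuracy on real
athletes, which the published real-data statistics describe.

## Numerical choices and degenerate inputs

* Zero-phase filtering pads by odd reflection (3 filter lengths) with
  steady-state initial conditions; signals must exceed three pad
  lengths or an `insufficient-samples` condition is raised.
* Prominence follows the standard topographic definition; plateaus
  count once at their earliest index; the first/last 0.25 s are
  ineligible for extrema.
* All failure modes are classed conditions (`codseg_no_start`,
  `codseg_too_few_minima`, `codseg_ambiguous_segmentation`,
  `codseg_insufficient_track`, `codseg_no_gnss`,
  `codseg_parse_error`, ...), so callers can branch on them.
* Refinements that would move a boundary more than `refine_window_s`
  or break strict timeline ordering are reverted to the macro value
  and flagged rather than propagated.
* The benchmark derives trial seeds as `seed_base + 0:(n-1)` and label
  seeds as `trial seed + 1000003`, so a single integer reproduces
  everything.
* The plain KS test is used for event errors to mirror the method's
  naming; because its parameters are estimated from the sample it is
  conservative, and a Monte-Carlo Lilliefors correction is available
  (`normality(..., lilliefors = TRUE)`).

## Known limitations

* The per-trial physiological variation (`randomize = TRUE`) is mild
  and independent across parameters; real athletes co-vary speed,
  cadence and impulse.
* The completion-time estimator assumes the GNSS speed is valid during
  the final phase; dropouts are only modelled as a missing trace
  (`codseg_no_gnss`), not as partial corruption.
* Left/right foot attribution and per-foot contact times are out of
  scope (they need foot-mounted sensors).
* The synthetic acceptance benchmark treats the published real-data
  error statistics as *upper bounds*; matching them exactly is neither
  possible (the cohort data are not public) nor attempted.
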