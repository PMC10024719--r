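# codseg — Agility T-test segmentation from a trunk-worn GNSS-IMU

`codseg` turns a single trunk-worn GNSS-IMU recording of the Agility
T-test into a full segmentation of the trial: the four
change-of-direction (COD) events, the five displacement phases (DPs),
and the total completion time. The traditional T-test score is one
photocell number; coaches and rehabilitation staff (e.g. after ACL
injury) want to know *where* time is gained or lost — in the 90° side
steps, the 180° split steps, the shuffles, or the sprints — and whether
left/right performance is asymmetric. This package computes exactly
that from sensors athletes already wear in training.

## Method

The detection signal is the antero-posterior (AP) trunk acceleration at
200 Hz. Braking before a COD produces a large positive AP reaction
impulse on the trunk, so:

1. **Start detection** — the AP signal is low-passed (zero-phase 2nd
   order Butterworth, 10 Hz); the first two local maxima above
   4 m/s² are the push-off and first-step impact, and the local
   minimum before them is the start (first-step convention).
2. **Macro analysis** — the AP signal is reconstructed from an
   undecimated Daubechies-4 wavelet decomposition keeping only the
   0.5–15 Hz band (mean re-added). Local minima below an adaptive
   threshold

   `T_MA = (1/4) · mean(qualifying local maxima)`

   with topographic prominence > 15 m/s² bound the foot stances. The
   signal is integrated (trapezoid) between each pair of consecutive
   minima — the *acceleration impulse* (AI), ~5–7 m/s during CODs
   versus 1–3 m/s during displacement steps — and the four
   non-overlapping pairs with the largest AI are the COD segments.
   Angle classes follow the fixed protocol order 90-180-180-90.
3. **Micro analysis** — per-COD boundary refinement: M1 re-detects
   minima in a 0.5–5 Hz reconstruction; M2 (180° CODs) pulls the start
   back to the penultimate foot contact and pushes a still-positive end
   forward to the second toe-off; M3 snaps to sub-g samples of the
   acceleration norm (flight phases); M4 advances the COD 1 end past a
   trailing push-off peak. The default method map is COD1 = (M0, M4),
   COD2 = COD3 = (M2, M2), COD4 = (M0, M0).
4. **Completion time** — with `t̂` the detected end of COD 4, the test
   end `T` solves `∫ₜ̂ᵀ v_GNSS(t) dt = L_DP5 − L_AR` on the 10 Hz GNSS
   ground speed (final phase 9.14 m minus 1.42 m arm reach,
   sub-sample root by linear interpolation).
5. **Validation** — signed errors against 60 Hz reference labels
   (ε = T_ref − T_est), absolute/relative duration errors,
   Bland–Altman bias and 95 % limits of agreement (bias ± 1.96 SD),
   per-participant shift flags, KS / Shapiro–Wilk normality tests.

Because instrumented T-test recordings are not publicly available, the
package ships a synthetic trial generator (`simulate_trial()`) that
emulates the measurement conditions — per-step impact transients, COD
impulse bursts with the stated 5–7 m/s magnitudes, a plausible speed
profile over the ten-yard T geometry, ~9.8 s completion times, 60
Hz-quantized labels with ±3-frame jitter — so the entire pipeline is
testable end to end.

## Worked example

```r
library(codseg)
trial <- simulate_trial(trial_spec(seed = 1))
det <- detect_t_test(trial$trace, trial$speed)
det$timeline
#> <event_timeline> start 1.250 s, end 11.052 s
#>   COD1 ( 90 deg): 3.195 - 3.645 s
#>   COD2 (180 deg): 4.665 - 5.155 s
#>   COD3 (180 deg): 7.080 - 7.580 s
#>   COD4 ( 90 deg): 8.860 - 9.310 s
det$completion_time_s        # 9.80 s (photocell truth: 9.79 s)

labels <- quantize_labels(trial$truth, jitter_frames = 3, seed = 42)
event_errors(det$timeline, labels)
#>   order eps_start_ms eps_end_ms
#> 1     1    -45.00000  -28.33333
#> 2     2     18.33333   11.66667
#> 3     3    -46.66667  -30.00000
#> 4     4    -43.33333  -26.66667
round(total_cutting_time(det$durations), 2)
#> [1] 3.42 3.44 3.70 3.47
```

The event errors are tens of milliseconds — dominated by the simulated
60 Hz labelling jitter, not by the detector (with jitter and noise off,
the pooled detection SD collapses below 15 ms). The four total cutting
times (approach + COD + exit) are the per-COD performance metric that
correlates with the overall T-test score.

A reproducible benchmark summarises detection quality over many
trials:

```r
run_benchmark(n_trials = 10, seed_base = 1)
#> <benchmark_result> 10 trials (seeds 1..10)
#>   event error SD: 33.4 ms (LOA half-width 65.4 ms)
#>   completion error SD: 0.006 s
#>   max |mean rel. duration error|: COD 2.42%, DP 1.19%
```

## Command line

An exec script is installed at `system.file("exec", "codseg")`:

```sh
codseg simulate  --n 50 --seed 1 --out trials/
codseg detect    --trial trials/trial_0001 --emit-macro --emit-micro
codseg validate  --detections trials/ --labels trials/ --out report/
codseg report    --detections trials/ --out report/athletes.txt
codseg benchmark --n 50 --seed 1 --out report/benchmark.json
```

All thresholds live in a single JSON config
(`write_config(pipeline_config(), "cfg.json")`), overridable per run
with `--set key=value`.

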