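# gaitacf

Video-free gait quantification from 2D pose keypoints: cadence by
short-time autocorrelation pitch detection, and freezing-of-gait
periodicity scoring by DTW/kNN distances from a normal-gait reference.

## The problem

Clinical gait videos — a person with Parkinson's disease walking down a
hospital hallway toward a hand-held camera — carry no spatial calibration,
so step length, speed or clearance cannot be measured. What *can* be
measured from markerless 2D pose estimates alone is **cadence** (steps per
minute) and, for severely disturbed gait, *when* the legs are moving
periodically at all. `gaitacf` implements that analysis for 18-keypoint
body skeletons (the standard pose-estimator output), without ever touching
the video itself.

## The method

Two scalar gait signals are computed per frame from the hip and ankle
keypoints (P8/P10 right hip/ankle, P11/P13 left hip/ankle):

* **LRang** (lateral view, degrees) — the angle between the two
  hip-to-ankle vectors,
  `LRang = arccos( u_R · u_L / (|u_R| |u_L|) )`;
  one oscillation per *step*.
* **LRdiff** (frontal view, dimensionless) — the bilateral
  leg-length-ratio difference,
  `LRdiff = |u_L|/|u_R| − |u_R|/|u_L|`;
  one oscillation per *gait cycle* (two steps).

Both are invariant to image scale, so no calibration is needed. After
band-pass filtering (0.1–7 Hz, zero phase), a **short-time
autocorrelation** (ST-ACF) is computed in sliding Hann-tapered windows
(2 s for normal gait, 3 s for pathological gait; 0.01 s shift at 100 fps).
In each window the gait lag is the maximum of the autocorrelation in the
*second positive phase* after the initial negative phase, flagged
significant when it exceeds the 95% white-noise bound `1.96/√n_eff`. The
representative gait frequency is the reciprocal of the median significant
lag (×0.5 for lateral views, where LRang runs at step rate), and

```
cadence [steps/min] = 120 × gait frequency [Hz]
```

since one gait cycle is two steps. Autocorrelation is used instead of a
spectrogram because an STFT bin at these window lengths is 1/2 s = 0.5 Hz
wide — far coarser than the 0.01 s lag grid.

For freezing-of-gait sequences, where no single lag may be trustworthy,
each window's ACF curve is instead *scored against normal gait*: the
dynamic-time-warping distance to a reference control's mean ACF curve, and
the mean Euclidean distance to its k nearest curves in a normal ACF
library (k = 5). Low distances localize the moments of periodic stepping;
pooled distances separate disease groups (ANOVA, ROC AUC).

## Worked example

```r
library(gaitacf)

# simulate a 25 fps frontal-view walk at 1.1 Hz gait frequency
sim <- simulate_gait(gait_sim_config(gait_freq_hz = 1.1, duration_s = 10,
                                     fps = 25, noise_sd_px = 1,
                                     dropout_prob = 0.02, seed = 7))
seq <- resample_keypoints(clean_and_interpolate(sim$seq), target_fps = 100)
feature <- bandpass(compute_lrdiff(seq))
cad <- estimate_cadence(st_acf(feature, window_s = 2.0))
summary(cad)
#> Cadence: 131.9 steps/min (frontal view, 2 s windows)
#> Windows: 801 total, 801 valid, 801 with significant peak
#> Significant-lag quartiles: 0.91 / 0.91 / 0.92 s
sim$truth$cadence_steps_per_min
#> [1] 132
```

The median gait-cycle lag of 0.91 s converts to 120/0.91 = 131.9
steps/min, within one 0.01 s lag step of the simulated truth of 132.

The same stages run from a shell via the bundled CLI
(`inst/cli/gaitacf.R`): subcommands `simulate`, `features`, `cadence`,
`periodicity` and `run`, all emitting CSV/JSON artifacts.

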