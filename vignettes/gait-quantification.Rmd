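---
title: "Methods: cadence and periodicity from 2D pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cadence and periodicity from 2D pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitacf)
```

## The measurement model

`gaitacf` analyses uncalibrated 2D pose-keypoint sequences, as produced by
markerless pose estimators on ordinary clinical video. Because pixel
coordinates carry no metric scale, the package restricts itself to two
scale-invariant gait signals built from the hip and ankle keypoints
(indices 8/10 right, 11/13 left in the 18-point body map):

* **LRang** — the inter-leg angle
  $\mathrm{LRang}=\arccos\!\big(\vec u_R\cdot\vec u_L/(|\vec u_R||\vec u_L|)\big)
  \in[0^\circ,180^\circ]$, one cycle per *step*, informative in lateral
  (sagittal) views;
* **LRdiff** — the bilateral leg-length-ratio difference
  $\mathrm{LRdiff}=|\vec u_L|/|\vec u_R|-|\vec u_R|/|\vec u_L|$, one cycle
  per *gait cycle* (two steps), informative in frontal (coronal) views
  where the subject walks toward the camera.

LRang is invariant to uniform scaling and rigid rotation of the image;
LRdiff to uniform scaling and translation; swapping the legs negates
LRdiff exactly. These invariances are what make the signals usable without
camera calibration, and they are enforced by property tests.

Cadence follows from pitch detection on these signals. With one gait
cycle comprising two steps, a gait-cycle frequency of $f$ Hz is a cadence
of $120f$ steps/min; lateral-view LRang frequencies are halved first,
because LRang runs at step rate.

## Pipeline stages and their parameters

| stage | parameter | default | why |
|---|---|---|---|
| cleaning | `max_gap_s` | 0.2 s | estimator flicker spans a few frames; longer dropouts are real occlusions and stay invalid |
| resampling | `target_fps` | 100 | gives the ACF a 0.01 s lag grid; clinical video is 25–60 fps, so only upsampling is supported |
| filtering | band | 0.1–7 Hz | keeps locomotor (≈0.5–2 Hz) and tremor-band (4–7 Hz) content, rejects baseline drift and pose jitter |
| ST-ACF | `window_s` | 2 s normal, 3 s pathological | 2–3 steps must fit one window; pathological gait is slower |
| ST-ACF | `shift_s` | 0.01 s | one frame at the working rate; maximal temporal resolution |
| lag search | `lag_min_s`, `lag_max_s` | 1/7 s, 10 s | mirrors the 0.1–7 Hz band |
| lag search | `min_overlap_s` | 0.25 s | see "numerical choices" |
| kNN | `k` | 5 | small enough to stay local in a few hundred reference curves, large enough to smooth noise |

The window is mean-removed, then Hann-tapered, in that order; per-window
mean removal makes the DC rejection local rather than relying on the
global filter alone.

## Numerical choices

**Taper-compensated autocorrelation.** The raw tapered estimator
$r(\ell)=\sum_t w_t w_{t+\ell}/\sum_t w_t^2$ multiplies the true
autocorrelation by the taper's decaying overlap envelope, which drags the
second-positive-phase peak toward shorter lags by up to ~10% — far more
than the 0.01 s lag quantization the method is meant to deliver. The
package therefore divides each lag's product sum by the Hann taper's own
overlap energy at that lag before normalizing to $r(0)=1$. The
compensation is exact for the envelope; its cost is that the variance of
$r(\ell)$ grows as the overlap shrinks, so values can exceed 1 in
magnitude near the window-length lag. Two consequences are handled
explicitly:

* **Minimum-overlap guard.** Lags within `min_overlap_s` (0.25 s) of the
  window length are never selected as gait lags: there the estimate rests
  on a handful of samples and the amplified values are artifacts, not
  structure. 0.25 s of overlap at 100 fps is 25 samples, a conventional
  minimum for a correlation estimate.
* **Effective sample size.** The white-noise 95% bound $1.96/\sqrt{n}$ is
  only nominal if $n$ accounts for the taper. `st_acf()` stores
  $n_\mathrm{eff}=(\sum h^2)^2/\sum h^4\approx 0.51\,L$ for a Hann taper
  of $L$ samples, which restores the intended coverage at short lags; at
  long lags coverage degrades by construction (the compensation trade-off
  above), which is another reason for the overlap guard.

**Zero-phase band-pass.** The filter applies the two-pass (forward plus
backward) magnitude response of an order-4 Butterworth band-pass
spectrally: the FFT of the odd-reflection-padded signal is multiplied by
the bilinear-prewarped squared magnitude, squared again for the second
pass. This realization is exactly linear, exactly zero-phase (peak
timings feeding the ACF windows are not shifted), and rejects DC exactly.
A recursive forward–backward implementation of the same design is
numerically fragile at a 0.1 Hz edge on 100 Hz data (poles at
$|z|\approx0.994$) and leaks edge transients several seconds into the
record.

**Peak rule details.** Scanning lags above zero, the initial negative
phase is the first maximal run of $r<0$ and the secondary positive phase
the next maximal run of $r>0$; zeros terminate runs. Ties inside the
search run break toward the *smaller* lag (higher frequency). Windows
containing any invalid sample are excluded entirely rather than patched;
the representative lag is the median over windows whose peak clears the
significance bound. Degenerate frames (coincident hip and ankle, missing
keypoints) are masked invalid, never clamped, and the arccos argument is
clipped to $[-1,1]$ against rounding.

**DTW.** The distance between a query window's ACF curve and the
reference curve uses absolute-difference local cost, the symmetric step
set {diagonal, left, up}, and normalization by the warping-path length
(cell count, shortest among minimum-cost paths), so that 2 s and 3 s
windows yield comparable distances. The kernel is compiled (Rcpp); tests
pit it against a brute-force path-enumeration oracle.

## The reference: one control for DTW, a library for kNN

The DTW score compares each window against the *mean* ACF curve of a
single normal-gait sequence that passed a quality gate (cadence estimable
with at least 80% significant windows). Warping absorbs differences in
peak lag, so one control generalizes across normal cadences — this
tolerance is precisely why DTW is used.

The kNN score is different: Euclidean distance on raw ACF vectors is
cadence-sensitive, so against a single control it measures "distance from
this particular walk" and cannot distinguish a normal walker at another
cadence from a pathological one. `merge_references()` therefore pools the
curves of several controls spanning the normal cadence range into one
library, and `distance_series(..., knn_ref = )` scores queries against
it. The per-curve DTW alternative (minimum over reference windows) exists
behind `mode = "min"` but is quadratic in practice and not the default.

## What the synthetic generator does and does not emulate

`simulate_gait()` builds a schematic 2D skeleton whose *projected leg
lengths* oscillate in antiphase at the gait frequency (frontal view,
giving LRdiff ≈ $A(t)\sin 2\pi f t$) and whose *inter-leg angle*
oscillates at twice the gait frequency (lateral view, one LRang cycle per
step). It reproduces the signal phenomenology the pipeline consumes:
known cadence, multiplicative amplitude growth as the subject approaches
the camera, freezing episodes in which locomotion stops and a 4–7 Hz
tremor-band oscillation appears (inside the analysis passband, so the
pipeline sees it), Gaussian pixel noise, and random detection dropouts.
All randomness derives from one seed.

It is *not* a biomechanical model: no double-support timing, no arm
swing, no posture, no perspective distortion, no correlated estimator
failures (e.g. left/right swaps), and the freeze onset is a hard switch
rather than a gradual degradation. Passing tests therefore demonstrate
the signal-processing chain is correct and recovers known ground truth
under realistic noise — not that any clinical discrimination threshold
transfers to real patients.

`simulate_cohort()` fixes the three study-group conditions: *normal*
(steady 0.85–1.15 Hz gait, 1 px noise, 1% dropout), *mild* (halved
oscillation amplitude, ±10% frequency wobble — periodic small steps),
*severe* (≥40% of the duration frozen with tremor, ±20% wobble, further
reduced amplitude). The wobble is slow sinusoidal frequency modulation
integrated into the phase.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
12 s sequences at 100 fps for cadence recovery (five frequencies,
0.6–1.5 Hz), 50 frontal/lateral pairs of 10 s for view consistency, and a
30-sequence cohort (10 per group, 12 s each, 3 s windows at 0.01 s shift,
~900 windows per sequence) for the group comparison. These sizes give
stable medians and pooled distributions while keeping a full run in the
low minutes on one core.

## Known limitations

* Periodic stepping is detected, not forward progression: stepping in
  place at a normal rate is indistinguishable from walking.
* The 3 s pathological window may still be too short to hold 2–3 steps of
  a very slow gait, degrading the frequency resolution exactly where it
  is most needed.
* A sequence whose every window fails the significance bound yields no
  cadence, by design (`estimate_cadence()` raises a typed error carrying
  the per-window table for inspection).
* The lateral ×0.5 correction assumes LRang completes one cycle per step;
  strongly asymmetric gait (e.g. hemiparesis) breaks that assumption.
* Reference quality gates accept any convincingly periodic sequence —
  including, say, a periodic small-step gait — so the choice of controls
  remains the analyst's responsibility.
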