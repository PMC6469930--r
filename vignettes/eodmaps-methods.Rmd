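---
title: "Methods: from EOD pulses and trajectories to spatial and egocentric maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from EOD pulses and trajectories to spatial and egocentric maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Pulse-type weakly electric fish emit discrete electric organ discharges
(EODs); each pulse is one electrosensory sampling event, so the
instantaneous EOD rate (EODr) is a readout of sensory sampling effort. This
package implements the analysis chain that links sparse spiking of
hippocampus-like pallial (DDi) neurons to that active-sensing behavior:
spike-triggered averages of EODr, swim speed and sampling density; spatial
firing-rate maps with Skaggs information; swim-direction preference; and
egocentric landmark-position maps. A seeded synthetic-session generator
with known ground truth backs every stage with recovery and calibration
tests. This vignette states the conventions precisely, in pipeline order.

```{r setup}
library(eodmaps)
```

## Coordinates and the arena

All positions are in cm in the camera frame, y up, headings in radians
counterclockwise from +x. `arena_layout()` describes a circular tank
(default: 1.5 m diameter, center `(100, 75)`) with polygonal landmarks and
an optional home enclosure; `default_arena()` provides a ready-made layout.
The camera frame is 1600 x 1200 px at `pixel_scale` 0.125 cm/px.

## EOD processing

* `instantaneous_eod_rate()` sets EODr between consecutive pulses to the
  reciprocal of their interval (a step function), sampled onto the 15 Hz
  video grid with constant extrapolation at the edges.
* `detect_down_states()` returns maximal intervals with EODr below 50 Hz
  lasting at least 1 s — behavioral "down states" of reduced sampling.
* `blank_eod_artifacts()` zeroes a +/-2.8 ms window around every pulse in a
  wideband trace; at 20 kHz one pulse blanks exactly 113 samples.
  `count_threshold_crossings()` quantifies how many putative spikes the
  blanking removes.

## Kinematics

`compute_speed()` uses a central difference (one-sided at the edges).
`classify_swim_direction()` labels each frame by the sign of the velocity
projection on the body axis: these fish routinely swim backward, and the
tracked heading follows the head, not the motion. Frames slower than
1 cm/s are quiescent; turns pool with the swim state of matching
projection sign. The speed threshold and smoothing are configurable
(`analysis_config()`), since they are conventions rather than measured
constants.

## Spike-triggered averages

`spike_triggered_average()` collects the covariate in a +/-4 s window
around every spike (spikes whose window crosses a trial edge are dropped;
units under 10 spikes are skipped). The sampling density
(SmpD = EODr / speed, pulses/cm) average is the mean of per-spike
elementwise quotients — not the quotient of the mean traces — with the
speed floored at 0.5 cm/s (`st_sampling_density()`).

Significance uses a circular-shift null: `circular_shift_null()` rotates
the spike train by 100 random offsets in `[30 s, T - 30 s]`, preserving
spike count and the circular inter-spike-interval multiset.
`test_mean_elevation()` compares observed per-spike window means against
the pooled null by Kruskal-Wallis; `test_peak()` compares each spike's
value at the mean-trace extremum lag with its own whole-window mean by a
paired Wilcoxon sign-rank test. `peak_dip_timing()` measures per-spike
extremum lags (dips = smallest interior local minimum, plateaus resolved to
their center, ties toward lag 0) and applies a sign test to the median.

## Occupancy and rate maps

`build_occupancy()` divides the tank's bounding box into 16 x 16 cm bins
anchored at its corner. A visit is counted when the head enters a bin;
staying within the bin counts once. Bins with fewer than five visits are
excluded. Occupancy probabilities `p_i` are normalized over the *included*
bins so that `sum(p_i) = 1`; with total-trial-time normalization the two
conventions coincide whenever exclusions are few, but only the included-bin
normalization makes `r_m = sum(p_i r_i)` the occupancy-weighted mean rate
of the analyzed bins, which the information measure requires.

`build_rate_map()` divides spike counts by time per included bin (display
values clipped at the 97th percentile). `place_information()` computes
Skaggs information `sum(p_i (r_i/r_m) log2(r_i/r_m))` in bits/spike.
`place_info_significance()` recomputes it for 1000 surrogate trains —
either circularly shifted (preserving ISI structure) or uniformly shuffled
spike times — and flags units above the null's 95th percentile, also
reporting permutation and t-test p-values. The shuffle null is the more
permissive of the two; the package's acceptance battery asserts that
ordering rather than any absolute count. `stationarity_check()` compares
firing rates across five bins per trial half by Kruskal-Wallis, and
`landmark_removal_effect()` / `landmark_effect_test()` compare normalized
rates in bins within 10 cm of a landmark polygon before and after its
removal.

## Egocentric landmark analysis

`direction_preference_index()` is
`(FR_forward - FR_backward) / (FR_forward + FR_backward)`; negative values
mean backward-swim preference.

`rasterize_arena()` converts the arena to a 160 x 120 binary matrix (10 x
10 px elements, 1.25 cm at the default scale) marking landmarks, home and
the tank wall. `egocentric_transform()` re-samples that raster around the
fish — position at the center element, heading rotated to "north" — by
inverse mapping with containing-element lookup; elements whose source
falls outside the frame are invalid (`NA`). `accumulate_stlm_ptlm()`
averages the transformed raster at every spike (STLM) and at poses
downsampled every 1.33 s (PTLM); the elementwise quotient of per-element
means estimates landmark-presence probability given a spike. Elements
whose PTLM is zero or below its lower 10th percentile are masked, the map
is cropped to a +/-10 cm window and normalized to its maximum.

`ap_lr_preference()` splits that window left/right of the midline and
anterior/posterior at one third of a body length *behind* the head — the
boundary between the anterior third and posterior two thirds of a 15 cm
fish, with the head as tracked point — and forms
`(maxR - maxL)/(maxR + maxL)` and `(maxA - maxP)/(maxA + maxP)` from the
per-region maxima, so positive means right/anterior. Elements exactly on
a boundary belong to neither region.

## Synthetic sessions and ground truth

`simulate_trial()` composes:

* `generate_trajectory()` — a correlated random walk with wall avoidance,
  intermittent landmark-approach bouts, slowed swimming near landmarks,
  backward-swim episodes and quiescent episodes; ground-truth labels are
  returned per frame. Active speed stays above the quiescence threshold so
  labels remain self-consistent.
* `generate_eod_train()` — an inhomogeneous gamma-renewal pulse train
  (time-rescaling); the default shape 500 gives the few-percent ISI jitter
  of real, clock-like EOD trains. The target rate is 70 Hz while active,
  40 Hz during quiescence, plus a smoothed transient near landmarks.
* `generate_spikes()` — a per-frame Poisson process whose intensity is the
  baseline times place-field, swim-direction, EOD-coupling, speed-coupling
  and landmark-driver gains, suppressed during quiescence. Every effect can
  be switched off, which is what the null-calibration tests rely on.

All randomness derives from the master seed; identical seeds give
bit-identical sessions.

## Running a session

```r
bundle <- simulate_trial(default_arena(), duration = 1800, seed = 1)
report <- run_session(bundle, analysis_config())
report
dir <- tempfile()
write_trial(bundle, dir)      # trajectory.csv, eod_pulses.csv, spikes_*.csv,
                              # arena.json, ground_truth.json
write_session_report(report, dir)  # report.json + tidy sta.csv
```

`load_trial()` reads the same interchange files back (validating schemas,
interpolating single-frame tracking gaps, rejecting non-monotone spike
times), so externally recorded sessions enter the pipeline through the
same door as synthetic ones.
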