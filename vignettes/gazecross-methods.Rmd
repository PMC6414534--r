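---
title: "Methods: gaze parsing, similarity mapping and decision statistics in gazecross"
author: "gazecross maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze parsing, similarity mapping and decision statistics in gazecross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gazecross` implements an analysis pipeline for eye-tracking studies of
road-crossing behaviour: 1000 Hz gaze streams recorded while observers
watch 10-second road-traffic videos and press a button whenever they judge
crossing to be safe. This vignette documents the models and procedures,
the parameters that matter, the synthetic-data generator used to validate
everything, and the numerical choices made where the design was open.
It states no empirical result that the package's tests and scripts do not
themselves compute.

## Screen geometry and angular units

All velocity thresholds are expressed in degrees of visual angle, the
natural unit for oculomotor events. The reference monitor is 1920 x 1080
pixels, 521 x 293 mm, viewed at 600 mm, giving a 46.9 x 27.4 degree field
of view. Large extents use the centred-chord formula
$\theta = 2\arctan\!\left(\frac{e\,m/2}{D}\right)$ (extent $e$ px,
$m$ mm/px, distance $D$); per-sample displacements are tiny, so sample
velocities use the local linear factor $m/D$ at screen centre
(about 0.0259 deg/px here). The small-angle approximation deviates from
the chord formula by under 1% below 5 degrees, which the tests verify.

## Oculomotor event parsing

Samples are parsed into **fixations**, **saccades**, **smooth pursuits**
and **missing** spans (blinks / track loss; invalid samples keep their
last coordinates but are excluded from every computation).

1. **Velocity.** Central-difference displacement per axis, converted to
   deg/s, then smoothed with a centred 20 ms moving average. The central
   difference spreads a single-sample jump over two samples; the 20 ms
   window suppresses 1000 Hz sensor noise without blunting saccade peaks.
   Speed is undefined at trace ends and next to invalid spans.
2. **Saccades.** Maximal runs with speed above 50 deg/s (the conventional
   video-oculography threshold).
3. **Smooth candidates.** Maximal non-saccade runs at or below 30 deg/s
   lasting at least 100 ms (inclusive bound). Samples in the intermediate
   30-50 deg/s band belong to fixations: only the pursuit-candidate and
   saccade bands are defined by the procedure.
4. **Pursuit score.** Each candidate is fitted by degree-2 polynomials
   $x(t), y(t)$ (curved pursuit without overfitting jitter), after one
   robust cleaning pass that drops samples whose pooled residual deviates
   from the median by more than 3 MAD-based SDs. The score is
   $P_{RMSE} / \exp(A)$: the pooled root-mean-square residual divided by
   the exponential of the fitted curve's arc length, both in pixels.
   Pixel units make the discriminator behave sensibly with the
   $10^{-9}$ threshold: a true pursuit traces tens to hundreds of pixels
   of arc, so $\exp(A)$ is astronomically large and the score collapses;
   a jittering fixation yields a near-point curve and a score of the
   order of the jitter SD. Scores below $10^{-9}$ are labelled pursuit,
   guarded by a 10 px minimum displacement so a noiseless static segment
   (score exactly 0) cannot masquerade as pursuit.
5. **Cleanup and partition.** Everything not saccade, pursuit or missing
   is fixation. Transition slivers shorter than 20 ms (created by the
   velocity smoothing at event boundaries) are absorbed into the longer
   neighbouring segment. Segments are half-open intervals
   `[t_start, t_end)`, so per-label totals plus missing time equal the
   trial duration exactly, in milliseconds.

**Quality control.** A trial is removed when strictly more than half of
its valid samples exceed the saccade threshold; a participant is excluded
when strictly more than half of their trials are removed. Both rules are
strict majorities: exactly half survives.

The parser is validated two ways: against the simulator's ground-truth
sample labels (at least 95% sample agreement over 100 default-noise
scripts), and against an independently coded one-pass reference parser
(exact boundary equality on short traces).

## Gaze maps and similarity

A trial's gaze map accumulates valid sample positions on the screen grid
(default 4x downsampled: the 1 degree smoothing kernel spans ~39 px, so
full resolution is redundant and pairwise correlations are invariant to
modest downsampling), convolves with an isotropic Gaussian of SD 1 degree
of visual angle, and z-scores over grid cells. Smoothing uses
renormalised truncated kernels (each kernel row re-sums to 1 at the
borders), so expected intensity stays uniform at the edges and maps from
independent random scanpaths correlate around zero rather than sharing a
border artefact. Smoothing and z-scoring commute for every correlation
computed downstream (Pearson r is affine-invariant), so the order is a
free choice.

The **gaze similarity matrix** is the trial-by-trial matrix of Fisher
z-transformed Pearson correlations between flattened maps; correlations
are clipped at $|r| = 1 - 10^{-6}$ so duplicate maps stay finite. All
valid samples enter the maps regardless of event label, since the mapped
quantity is gaze position as such; a label filter can be applied
upstream. The group **similarity curve** is the across-participant mean
of each trial's mean similarity to all other trials, sorted descending,
with percentile-bootstrap confidence intervals from resampling
participants (1000 resamples by default) — participants, not trials, are
the exchangeable unit for group inference.

## Pixel-wise statistical mapping

The mapping stage asks where on the stimulus gaze density differs by
experimental factor (age group, pedestrian presence, traffic density).
A full per-pixel linear mixed model with crossed random intercepts is
approximated by the classical two-stage summary-statistics approach: maps
are averaged within participant x condition cells (absorbing the subject
random intercept and stimulus variation), then an ordinary linear model
is fitted at every grid cell and the requested term is tested by a
full-versus-reduced F comparison. Under balanced designs this gives the
same fixed-effect inference as the mixed model, with no per-pixel
iterative fitting — and per-pixel mixed models of this kind must
typically drop their random slopes to converge anyway, which narrows the
practical gap further.

Multiple comparisons are handled by a **bootstrap cluster-mass test**:
the cluster-forming threshold is the pointwise $1-\alpha$ F quantile;
4-connected suprathreshold clusters are scored by mass (summed F, more
sensitive than extent alone); the null distribution of the maximum
cluster mass comes from resampling whole participants' full-model
residual maps (cells matched by condition) on top of the reduced-model
fit — respecting the subject as the exchangeable unit — and observed
clusters above the null $1-\alpha$ mass quantile survive. Familywise
error calibration (at most 0.10 observed at nominal 0.05 over 20 null
cohorts) and planted-effect recovery (Jaccard at least 0.5 against a
planted disc) are exercised by the test suite at a 480 x 270 grid with
200 bootstrap resamples, sizes chosen to make the calibration study a
routine part of the suite. Significant areas are reported rescaled to
full-resolution pixel units. Pairwise group contrasts use the same
machinery on per-participant mean maps, reporting a signed t grid.

## Decision statistics

- **k-means++** (`kmeans_pp`): Lloyd's algorithm with probabilistic
  far-point seeding, 1000 restarts by default ("restarts" being the
  natural reading of running the clustering repeatedly to verify that
  centroids group consistently); best weighted by lowest within-cluster
  sum of squares, ties to the earliest restart; centroids reported
  sorted. Empty clusters are revived at the farthest point.
- **Yuen's test** (`yuen_test`): 20% trimmed means with winsorized
  variances and Welch-Satterthwaite degrees of freedom; at `trim = 0` it
  reduces exactly to Welch's t test, which the tests verify to 1e-10.
  The effect size is the explanatory (xi-type) robust measure — variance
  of the trimmed group means over a winsorized-variance estimate of total
  variance (rescaled by the normal-consistency constant, 0.412 at 20%
  trim) — signed by the direction of the difference and reported as `d`.
- **Shift function** (`shift_function`): Harrell-Davis estimates of
  deciles 1-9 for each sample, their differences, and percentile-bootstrap
  confidence intervals from independent resampling of each sample.
- **Traffic dichotomisation** (`density_split`): the fixed rule calls a
  trial dense when strictly more than 3 vehicles are on screen. The KDE
  rule estimates the threshold from data as the half-mass point (smoothed
  median) of a Gaussian KDE with Silverman bandwidth: on a bimodal
  low/high traffic mixture this lands stably in the valley between the
  regimes (~3 vehicles), where discrete sample modes are unstable — a
  deliberate choice of "centre" over the global mode, which for skewed
  count mixtures sits inside the low-traffic component.

## Traffic density from video

Vehicle counts come from per-pixel Gaussian-mixture background
subtraction (3 components; online updates; a pixel's background is its
highest-ranked components by weight/SD up to a 0.6 cumulative-weight
fraction) followed by blob analysis: 3x3 morphological opening,
8-connected component labelling, minimum blob area 40 px at toy-video
scale. The learning rate defaults to 0.02, kept deliberately low so that
road pixels crossed by several successive vehicles do not absorb the
vehicle intensity into the background. The per-trial count is the
**maximum simultaneous** per-frame count, matching the on-screen reading
of the dense-traffic rule. Counting is invariant to a global brightness
offset and monotone in the area threshold.

## The synthetic-data generator

Because the analysis is validated without access to recordings, the
generator produces every input with the statistical structure the
analysis assumes, and with ground truth:

- **Scanpaths** (`simulate_scanpath`): scripted event sequences rendered
  at 1000 Hz. Fixations are static positions plus isotropic Gaussian
  jitter (SD 0.5 px, in the range of a tower-mounted tracker's filtered
  noise); pursuits move linearly at scripted speed (8-15 deg/s for
  vehicle-like targets) and heading; saccades are raised-cosine
  transitions of 30-60 ms, which reach peak velocities well above
  200 deg/s at typical amplitudes — a triangular-profile stand-in that
  deliberately omits a main-sequence model, since no downstream stage
  uses saccade kinematics beyond threshold crossing.
- **Cohorts** (`simulate_cohort`): groups defined by a spatial bias
  mixture over the vehicle appearing point (upper-left road entry), the
  sidewalk band, and vehicle-following pursuit. Defaults emulate the
  study design — 100 trials x 10 s x 1000 Hz; group sizes 29/28/10;
  younger children more diffuse (larger spread, more sidewalk weight,
  larger pedestrian boost); decision counts for the two child groups use
  the reference cluster parameters (means 8 and 13, SD 1), with adults
  matching the older children, per-trial counts drawn around the
  participant mean, rounded and floored at zero, and log-normal press
  durations (median 500 ms).
- **Traffic videos** (`render_traffic_video`): static textured background,
  vehicles as bright rectangles entering at a fixed appearing point and
  staggered so all co-occur on screen, an optional slow pedestrian blob
  on the sidewalk band, per-frame sensor noise, and a vehicle-free
  burn-in for the background model.

What the generator does *not* emulate: real scene content and its
bottom-up salience, gaze-contingent behaviour, main-sequence saccade
kinematics, drift/microsaccades, calibration error, and vehicle
appearance variation. Passing tests therefore demonstrate that the
pipeline recovers known structure of this idealised kind — correct event
boundaries, planted spatial effects, generating cluster means, true
vehicle counts — not that it would make identical claims on real
recordings.

## Problem sizes and numerical choices

The test suite and the analysis scripts run everything at reduced but
non-trivial sizes chosen as routine desk-scale experiments: 100
ten-second scripts for parser recovery; 100-map similarity nulls; a
480 x 270 statistical-map grid with 200 bootstrap resamples and 20 null
cohorts for calibration; 2000 replicates for the Yuen level check; 200
simulations for shift-function coverage; 100 replicates of the
two-cluster recovery; toy videos of 160 x 120 x 120 frames. The
`analysis/` drivers use a 16-participant, 12-trial, 2-second cohort.
Further numerical conventions: Fisher clipping at $1-10^{-6}$;
polynomial fits on centred time in seconds for conditioning; arc length
by trapezoid integration of the analytic derivative; residual sums below
$10^{-12}$ of the response scale treated as exact fits (F set to 0);
degenerate smooth segments (fewer than degree + 2 samples) fall back to
fixation; a single-participant similarity curve degenerates its CI to
the estimate with a warning.

## Known limitations

The two-stage statistical map is exact only for balanced designs; badly
unbalanced cells deserve the mixed-model route it approximates. The
bootstrap cluster test needs enough participants for resampling to make
sense (the suite uses 8 per group). Blob counting merges touching
vehicles by construction and cannot separate occlusions. The KDE
threshold assumes the traffic-count distribution is genuinely bimodal;
unimodal distributions yield its smoothed median, which is then a
somewhat arbitrary split. None of the defaults have been tuned to any
particular real dataset.
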