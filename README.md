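# gazecross

Eye movements decide what a pedestrian knows about approaching traffic.
`gazecross` is an R package for analysing gaze behaviour and crossing
decisions in road-crossing experiments: observers watch videos of a road
with varying traffic density (with or without pedestrian distractors)
while their gaze is sampled at 1000 Hz, and they press a button whenever
they judge crossing to be safe. The package is aimed at visual-attention
and developmental researchers who need the full chain from raw gaze
samples to corrected statistical maps and robust group comparisons — and
at anyone who wants to validate such a chain against data with known
ground truth, which the built-in simulator provides.

## What it computes

**Oculomotor event parsing.** Samples become fixations, saccades and
smooth pursuits. Saccades exceed a 50 deg/s velocity threshold. Pursuit
candidates are smooth segments at <= 30 deg/s for >= 100 ms; each is
fitted by degree-2 polynomials in x(t), y(t) and scored by

```
P_RMSE / exp(A)
```

the root-mean-square fit residual over the exponential of the fitted
curve's arc length (both in pixels). Scores below 1e-9 are pursuit: a
genuinely moving eye traces a long curve, exp(A) explodes and the score
collapses; a jittering fixation does not. Trials whose valid samples are
majority supra-threshold are removed, participants with a majority of
removed trials are excluded.

**Gaze similarity.** Per trial, a smoothed (1 degree of visual angle)
z-scored gaze-density map; per participant, the trial-by-trial matrix of
Fisher-z correlations between maps (GSM); per group, the sorted mean
similarity curve with participant-level bootstrap confidence intervals —
a measure of how consistently a group deploys its gaze across trials.

**Pixel-wise statistical mapping.** A two-stage linear-model
approximation of per-pixel mixed models (cell means per participant x
condition, then an F test per grid cell), corrected by a bootstrap
cluster-mass test that resamples participants. Reports significance
masks, cluster tables and significant areas in screen-pixel units, plus
signed pairwise group contrasts.

**Decision statistics.** k-means++ with 1000 restarts for data-driven
clustering of per-participant crossing-decision counts; Yuen's 20%
trimmed-mean test with winsorized variances and an explanatory effect
size; Harrell-Davis shift functions with bootstrap CIs; traffic-density
dichotomisation (dense = more than 3 vehicles on screen, or a KDE-based
threshold).

**Traffic density from video.** Per-pixel Gaussian-mixture background
subtraction and blob analysis count moving vehicles per frame; the trial
density is the maximum simultaneous count.

**Synthetic data.** Scripted 1000 Hz scanpaths with ground-truth labels,
full cohorts with group-dependent spatial gaze biases and decision
distributions, and toy traffic videos with known vehicle counts.

## Worked example

Parse a scripted trial (4 s fixation, 40 ms saccade, ~6 s pursuit at
10 deg/s) and recover the structure, then cluster decision counts drawn
from two groups:

```r
library(gazecross)
geom <- screen_geometry(1920, 1080, 521, 293, 600)  # px, mm, mm distance

script <- scanpath_script(data.frame(
  label       = c("fixation", "saccade", "pursuit"),
  duration_ms = c(4000, 40, 5960),
  x = c(400, NA, 900), y = c(300, NA, 600),
  speed_deg_s = c(NA, NA, 10), heading_deg = c(NA, NA, 20)))
sim <- simulate_scanpath(script, geom, seed = 42)
events <- parse_trial(sim$recording, geom)
events[, c("label", "t_start_ms", "t_end_ms", "duration_ms")]
#>     label t_start_ms t_end_ms duration_ms
#>  fixation          0     3995        3995
#>   saccade       3995     4044          49
#>   pursuit       4044    10000        5956
mean(attr(events, "sample_labels") == sim$labels)   # 0.999

set.seed(1)
counts <- c(rnorm(30, 8, 1), rnorm(30, 13, 1))      # decision counts
km <- kmeans_pp(counts, k = 2, n_restarts = 1000, seed = 1)
km
#> <kmeans_pp> k = 2, WCSS = 43.11 (1000 restarts)
#>  centroids: 8.082, 13.13
yuen_test(counts[km$assignments == 1], counts[km$assignments == 2])
#> Yuen's test (20% trimmed means): t = -21.625, df = 33.38, p = 3.304e-21, d = -0.682
```

The parser finds one segment per scripted event, boundaries within 10 ms
of the script (velocity smoothing shifts threshold crossings by a few
samples), and 99.9% of samples carry the generating label. The
two-cluster centroids round to the generating means of 8 and 13 presses,
and Yuen's test separates the clusters decisively.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study pipeline on a
simulated cohort, writing tables to `results/` (intermediates under
`scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R     # cohort, metadata, decisions
Rscript analysis/02_parse_events.R        # events, QC, group summaries
Rscript analysis/03_gaze_similarity.R     # GSMs and group curves
Rscript analysis/04_statistical_maps.R    # corrected F maps, contrasts
Rscript analysis/05_crossing_decisions.R  # k-means, Yuen, shift function
Rscript analysis/06_traffic_density.R     # vehicle counting vs ground truth
```

With the default seed the similarity step prints group mean similarities
of 0.57 (adult), 0.39 (11-15) and 0.09 (5-10) — the concentrated groups
are the consistent ones — and the decision step recovers the two press
clusters and a decile-wise shift of about -4.6 presses between them.

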