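#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates a scaled-down synthetic cohort with the structure of the road
# crossing experiment: three age groups with group-specific gaze biases
# (appearing point / sidewalk distraction / vehicle following), per-trial
# pedestrian and traffic-density metadata, and crossing-decision records
# whose group means follow the reference cluster parameters (8 vs 13
# presses, SD 1). The full-size design (100 trials x 10 s x 1000 Hz,
# 67 participants) is the generator default; here we run a reduced cohort
# so the whole workflow completes in minutes.

library(gazecross)

seed <- 20240917
geom <- screen_geometry(1920, 1080, 521, 293, 600)

spec <- cohort_spec(
  geom,
  groups = list(
    child_5_10 = list(n_participants = 6, weights = c(0.45, 0.30, 0.25),
                      spread_px = 160, ped_sidewalk_boost = 0.25,
                      decision_mean = 8, decision_sd = 1),
    child_11_15 = list(n_participants = 6, weights = c(0.70, 0.10, 0.20),
                       spread_px = 90, ped_sidewalk_boost = 0.05,
                       decision_mean = 13, decision_sd = 1),
    adult = list(n_participants = 4, weights = c(0.80, 0.05, 0.15),
                 spread_px = 60, ped_sidewalk_boost = 0.02,
                 decision_mean = 13, decision_sd = 1)),
  n_trials = 12, trial_duration_ms = 2000, rate_hz = 500)

message("simulating cohort (16 participants x 12 trials, 2 s at 500 Hz) ...")
cohort <- simulate_cohort(spec, seed = seed, keep_labels = TRUE)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

write_metadata_csv(cohort$metadata, "results/trial_metadata.csv")
write_decisions_csv(cohort$decisions, "results/decisions.csv")
write.csv(cohort$design, "results/design.csv", row.names = FALSE)
saveRDS(cohort, "scratch/cohort.rds")

n_samples <- sum(vapply(cohort$recordings,
                        function(p) sum(vapply(p, function(r) length(r$t),
                                               0L)), 0L))
message(sprintf("done: %d participants, %d trials each, %.1fM gaze samples",
                length(cohort$recordings), nrow(cohort$metadata),
                n_samples / 1e6))
message(sprintf("pedestrian trials: %d / %d; dense-traffic trials: %d",
                sum(cohort$metadata$pedestrian_present),
                nrow(cohort$metadata),
                sum(cohort$metadata$density_class == "high")))
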