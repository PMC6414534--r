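#!/usr/bin/env Rscript
# Step 5: road-crossing decision statistics.
#
# Clusters per-participant mean press counts with k-means++ (k = 2, 1000
# restarts), compares the clusters' press counts and press durations with
# Yuen's 20% trimmed-mean tests, summarises distributional differences
# with a Harrell-Davis shift function, and dichotomises traffic density
# from the per-trial vehicle counts.

library(gazecross)

cohort <- readRDS("scratch/cohort.rds")
dec <- cohort$decisions
grp <- cohort$design$age_group[match(dec$participant_id,
                                     cohort$design$participant_id)]

per_part <- aggregate(n_presses ~ participant_id, data = dec, FUN = mean)
km <- kmeans_pp(per_part$n_presses, k = 2, n_restarts = 1000, seed = 99)
print(km)
message(sprintf("rounded cluster means: %d and %d presses",
                round(km$centroids[1]), round(km$centroids[2])))

cl <- km$assignments[match(dec$participant_id, per_part$participant_id)]
lo <- dec$n_presses[cl == 1]
hi <- dec$n_presses[cl == 2]
yu <- yuen_test(lo, hi)
message("press counts, low vs high cluster: ")
print(yu)

dur <- vapply(dec$press_durations_ms, function(d) {
  if (length(d)) mean(d) else NA_real_
}, numeric(1))
yu_dur <- yuen_test(dur[cl == 1 & !is.na(dur)], dur[cl == 2 & !is.na(dur)])
message("mean press durations, low vs high cluster: ")
print(yu_dur)

sf <- shift_function(lo, hi, n_boot = 1000, seed = 5)
message("decile shift function (low - high cluster presses):")
print(round(sf, 2), row.names = FALSE)

kde_thr <- attr(density_split(cohort$metadata$n_vehicles, rule = "kde"),
                "threshold")
message(sprintf("KDE traffic-density threshold: %.2f vehicles (fixed rule: > 3)",
                kde_thr))

res <- data.frame(
  comparison = c("press_count", "press_duration"),
  t = c(yu$statistic, yu_dur$statistic),
  df = c(yu$df, yu_dur$df),
  p = c(yu$p.value, yu_dur$p.value),
  d = c(yu$effect_size, yu_dur$effect_size))
write.table(format(res, digits = 4), "results/decision_tests.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(format(sf, digits = 4), "results/decision_shift_function.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
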