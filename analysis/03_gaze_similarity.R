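#!/usr/bin/env Rscript
# Step 3: gaze maps and gaze similarity matrices.
#
# Builds a smoothed (1 degree of visual angle) z-scored gaze map per trial
# and participant, correlates maps across trials within each participant
# (Fisher z), and summarises each group as a sorted similarity curve with
# participant-level bootstrap confidence intervals. Spatially concentrated
# groups (older observers locked on the vehicle appearing point) should sit
# above diffuse ones.

library(gazecross)

geom <- screen_geometry(1920, 1080, 521, 293, 600)
cohort <- readRDS("scratch/cohort.rds")

groups <- split(unique(cohort$design$participant_id),
                cohort$design$age_group[!duplicated(cohort$design$participant_id)])

message("building gaze maps and similarity matrices ...")
maps_by_part <- lapply(cohort$recordings, function(recs) {
  lapply(recs, build_gaze_map, geometry = geom, downsample = 8)
})
saveRDS(maps_by_part, "scratch/gaze_maps.rds")

curves <- list()
for (g in names(groups)) {
  mats <- lapply(groups[[g]], function(pid) {
    similarity_matrix(maps_by_part[[pid]])
  })
  cur <- similarity_curve(mats, n_boot = 1000, seed = 42)
  cur$age_group <- g
  cur$rank <- seq_len(nrow(cur))
  curves[[g]] <- cur
  message(sprintf("  %-12s mean similarity z = %.3f  [curve %.3f .. %.3f]",
                  g, mean(cur$mean_z), max(cur$mean_z), min(cur$mean_z)))
}
curves <- do.call(rbind, curves)
write.table(format(curves, digits = 4), "results/similarity_curves.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

adult <- curves[curves$age_group == "adult", "mean_z"]
young <- curves[curves$age_group == "child_5_10", "mean_z"]
message(sprintf("adult curve above 5-10 y/o curve on %d / %d sorted positions",
                sum(adult > young), length(adult)))
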