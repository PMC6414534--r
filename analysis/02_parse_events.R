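#!/usr/bin/env Rscript
# Step 2: oculomotor event parsing and quality control.
#
# Parses every trial into fixations, saccades and smooth pursuits
# (50 deg/s saccade threshold; pursuit = smooth segment at <= 30 deg/s for
# >= 100 ms whose polynomial-dispersion score P_RMSE / exp(A) falls below
# 1e-9), applies the majority-noise QC rules, and tabulates per-group event
# counts and trial-time proportions. Also scores the parser against the
# simulator's ground-truth sample labels.

library(gazecross)

geom <- screen_geometry(1920, 1080, 521, 293, 600)
cohort <- readRDS("scratch/cohort.rds")

qc <- qc_filter(cohort$recordings, geom)
message(sprintf("QC: %d trials removed, %d participants excluded",
                nrow(qc$removed_trials), length(qc$excluded_participants)))

rows <- list()
all_events <- list()
agree_n <- agree_ok <- 0
for (pid in names(qc$kept)) {
  grp <- cohort$design$age_group[match(pid, cohort$design$participant_id)]
  for (tid in names(qc$kept[[pid]])) {
    seg <- parse_trial(qc$kept[[pid]][[tid]], geom)
    all_events[[paste(pid, tid)]] <- seg
    truth <- cohort$labels[[pid]][[tid]]
    lab <- attr(seg, "sample_labels")
    agree_ok <- agree_ok + sum(lab == truth)
    agree_n <- agree_n + length(lab)
    summ <- summarize_events(seg)
    summ$participant_id <- pid
    summ$trial_id <- tid
    summ$age_group <- grp
    rows[[length(rows) + 1]] <- summ
  }
}
events <- do.call(rbind, rows)
message(sprintf("sample-level agreement with ground truth: %.2f%%",
                100 * agree_ok / agree_n))

write_events_tsv(do.call(rbind, all_events), "results/events.tsv")

# group summary in the shape of a global-characteristics table
tab <- aggregate(cbind(count, total_ms, proportion) ~ age_group + label,
                 data = events[events$label != "missing", ], FUN = mean)
tab <- tab[order(tab$label, tab$age_group), ]
write.table(format(tab, digits = 4), "results/event_summaries.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message("per-group mean event counts and trial-time proportions:")
print(tab, row.names = FALSE, digits = 3)
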