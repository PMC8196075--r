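#!/usr/bin/env Rscript
# Segment struggle bouts from the simulated pose table written by
# 01_simulate_session.R, compare against ground truth, and export the
# bout table and per-type summary.

library(strugglescope)

in_dir <- "results/session_seed1"
stopifnot(file.exists(file.path(in_dir, "pose.csv")))

track <- read_pose_table(file.path(in_dir, "pose.csv"))
speeds <- compute_speeds(track)
mob <- classify_mobility(speeds)
cat("adaptive thresholds (px/frame):",
    paste(sprintf("%s=%.3f", names(mob$thresholds), mob$thresholds),
          collapse = ", "), "\n")

bouts <- segment_bouts(mob, session_id = "seed1")
write_bout_table(bouts, file.path(in_dir, "bouts.csv"))
write_bout_table(bouts, file.path(in_dir, "bouts.bed"), format = "bed")

s <- summarize_bouts(bouts)
print(s$by_type)
cat(sprintf("immobile: %.1f%% of trial\n", s$pct_immobile))

truth <- yaml::read_yaml(file.path(in_dir, "ground_truth.yaml"))$bouts
truth_df <- as.data.frame(truth)
m <- match_bouts(bouts, truth_df)
cat(sprintf("recovery vs ground truth: recall %.2f, FDP %.2f, type accuracy %.2f\n",
            m$recall, m$fdp, m$type_accuracy))
write.csv(s$by_type, file.path(in_dir, "bout_summary.csv"), row.names = FALSE)
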