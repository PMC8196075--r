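#!/usr/bin/env Rscript
# Simulate one 30-min restraint session (pose track + two-channel
# photometry with ground truth) and write it to the on-disk text formats
# that the readers consume.

library(strugglescope)

out <- "results/session_seed1"
seed <- 1

bp <- behavior_sim_params(seed = seed)
pose <- simulate_pose_session(bp)
phot <- simulate_photometry_session(photometry_sim_params(seed = seed),
                                    pose$truth$bouts)
paths <- write_simulated_session(pose, phot, out)

truth <- pose$truth$bouts
cat(sprintf("session: %d s at %g fps, %d true bouts (%s)\n",
            bp$session_s, bp$fps, nrow(truth),
            paste(sprintf("%s=%d", names(table(truth$type)),
                          as.integer(table(truth$type))), collapse = ", ")))
cat(sprintf("photometry: %d samples at %g Hz, %d true transients\n",
            length(phot$recording$time), phot$recording$sample_rate,
            nrow(phot$truth$transients)))
cat("wrote:", paste(paths, collapse = ", "), "\n")
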