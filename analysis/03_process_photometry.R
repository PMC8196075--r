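#!/usr/bin/env Rscript
# Process the simulated two-channel recording: isosbestic regression,
# dF/F, airPLS baseline correction, session Z-scoring, and transient
# detection at the 2.91 Z outlier threshold.

library(strugglescope)

in_dir <- "results/session_seed1"
rec <- read_photometry_table(file.path(in_dir, "photometry.csv"))
print(rec)

proc <- process_photometry(rec)
cat(sprintf("isosbestic fit: slope %.3f, intercept %.3f\n",
            proc$fit$slope, proc$fit$intercept))
cat(sprintf("detected %d transients; frequency %.4f Hz\n",
            nrow(proc$transients), proc$frequency_hz))
write_transient_table(proc$transients, file.path(in_dir, "transients.csv"))

# standardized trace for downstream alignment
write.csv(proc$z, file.path(in_dir, "session_z.csv"), row.names = FALSE)
cat("wrote transients.csv and session_z.csv\n")
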