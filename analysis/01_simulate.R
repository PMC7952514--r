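#!/usr/bin/env Rscript
# Simulate one resting-state subject with known microstate structure and
# persist it in every supported format, plus its ground-truth sidecars.
# A demonstration-scale recording (16 channels, 500 Hz, 60 s) keeps the
# artifacts small; the acceptance study runs the full 64-channel,
# 5,000 Hz, 180 s conditions.

suppressPackageStartupMessages(library(microstatr))
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_channels = 16, fs = 500, duration = 60, seed = 1)
sim <- simulate_subject(cfg)
cat(sprintf("simulated %d channels x %d samples at %g Hz (%d true runs)\n",
            nrow(sim$recording$data), ncol(sim$recording$data), cfg$fs,
            length(rle(sim$truth$labels)$lengths)))

write_container(sim$recording, file.path(out, "subject01"))
write_edf(sim$recording, file.path(out, "subject01.edf"))
write_brainvision(sim$recording, file.path(out, "subject01"))
write_ground_truth(sim$truth, file.path(out, "subject01"))

# verify the EDF round trip stays within its quantization bound
back <- read_edf(file.path(out, "subject01.edf"))
err <- max(abs(back$data - sim$recording$data[, seq_len(ncol(back$data))]))
cat(sprintf("EDF round-trip max abs error: %.4g uV\n", err))
cat("wrote container, EDF, BrainVision triad, and truth sidecars to",
    out, "\n")
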