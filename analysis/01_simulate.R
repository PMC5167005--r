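#!/usr/bin/env Rscript
# Simulate the synthetic cohort: 20 subjects, the study protocol (3
# conditions x 15 events, 5 s stimuli, 15 s ISI, 5 min baseline), default
# effect structure (PAPain > PA30 > Brush = 0, scalp component largest for
# painful pressure). Recordings are large and go under scratch/; everything
# downstream reads from there.

library(nirspine)

seed <- 20260928L
study_dir <- "scratch/study"

man <- simulate_study(study_dir, n_subjects = 20, seed = seed)
cat(sprintf("wrote %d subjects to %s (seed %d, package %s)\n",
            man$n_subjects, study_dir, man$seed, man$version))
sub1 <- read_protocol(file.path(study_dir, "S01", "protocol.tsv"))
cat(sprintf("subject S01: %d events, %.0f min session, max run length %d\n",
            nrow(sub1), attr(sub1, "total_s") / 60,
            max(rle(sub1$condition)$lengths)))
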