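#!/usr/bin/env Rscript
# Simulate the study's raw inputs with recorded ground truth:
# a tuned V1-like population imaged on three days (D1, D3, D7) with
# drifting preferred orientations, plus behavioral sessions and
# immunostaining-like images for the downstream stages.
#
# Heavy raw data (trace matrices) go under scratch/; everything later
# stages report is recomputed from them.

suppressMessages(library(tunedrift))

seed <- 20261001
out_dir <- "scratch/sessions"
dir.create("results", showWarnings = FALSE)

pop <- gen_population(150, frac_untuned = 0.1, seed = seed)
design <- trial_design()   # 16 directions, 2 s stim / 4 s ITI, 15 Hz, 10 trials

# Per-step drift of 7 degrees SD emulates the reported stability range
# (a majority of cells under 10 degrees change between sessions).
sessions <- gen_drifted_sessions(pop, design, drift_sd = 7, n_sessions = 3,
                                 noise_sd = 0.05, a_true = 0.7, seed = seed)
names(sessions) <- c("D1", "D3", "D7")
for (day in names(sessions))
  write_session(sessions[[day]], file.path(out_dir, day))

write.csv(pop, "results/population_truth.csv", row.names = FALSE)
cat(sprintf("simulated %d cells x %d frames on %s (drift_sd = 7 deg/step)\n",
            nrow(pop), ncol(sessions[[1]]$traces),
            paste(names(sessions), collapse = ", ")))
cat(sprintf("untuned fraction: %.2f; sessions under %s\n",
            mean(!pop$tuned_truth), out_dir))
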