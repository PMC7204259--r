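#!/usr/bin/env Rscript
# Simulate one full synthetic recording session (all eight task conditions)
# and write it to results/session/ as self-describing text streams.
suppressPackageStartupMessages(library(synergydecode))

seed <- 1L
gt <- make_ground_truth(seed = seed, snr_db = 20)
protocol <- default_protocol(n_trials = 3, n_reps = 3)
session <- generate_session(gt, protocol, seed = seed + 1L, keep_truth = FALSE)

dir.create("results", showWarnings = FALSE)
write_session(session, "results/session")
write_synergy_set("results/session/generator_synergies.tsv",
                  synergy_set(gt$S_true,
                              roles = gt$tuning_map$role,
                              channels = forearm_channels()))
print(session)
cat("session written to results/session\n")
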