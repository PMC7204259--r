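#!/usr/bin/env Rscript
# Choose the wrist synergy count: VAF-versus-count table over the wrist
# training trials plus a decoding-performance sweep, both written to results/.
suppressPackageStartupMessages(library(synergydecode))

session <- read_session("results/session")
prep <- preprocess_session(session, zero_phase = TRUE)
conds <- vapply(prep$trials, `[[`, "", "condition")
hc <- hals_config(seed = 1, n_restarts = 5)

train_E <- lapply(prep$trials[conds == "comfortable_max"], `[[`, "E")
sel <- select_synergy_count(train_E, j_range = 1:6, config = hc)
print(sel)
write.table(sel$table, "results/vaf_by_synergy_count.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sweep <- synergy_number_sweep(prep, j_range = 1:6, strategy = "separate",
                              config = hc)
print(sweep)
write.table(sweep, "results/performance_by_synergy_count.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("selected synergy count: %d\n", sel$j))
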