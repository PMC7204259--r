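#!/usr/bin/env Rscript
# Quality checks on the envelope preprocessing: filter response, task-peak
# normalization constants, and per-trial envelope summaries.
suppressPackageStartupMessages(library(synergydecode))

session <- read_session("results/session")

# designed filter response at the frequencies of interest
resp <- envelope_filter_response(c(0, 1, 2, 5, 10, 20, 50, 100),
                                 rate = 2000, cutoff = 5, order = 2)
write.table(resp, "results/filter_response.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

prep <- preprocess_session(session, zero_phase = TRUE)

peaks <- data.frame(channel = names(prep$peaks), task_peak = unname(prep$peaks))
write.table(peaks, "results/task_peaks.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

qc <- do.call(rbind, lapply(seq_along(prep$trials), function(i) {
  tr <- prep$trials[[i]]
  data.frame(trial = i, condition = tr$condition,
             n_samples = nrow(tr$E),
             env_min = min(tr$E), env_max = max(tr$E),
             env_mean = mean(tr$E))
}))
write.table(qc, "results/preprocess_qc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

stopifnot(all(qc$env_min >= 0), all(qc$env_max <= 1 + 1e-9))
print(qc)
cat("filter response, task peaks and envelope QC written to results/\n")
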