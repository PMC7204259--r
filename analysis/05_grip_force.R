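#!/usr/bin/env Rscript
# Grip-force estimation and grip-induced wrist-angle perturbation: how well
# the calibrated grip synergy tracks force, and how strongly maximum-force
# grips disturb the decoded wrist angle relative to quarter-force grips.
suppressPackageStartupMessages(library(synergydecode))

session <- read_session("results/session")
prep <- preprocess_session(session, zero_phase = TRUE)
hc <- hals_config(seed = 1, n_restarts = 10)

rep_ <- exhaustive_cv(prep, strategy = "separate", j_wrist = 4, j_grip = 1,
                      config = hc)
tr <- rep_$trials
grip_like <- c("grip_only", "force_max", "force_half", "force_quarter")
grip <- tr[tr$condition %in% grip_like, ]

by_cond <- do.call(rbind, lapply(split(grip, grip$condition), function(g) {
  data.frame(condition = g$condition[1],
             angle_nrmse_mean = mean(g$nrmse),
             angle_nrmse_sd = sd(g$nrmse),
             force_r_mean = mean(g$force_r, na.rm = TRUE))
}))
print(by_cond)
write.table(by_cond, "results/grip_force_by_condition.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

pert <- compare_models(grip$nrmse[grip$condition == "force_max"],
                       grip$nrmse[grip$condition == "force_quarter"])
cat("\nwrist-angle perturbation, max-force vs quarter-force grips:\n")
print(pert)
write.table(pert, "results/force_perturbation_test.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
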