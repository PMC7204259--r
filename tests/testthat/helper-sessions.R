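# compact session builders shared across tests; small repetition counts keep
# the suite fast while preserving the protocol structure

proto_cv <- function(n_max = 2L, n_reps = 3L, extra = character(0)) {
  c(lapply(seq_len(n_max), function(i) trial_spec("comfortable_max", n_reps = n_reps)),
    list(trial_spec("grip_only", n_reps = n_reps)),
    lapply(extra, trial_spec, n_reps = n_reps))
}

tiny_session <- function(seed = 1L, snr_db = 20, n_max = 2L, n_reps = 2L,
                         extra = character(0), ...) {
  gt <- make_ground_truth(seed = seed, snr_db = snr_db, ...)
  generate_session(gt, proto_cv(n_max, n_reps, extra), seed = seed + 1000L)
}
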