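test_that("HALS factorizes an exact rank-1 matrix and is deterministic", {
  set.seed(1)
  m <- runif(60, 0.1, 1); s <- runif(7, 0.1, 1)
  E <- m %o% s
  fit <- hals_nmf(E, 1, hals_config(seed = 2))
  expect_gte(fit$vaf, 1 - 1e-9)
  fit2 <- hals_nmf(E, 1, hals_config(seed = 2))
  expect_identical(fit$S, fit2$S)
  expect_identical(fit$M, fit2$M)
  expect_error(hals_nmf(E, 0), "j")
  expect_error(hals_nmf(matrix(0, 5, 3), 2), "degenerate")
  expect_error(hals_nmf(-E, 1), "nonnegative")
})

test_that("HALS objective never increases within a run", {
  set.seed(3)
  E <- matrix(runif(50 * 7), 50, 7)
  fit <- hals_nmf(E, 3, hals_config(seed = 4, n_restarts = 3))
  expect_true(all(diff(fit$history) <= 1e-10 * fit$history[-length(fit$history)] + 1e-12))
})

test_that("best-restart VAF is non-decreasing in the synergy count", {
  set.seed(5)
  E <- matrix(runif(80 * 7), 80, 7)
  vafs <- vapply(1:5, function(j) {
    hals_nmf(E, j, hals_config(seed = 6, n_restarts = 10))$vaf
  }, 0)
  expect_true(all(diff(vafs) >= -1e-6))
})

test_that("scaling the data scales activations and leaves unit-norm synergies unchanged", {
  set.seed(8)
  E <- matrix(runif(60 * 7), 60, 7)
  f1 <- hals_nmf(E, 3, hals_config(seed = 9, n_restarts = 2))
  f2 <- hals_nmf(5 * E, 3, hals_config(seed = 9, n_restarts = 2))
  expect_equal(f2$S, f1$S, tolerance = 1e-7)
  expect_equal(f2$M, 5 * f1$M, tolerance = 1e-7)
})

test_that("VAF matches hand-computed values and guards degenerate input", {
  E <- diag(2)
  M <- cbind(c(1, 0))
  S <- cbind(c(1, 0))
  expect_equal(vaf(E, M, S), 0.5)             # residual [[0,0],[0,1]]
  expect_equal(vaf(E, cbind(c(0, 0)), S), 0)  # zero activations
  set.seed(2)
  A <- matrix(runif(12), 4, 3); B <- matrix(runif(9), 3, 3)
  expect_equal(vaf(A %*% t(B), A, B), 1, tolerance = 1e-12)
  expect_error(vaf(matrix(0, 2, 2), M, S), "degenerate")
})

test_that("synergy count selection follows the minimum-VAF-over-datasets rule", {
  expect_identical(select_from_vaf_table(c(`3` = 0.88, `4` = 0.9647)), 4L)
  expect_identical(select_from_vaf_table(c(`1` = 0.95)), 1L)
  err <- tryCatch(select_from_vaf_table(c(`1` = 0.5, `2` = 0.7)),
                  error = function(e) e)
  expect_s3_class(err, "vaf_selection_error")
  expect_named(err$vaf_table, c("1", "2"))
})

test_that("selection on noiseless synthetic data does not exceed the generating count", {
  sess <- tiny_session(seed = 4, snr_db = Inf, n_max = 1, n_reps = 2)
  prep <- preprocess_session(sess, zero_phase = TRUE)
  sel <- select_synergy_count(list(prep$trials[[1]]$E), j_range = 1:6,
                              config = hals_config(seed = 1, n_restarts = 5))
  expect_lte(sel$j, 4L)
  expect_true(all(sel$table$j %in% 1:6))
})

test_that("joint extraction finds and labels the grip synergy", {
  gt <- make_ground_truth(j_wrist = 2, seed = 6, snr_db = Inf)
  sess <- generate_session(gt, list(trial_spec("max_with_grip", n_reps = 2),
                                    trial_spec("grip_only", n_reps = 2)),
                           seed = 13)
  prep <- preprocess_session(sess, zero_phase = TRUE)
  trials <- list(prep$trials[[1]]$E, prep$trials[[2]]$E)
  S <- extract_synergies_joint(trials, j_wrist = 2, j_grip = 1,
                               config = hals_config(seed = 3))
  expect_identical(S$roles, c("wrist", "wrist", "grip"))
  grip_col <- S$S[, 3]
  expect_gte(abs(cosine(grip_col, gt$S_true[, 3])), 0.9)
  # determinism
  S2 <- extract_synergies_joint(trials, 2, 1, hals_config(seed = 3))
  expect_identical(S$S, S2$S)
  # permuting channels permutes synergy rows (up to restart-path differences:
  # the random init is drawn per channel, so convergence is not bit-identical)
  perm <- c(2, 5, 1, 7, 3, 6, 4)
  Sp <- extract_synergies_joint(lapply(trials, function(e) e[, perm]),
                                2, 1, hals_config(seed = 3))
  for (k in 1:3) {
    expect_gte(abs(cosine(Sp$S[, k], S$S[perm, k])), 0.999)
  }
})

test_that("separate extraction recovers generator synergies and keeps grip on the flexors", {
  gt <- make_ground_truth(seed = 7, snr_db = Inf, grip_spillover = 0)
  sess <- generate_session(gt, proto_cv(n_max = 1, n_reps = 2), seed = 14)
  prep <- preprocess_session(sess, zero_phase = TRUE)
  S <- extract_synergies_separate(prep$trials[[1]]$E, prep$trials[[2]]$E,
                                  j_wrist = 4, j_grip = 1,
                                  config = hals_config(seed = 5))
  mm <- match_synergies(S, gt$S_true)
  expect_gte(min(mm$cosines), 0.95)
  # with zero generator spillover the grip column sits on FDS+FDP
  grip_col <- S$S[, S$roles == "grip"]
  expect_gte(sum(grip_col[6:7]^2) / sum(grip_col^2), 0.8)
  expect_error(extract_synergies_separate(prep$trials[[1]]$E,
                                          prep$trials[[2]]$E, 0), "j_wrist")
})

test_that("activation projection solves the frozen-basis nonnegative least squares", {
  set.seed(10)
  S <- matrix(runif(7 * 3, 0.1, 1), 7, 3)
  M0 <- matrix(runif(40 * 3), 40, 3)
  E <- M0 %*% t(S)
  M <- project_activations(E, S)
  expect_equal(unname(M), unname(M0), tolerance = 1e-6)
  expect_equal(unname(project_activations(matrix(0, 10, 7), S)),
               matrix(0, 10, 3), tolerance = 1e-12)
  # optimality spot-check against random nonnegative candidates
  E2 <- matrix(runif(30 * 7), 30, 7)
  Mhat <- project_activations(E2, S)
  obj_hat <- sum((E2 - Mhat %*% t(S))^2)
  for (i in 1:100) {
    cand <- matrix(runif(30 * 3, 0, 2), 30, 3)
    expect_lte(obj_hat, sum((E2 - cand %*% t(S))^2))
  }
  expect_error(project_activations(matrix(1, 5, 4), S), "channel mismatch")
})

test_that("synergy matching finds the permutation that restores generators", {
  set.seed(11)
  S_ref <- matrix(runif(7 * 4, 0.05, 1), 7, 4)
  S_ref <- sweep(S_ref, 2, sqrt(colSums(S_ref^2)), "/")
  perm <- c(3, 1, 4, 2)
  mm <- match_synergies(S_ref[, perm], S_ref)
  expect_identical(as.integer(mm$perm), order(perm))
  expect_equal(mm$cosines, rep(1, 4), tolerance = 1e-12)
})
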