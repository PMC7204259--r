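test_that("pearson_r matches the textbook formula and handles trivial cases", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  expect_equal(pearson_r(x, y), pearson_textbook(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x), -1, tolerance = 1e-12)
  expect_error(pearson_r(x, c(1, 2)), "lengths differ")
  expect_error(pearson_r(1, 2), "at least 2")
  expect_error(pearson_r(x, rep(3, 4)), "constant")
})

test_that("nrmse matches hand values and scales inversely with the normalizer", {
  y <- c(0, 30, -30, 60)
  expect_equal(nrmse(y, y), 0)
  expect_equal(nrmse(y + 9, y), 0.1, tolerance = 1e-12)   # 9 deg / 90 deg
  expect_equal(nrmse(y + 90, y), 1, tolerance = 1e-12)
  expect_equal(nrmse(y + 9, y, a = 45), 0.2, tolerance = 1e-12)
  # matrices pool squared error over both columns
  m <- cbind(y, y)
  expect_equal(nrmse(m + 9, m), 0.1, tolerance = 1e-12)
  expect_equal(nrmse(cbind(y + 18, y), cbind(y, y)),
               sqrt(mean(c(rep(18^2, 4), rep(0, 4)))) / 90, tolerance = 1e-12)
  expect_error(nrmse(y, y[1:2]), "shapes differ")
  expect_error(nrmse(y, y, a = 0), "a")
})

test_that("pearson_r is invariant under positive affine maps of either series", {
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(3 * x + 2, y), r, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.5 * y - 7), r, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y), -r, tolerance = 1e-12)
})

test_that("exhaustive CV enumerates all train pairs and excludes training trials", {
  # 3 wrist-training trials x 3 grip trials -> 9 folds
  sess <- tiny_session(seed = 9, snr_db = 20, n_max = 3, n_reps = 1,
                       extra = c("grip_only", "grip_only"))
  rep_ <- exhaustive_cv(sess, strategy = "separate", j_wrist = 3,
                        config = hals_config(seed = 2, n_restarts = 2),
                        zero_phase = TRUE)
  expect_equal(nrow(rep_$folds), 9L)
  expect_equal(nrow(unique(rep_$folds[, c("train_wrist", "train_grip")])), 9L)
  # no fold evaluates its own training trials
  for (f in seq_len(nrow(rep_$folds))) {
    rows <- rep_$trials[rep_$trials$fold == f, ]
    expect_false(rep_$folds$train_wrist[f] %in% rows$trial)
    expect_false(rep_$folds$train_grip[f] %in% rows$trial)
    expect_equal(nrow(rows), length(sess$trials) - 2L)
  }
  expect_identical(rep_$summary$metric,
                   c("wrist_r", "wrist_nrmse", "grip_angle_nrmse",
                     "grip_force_r"))
  # rerunning is bit-identical
  rep2 <- exhaustive_cv(sess, strategy = "separate", j_wrist = 3,
                        config = hals_config(seed = 2, n_restarts = 2),
                        zero_phase = TRUE)
  expect_identical(rep_$folds, rep2$folds)
})

test_that("exhaustive CV requires enough training material", {
  sess <- tiny_session(seed = 10, n_max = 1, n_reps = 1)
  expect_error(exhaustive_cv(sess, j_wrist = 2), ">= 2 trials")
  gt <- make_ground_truth(seed = 10, snr_db = 20)
  no_grip <- generate_session(
    gt, list(trial_spec("comfortable_max", n_reps = 1),
             trial_spec("comfortable_max", n_reps = 1)), seed = 3)
  expect_error(exhaustive_cv(no_grip, j_wrist = 2), "grip training trial")
})

test_that("the synergy-number sweep covers the requested counts", {
  sess <- tiny_session(seed = 11, snr_db = 20, n_max = 2, n_reps = 1)
  prep <- preprocess_session(sess, zero_phase = TRUE)
  sw <- synergy_number_sweep(prep, j_range = 2:4, strategy = "separate",
                             config = hals_config(seed = 1, n_restarts = 2))
  expect_identical(sw$j, 2:4)
  expect_true(all(is.finite(sw$wrist_r)))
  expect_true(all(sw$wrist_nrmse >= 0))
})

test_that("model comparison reproduces a direct t-test", {
  set.seed(12)
  x <- rnorm(20, 1); y <- rnorm(20, 0)
  cmp <- compare_models(x, y)
  tt <- t.test(x, y)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(cmp$diff, mean(x) - mean(y), tolerance = 1e-12)
  cmp_p <- compare_models(x, y, paired = TRUE)
  expect_equal(cmp_p$p_value, t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)
})
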