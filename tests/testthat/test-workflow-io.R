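test_that("time-series files round-trip data, rate, channels and condition", {
  set.seed(1)
  x <- matrix(runif(40 * 3), 40, 3)
  p <- file.path(tempdir(), "ts_roundtrip.tsv")
  write_timeseries(p, x, rate = 74, channels = c("a", "b", "c"),
                   condition = "comfortable_max")
  got <- read_timeseries(p)
  expect_equal(unname(got$data), unname(x), tolerance = 1e-12)
  expect_identical(got$channels, c("a", "b", "c"))
  expect_equal(got$rate, 74)
  expect_identical(got$condition, "comfortable_max")
  expect_error(write_timeseries(p, x, 74, channels = c("a", "b")),
               "does not match")
  unlink(p)
})

test_that("malformed stream files fail with the offending line identified", {
  p <- file.path(tempdir(), "ts_bad.tsv")
  hdr <- c("# channels: a,b,c", "# rate: 74")
  good <- replicate(14, paste(format(runif(3)), collapse = "\t"))
  writeLines(c(hdr, good, "0.1\t0.2"), p)   # line 17 has 2 fields, not 3
  expect_error(read_timeseries(p), "line 17")
  writeLines(c(hdr, good, "0.1\tpotato\t0.3"), p)
  expect_error(read_timeseries(p), "non-numeric value on line 17")
  writeLines(hdr, p)
  expect_error(read_timeseries(p), "empty data section")
  writeLines(c("# rate: 74", good), p)
  expect_error(read_timeseries(p), "channels")
  expect_error(read_timeseries(file.path(tempdir(), "nope.tsv")),
               "no such file")
  unlink(p)
})

test_that("sessions round-trip through a directory of streams plus manifest", {
  sess <- tiny_session(seed = 2, n_max = 1, n_reps = 1)
  d <- file.path(tempdir(), "sess_roundtrip")
  write_session(sess, d)
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  back <- read_session(d)
  expect_length(back$trials, length(sess$trials))
  for (i in seq_along(sess$trials)) {
    expect_identical(back$trials[[i]]$condition, sess$trials[[i]]$condition)
    expect_equal(unname(back$trials[[i]]$emg),
                 unname(sess$trials[[i]]$emg), tolerance = 1e-10)
    expect_equal(unname(back$trials[[i]]$angles),
                 unname(sess$trials[[i]]$angles), tolerance = 1e-10)
    expect_identical(back$trials[[i]]$channels, sess$trials[[i]]$channels)
  }
  # a manifest that points at a missing file is caught
  unlink(file.path(d, "trial01_emg.tsv"))
  expect_error(read_session(d), "missing file")
  unlink(d, recursive = TRUE)
})

test_that("synergy sets are written as self-describing text", {
  E <- matrix(runif(60 * 7, 0.1, 1), 60, 7,
              dimnames = list(NULL, forearm_channels()))
  fit <- hals_nmf(E, 2, hals_config(seed = 1, n_restarts = 2))
  ss <- synergy_set(fit$S, roles = c("wrist", "wrist"),
                    channels = forearm_channels())
  p <- file.path(tempdir(), "synergies.tsv")
  write_synergy_set(p, ss)
  got <- read_timeseries(p)
  expect_identical(got$channels, forearm_channels())
  expect_equal(unname(got$data), unname(t(ss$S)), tolerance = 1e-10)
  expect_identical(got$meta$roles, "wrist,wrist")
  expect_error(write_synergy_set(p, matrix(1, 7, 2)), "synergy_set")
  unlink(p)
})

test_that("config validation rejects unknown keys and bad values up front", {
  cfg <- default_run_config()
  expect_invisible(validate_run_config(cfg))
  bad <- cfg; bad$frobnicate <- 1
  expect_error(validate_run_config(bad), "unknown config key")
  bad <- cfg; bad$model$typo_key <- 1
  expect_error(validate_run_config(bad), "section 'model'.*typo_key")
  bad <- cfg; bad$model$j_wrist <- 0
  expect_error(validate_run_config(bad), "j_wrist")
  bad <- cfg; bad$model$strategy <- "pooled"
  expect_error(validate_run_config(bad), "strategy")
})

test_that("YAML configs merge over the defaults and are validated", {
  p <- file.path(tempdir(), "run_config.yaml")
  writeLines(c("seed: 7", "model:", "  strategy: joint"), p)
  cfg <- read_run_config(p)
  expect_identical(cfg$seed, 7L)
  expect_identical(cfg$model$strategy, "joint")
  # untouched sections keep their defaults
  expect_identical(cfg$synthetic$n_trials, default_run_config()$synthetic$n_trials)
  writeLines(c("model:", "  j_wrist: 0"), p)
  expect_error(read_run_config(p), "j_wrist")
  unlink(p)
})

test_that("run_all produces the documented artifacts and is reproducible", {
  cfg <- default_run_config()
  cfg$synthetic$n_trials <- 2L
  cfg$synthetic$n_reps <- 1L
  cfg$model$j_wrist <- 2L
  cfg$hals$n_restarts <- 2L
  d1 <- file.path(tempdir(), "run_all_1")
  d2 <- file.path(tempdir(), "run_all_2")
  rep1 <- run_all(cfg, d1, quiet = TRUE)
  rep2 <- run_all(cfg, d2, quiet = TRUE)
  for (f in c("per_trial.tsv", "per_fold.tsv", "summary.tsv",
              "config.yaml", "run.log", "session/manifest.yaml")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  # the producing config's hash is embedded in every table
  hash <- config_hash(cfg)
  expect_identical(readLines(file.path(d1, "per_fold.tsv"), n = 1),
                   sprintf("# config_md5: %s", hash))
  expect_identical(readLines(file.path(d1, "summary.tsv")),
                   readLines(file.path(d2, "summary.tsv")))
  expect_identical(rep1$folds, rep2$folds)
  expect_s3_class(rep1, "performance_report")
  # a bad config fails before any artifact is produced
  bad <- cfg; bad$model$j_wrist <- 0
  expect_error(run_all(bad, file.path(tempdir(), "run_all_bad"), quiet = TRUE),
               "j_wrist")
  expect_false(dir.exists(file.path(tempdir(), "run_all_bad")))
  unlink(c(d1, d2), recursive = TRUE)
})
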