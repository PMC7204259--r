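#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between an estimate and a reference series,
#' with explicit guards: both series must have length >= 2 and be
#' non-constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("series lengths differ")
  if (length(x) < 2L) stopf("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("undefined correlation: constant series")
  }
  stats::cor(x, y)
}

#' Normalized root-mean-square error
#'
#' RMSE between estimate and reference divided by a normalization range `a`
#' (default 90 degrees, the wrist angle range limit). Matrix inputs pool the
#' squared errors over all entries (both angle dimensions).
#'
#' @param x Estimate (vector or matrix).
#' @param y Reference, same shape.
#' @param a Positive normalizer (default 90).
#' @return Nonnegative scalar.
#' @export
nrmse <- function(x, y, a = 90) {
  assert_scalar_pos(a, "a")
  x <- as_matrix(x); y <- as_matrix(y)
  if (!all(dim(x) == dim(y))) stopf("estimate and reference shapes differ")
  sqrt(mean((x - y)^2)) / a
}

# metrics for one held-out trial given a fitted decoder
evaluate_trial <- function(trial, model, a = 90) {
  M <- project_activations(trial$E, model$synergies)
  ang_hat <- predict_angles(M, model)
  is_grip_only <- trial$condition %in%
    c("grip_only", "force_max", "force_half", "force_quarter")
  r_x <- r_y <- NA_real_
  if (!is_grip_only) {
    r_x <- pearson_r(ang_hat[, 1L], trial$angles[, 1L])
    r_y <- pearson_r(ang_hat[, 2L], trial$angles[, 2L])
  }
  ref <- if (is_grip_only) matrix(0, nrow(ang_hat), 2L) else trial$angles
  err <- nrmse(ang_hat, ref, a)
  force_r <- NA_real_
  if (!is.null(trial$force) && !is.na(model$grip_col) &&
      stats::sd(trial$force) > 1e-9) {
    force_r <- pearson_r(estimate_grip_force(M, model), trial$force)
  }
  data.frame(condition = trial$condition, r_x = r_x, r_y = r_y,
             r_mean = mean(c(r_x, r_y)), nrmse = err, force_r = force_r)
}

#' Exhaustive cross-validation of the synergy decoder
#'
#' For every pair of (wrist training trial, grip training trial) - wrist
#' training trials drawn from the comfortable-maximum condition by default -
#' synergies are extracted with the chosen strategy, the decoder is fitted,
#' and every other trial is evaluated: wrist-movement trials report Pearson r
#' per angle dimension and pooled nRMSE against the reference angles;
#' grip-only and force trials report nRMSE of the angle estimate against the
#' zero-angle reference (any excursion is a perturbation) plus the
#' grip-force correlation. Fold metrics are aggregated as mean and SD.
#'
#' @param session An `emg_session` (raw; preprocessed internally) or a
#'   `prepped_session` from [preprocess_session()].
#' @param strategy `"separate"` (wrist and grip synergies from their own
#'   trials) or `"joint"` (one factorization of the pooled trials).
#' @param j_wrist,j_grip Synergy counts (defaults 4 and 1).
#' @param config A [hals_config()].
#' @param train_condition Condition supplying wrist training trials.
#' @param grip_condition Condition supplying grip training trials.
#' @param include_grip_regressor Passed to [fit_decoder()].
#' @param a nRMSE normalizer, degrees (default 90).
#' @param ... Passed to [preprocess_session()] when `session` is raw.
#' @return A `performance_report`: `trials` (per fold x test trial metrics),
#'   `folds` (per-fold means), `summary` (mean and SD across folds),
#'   `strategy`, `j_wrist`.
#' @export
exhaustive_cv <- function(session, strategy = c("separate", "joint"),
                          j_wrist = 4L, j_grip = 1L,
                          config = hals_config(),
                          train_condition = "comfortable_max",
                          grip_condition = "grip_only",
                          include_grip_regressor = TRUE, a = 90, ...) {
  strategy <- match.arg(strategy)
  prep <- if (inherits(session, "prepped_session")) session
          else preprocess_session(session, ...)
  conds <- vapply(prep$trials, `[[`, "", "condition")
  wrist_train <- which(conds == train_condition)
  grip_train <- which(conds == grip_condition)
  if (length(wrist_train) < 2L) {
    stopf("need >= 2 trials of the training condition '%s' (found %d)",
          train_condition, length(wrist_train))
  }
  if (length(grip_train) < 1L) {
    stopf("need >= 1 grip training trial of condition '%s'", grip_condition)
  }
  trial_rows <- list()
  fold_rows <- list()
  fold <- 0L
  for (w in wrist_train) for (g in grip_train) {
    fold <- fold + 1L
    S <- switch(strategy,
      joint = extract_synergies_joint(
        list(prep$trials[[w]]$E, prep$trials[[g]]$E),
        j_wrist = j_wrist, j_grip = j_grip, config = config),
      separate = extract_synergies_separate(
        prep$trials[[w]]$E, prep$trials[[g]]$E,
        j_wrist = j_wrist, j_grip = j_grip, config = config))
    model <- fit_decoder(S, prep$trials[[w]], prep$trials[[g]],
                         include_grip_regressor = include_grip_regressor)
    test_idx <- setdiff(seq_along(prep$trials), c(w, g))
    res <- do.call(rbind, lapply(test_idx, function(i) {
      cbind(fold = fold, trial = i,
            evaluate_trial(prep$trials[[i]], model, a = a))
    }))
    trial_rows[[fold]] <- res
    grip_like <- res$condition %in%
      c("grip_only", "force_max", "force_half", "force_quarter")
    fold_rows[[fold]] <- data.frame(
      fold = fold, train_wrist = w, train_grip = g,
      wrist_r = mean(res$r_mean[!grip_like], na.rm = TRUE),
      wrist_nrmse = mean(res$nrmse[!grip_like]),
      grip_angle_nrmse = if (any(grip_like)) mean(res$nrmse[grip_like])
                         else NA_real_,
      grip_force_r = mean(res$force_r, na.rm = TRUE))
  }
  folds <- do.call(rbind, fold_rows)
  metrics <- c("wrist_r", "wrist_nrmse", "grip_angle_nrmse", "grip_force_r")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(trials = do.call(rbind, trial_rows), folds = folds,
                 summary = summ, strategy = strategy,
                 j_wrist = j_wrist, j_grip = j_grip),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("decoder performance (%s extraction, %d wrist + %d grip synergies, %d folds)\n",
              x$strategy, x$j_wrist, x$j_grip, nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %6.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Decoder performance as a function of wrist synergy count
#'
#' Runs [exhaustive_cv()] at each candidate count and tabulates the
#' aggregate metrics, exposing the characteristic rise-then-degrade of
#' estimation performance as extra (noise-fitting) synergies are added.
#'
#' @inheritParams exhaustive_cv
#' @param j_range Wrist synergy counts to evaluate (default 1:6).
#' @return Data frame with one row per count: mean/SD of wrist r, wrist
#'   nRMSE, grip-trial angle nRMSE.
#' @export
synergy_number_sweep <- function(session, j_range = 1:6,
                                 strategy = c("separate", "joint"),
                                 config = hals_config(), ...) {
  strategy <- match.arg(strategy)
  prep <- if (inherits(session, "prepped_session")) session
          else preprocess_session(session, ...)
  rows <- lapply(j_range, function(j) {
    rep_ <- exhaustive_cv(prep, strategy = strategy, j_wrist = j,
                          config = config, ...)
    s <- rep_$summary
    data.frame(j = j,
               wrist_r = s$mean[s$metric == "wrist_r"],
               wrist_r_sd = s$sd[s$metric == "wrist_r"],
               wrist_nrmse = s$mean[s$metric == "wrist_nrmse"],
               grip_angle_nrmse = s$mean[s$metric == "grip_angle_nrmse"])
  })
  do.call(rbind, rows)
}

#' Two-sample comparison of model performance
#'
#' Thin wrapper over Student's t-test for comparing per-fold (or per-trial)
#' metric samples of two models. No multiple-testing adjustment is applied.
#'
#' @param x,y Numeric metric samples.
#' @param paired Paired test (default FALSE).
#' @return Data frame with the difference of means, t statistic, df and
#'   p value.
#' @export
compare_models <- function(x, y, paired = FALSE) {
  tt <- stats::t.test(x, y, paired = paired)
  data.frame(mean_x = mean(x), mean_y = mean(y),
             diff = mean(x) - mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
}
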