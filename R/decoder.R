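#' Fit the linear regression from activations to angle coordinates
#'
#' Ordinary least squares per target dimension: each normalized sum/diff
#' coordinate is modeled as a bias plus a linear combination of the synergy
#' activations. Rank-deficient designs produce a warning and the
#' minimum-norm solution.
#'
#' @param M_train Activation matrix (time x j).
#' @param targets Time x 2 matrix of normalized sum/difference coordinates
#'   (columns u, v), or any time x d target matrix.
#' @return List of class `regression_model`: `a0` (per-dimension bias), `A`
#'   (j x d coefficient matrix), `residual_scale` (per-dimension residual
#'   RMS), `j`.
#' @export
fit_regression <- function(M_train, targets) {
  M_train <- as_matrix(M_train)
  targets <- as_matrix(targets)
  if (nrow(M_train) != nrow(targets)) stopf("time lengths differ")
  j <- ncol(M_train)
  if (nrow(M_train) < j + 1L) stopf("need at least j + 1 samples to fit")
  X <- cbind(`(bias)` = 1, M_train)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warnf("rank-deficient regression design (rank %d of %d); using the minimum-norm solution",
          qx$rank, ncol(X))
    coefs <- MASS::ginv(X) %*% targets
  } else {
    coefs <- qr.coef(qx, targets)
  }
  coefs <- as_matrix(coefs)
  resid <- targets - X %*% coefs
  structure(list(
    a0 = coefs[1L, ],
    A = coefs[-1L, , drop = FALSE],
    residual_scale = sqrt(colMeans(resid^2)),
    j = j
  ), class = "regression_model")
}

#' Fit the full decoder from a synergy set and training trials
#'
#' Projects the training envelopes onto the (frozen) synergy basis and fits
#' the angle regression in normalized sum/difference coordinates on the
#' combination of the two training trials: the wrist-movement trial with its
#' measured angles, and the grip trial with a zero-angle reference (the hand
#' is stationary while gripping). Including the grip trial is what
#' identifies the grip synergy's angle coefficient - on a wrist-only trial
#' the grip activation is near zero and its coefficient would be
#' unconstrained. The grip-force gain is calibrated so the grip synergy's
#' peak activation on the grip training trial maps to normalized maximum
#' force 1. Angle-normalization constants are estimated on the wrist
#' training trial only and frozen.
#'
#' @param S A `synergy_set`.
#' @param wrist_train List with `E` (envelope) and `angles` (time x 2,
#'   degrees) for the wrist training trial.
#' @param grip_train List with `E` for the grip training trial (used for
#'   gain calibration); optional if the set has no grip synergy.
#' @param include_grip_regressor Use the grip synergy activation as an angle
#'   regressor too (default TRUE; the regression sums over all activations).
#' @return List of class `decoder_model`: the `regression_model` fields plus
#'   `norm_constants`, `grip_gain`, `grip_col`, `include_grip_regressor`,
#'   and the synergy set.
#' @export
fit_decoder <- function(S, wrist_train, grip_train = NULL,
                        include_grip_regressor = TRUE) {
  if (!inherits(S, "synergy_set")) stopf("`S` must be a synergy_set")
  nrm <- fit_normalization(wrist_train$angles)
  targets <- to_sum_diff(wrist_train$angles, nrm[["max_x"]], nrm[["max_y"]])
  M_w <- project_activations(wrist_train$E, S)
  wrist_cols <- which(S$roles == "wrist")
  grip_cols <- which(S$roles == "grip")
  reg_cols <- if (include_grip_regressor) seq_len(ncol(S$S)) else wrist_cols
  M_fit <- M_w
  targets_fit <- targets
  grip_gain <- NA_real_
  grip_col <- if (length(grip_cols)) grip_cols[1L] else NA_integer_
  if (!is.na(grip_col)) {
    if (is.null(grip_train)) stopf("grip training trial required to calibrate the grip gain")
    M_g <- project_activations(grip_train$E, S)
    peak <- max(M_g[, grip_col])
    if (peak <= 0) stopf("calibration error: zero grip activation on the training grip trial")
    grip_gain <- 1 / peak
    if (include_grip_regressor) {
      # grip trial enters the regression with a zero-angle reference
      M_fit <- rbind(M_w, M_g)
      targets_fit <- rbind(targets, matrix(0, nrow(M_g), 2L))
    }
  }
  reg <- fit_regression(M_fit[, reg_cols, drop = FALSE], targets_fit)
  structure(list(
    a0 = reg$a0, A = reg$A, residual_scale = reg$residual_scale,
    reg_cols = reg_cols,
    norm_constants = nrm,
    grip_gain = grip_gain, grip_col = grip_col,
    include_grip_regressor = include_grip_regressor,
    synergies = S
  ), class = "decoder_model")
}

#' Predict wrist angles from synergy activations
#'
#' Applies the fitted affine map to get normalized sum/difference
#' coordinates, then inverts the transform to angles in degrees.
#'
#' @param M_new Activation matrix (time x j of the model's synergy set).
#' @param model A `decoder_model`.
#' @return Time x 2 angle matrix (columns x, y), degrees.
#' @export
predict_angles <- function(M_new, model) {
  if (!inherits(model, "decoder_model")) stopf("`model` must be a decoder_model")
  M_new <- as_matrix(M_new)
  if (ncol(M_new) != ncol(model$synergies$S)) {
    stopf("activation has %d synergies but the model expects %d",
          ncol(M_new), ncol(model$synergies$S))
  }
  X <- M_new[, model$reg_cols, drop = FALSE]
  sd_hat <- sweep(X %*% model$A, 2L, model$a0, "+")
  from_sum_diff(sd_hat, model$norm_constants[["max_x"]],
                model$norm_constants[["max_y"]])
}

#' Estimate normalized grip force from the grip synergy activation
#'
#' The grip synergy's activation, scaled by the calibration gain, is the
#' force estimate directly - no further regression. The gain maps the peak
#' activation of the training grip trial to normalized maximum force 1.
#'
#' @param M_new Activation matrix (time x j of the model's synergy set).
#' @param model A `decoder_model` with a calibrated grip synergy.
#' @return Numeric vector of normalized grip force.
#' @export
estimate_grip_force <- function(M_new, model) {
  if (!inherits(model, "decoder_model")) stopf("`model` must be a decoder_model")
  if (is.na(model$grip_col) || is.na(model$grip_gain)) {
    stopf("model has no calibrated grip synergy")
  }
  M_new <- as_matrix(M_new)
  M_new[, model$grip_col] * model$grip_gain
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("synergy decoder: %d regressors (+bias), norm (%.1f, %.1f) deg, grip gain %s\n",
              length(x$reg_cols), x$norm_constants[["max_x"]],
              x$norm_constants[["max_y"]],
              if (is.na(x$grip_gain)) "none" else sprintf("%.3f", x$grip_gain)))
  invisible(x)
}
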