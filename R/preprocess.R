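#' Full-wave rectification
#'
#' Elementwise absolute value of a raw EMG matrix.
#'
#' @param x Numeric matrix or vector (time x channel).
#' @return Matrix of the same shape.
#' @export
rectify <- function(x) {
  x <- as_matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stopf("non-finite values in EMG input")
  abs(x)
}

#' Butterworth low-pass envelope ("quasi-tension")
#'
#' Per-channel low-pass filtering of rectified EMG with a second-order
#' Butterworth filter (default cutoff 5 Hz). The smoothed envelope of
#' rectified EMG correlates with muscle tension, hence "quasi-tension".
#' Filtering is causal by default (single pass, suitable for on-line
#' control); `zero_phase = TRUE` applies forward-backward filtering for
#' offline analysis. Small negative undershoot after filtering is clipped to
#' zero so envelopes stay nonnegative.
#'
#' @param x Rectified EMG, time x channel matrix.
#' @param rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (default 5). Must be below Nyquist.
#' @param order Filter order (default 2).
#' @param zero_phase Use forward-backward filtering (default FALSE).
#' @return Nonnegative envelope matrix of the same shape.
#' @export
lowpass_envelope <- function(x, rate, cutoff = 5, order = 2L,
                             zero_phase = FALSE) {
  x <- as_matrix(x)
  rate <- assert_scalar_pos(rate, "rate")
  cutoff <- assert_scalar_pos(cutoff, "cutoff")
  order <- assert_count(order, "order")
  if (cutoff >= rate / 2) {
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, rate / 2)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  out <- apply(x, 2L, function(col) {
    if (zero_phase) signal::filtfilt(bf, col)
    else as.numeric(signal::filter(bf, col))
  })
  out <- pmax(as_matrix(out), 0)
  dimnames(out) <- dimnames(x)
  out
}

#' Complex frequency response of the designed envelope filter
#'
#' Evaluates the digital filter's transfer function at given frequencies
#' (analytically, from the designed coefficients).
#'
#' @param freq Frequencies, Hz.
#' @param rate Sampling rate, Hz.
#' @inheritParams lowpass_envelope
#' @return Data frame with `freq`, complex `h` and `gain_db`.
#' @export
envelope_filter_response <- function(freq, rate, cutoff = 5, order = 2L) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  z <- exp(-1i * 2 * pi * freq / rate)
  h <- vapply(z, function(zi) {
    num <- sum(bf$b * zi^(seq_along(bf$b) - 1L))
    den <- sum(bf$a * zi^(seq_along(bf$a) - 1L))
    num / den
  }, complex(1))
  data.frame(freq = freq, h = h, gain_db = 20 * log10(Mod(h)))
}

#' Normalize envelopes by the task peak
#'
#' Divides each channel by its maximum over all provided trials ("whole
#' task" scope), removing day-to-day electrode-gain differences. Returned
#' peaks can be re-applied to later data with [apply_task_peaks()].
#'
#' @param envelopes List of nonnegative envelope matrices with identical
#'   channel sets (columns).
#' @return List with `envelopes` (normalized, same order) and `peaks`
#'   (named per-channel maxima).
#' @export
normalize_by_task_peak <- function(envelopes) {
  if (!length(envelopes)) stopf("empty envelope list")
  envelopes <- lapply(envelopes, as_matrix)
  nch <- ncol(envelopes[[1L]])
  if (any(vapply(envelopes, ncol, 0L) != nch)) {
    stopf("inconsistent channel counts across trials")
  }
  peaks <- apply(do.call(rbind, lapply(envelopes, function(e) {
    apply(e, 2L, max)
  })), 2L, max)
  labels <- colnames(envelopes[[1L]])
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nch))
  names(peaks) <- labels
  if (any(peaks <= 0)) {
    stopf("degenerate channel(s) with zero peak: %s",
          paste(labels[peaks <= 0], collapse = ", "))
  }
  list(envelopes = lapply(envelopes, apply_task_peaks, peaks = peaks),
       peaks = peaks)
}

#' Apply stored task-peak normalization
#'
#' @param e Envelope matrix.
#' @param peaks Per-channel peaks from [normalize_by_task_peak()].
#' @return Normalized envelope.
#' @export
apply_task_peaks <- function(e, peaks) {
  e <- as_matrix(e)
  if (ncol(e) != length(peaks)) stopf("channel count does not match peaks")
  sweep(e, 2L, peaks, "/")
}

#' Resample a series by linear interpolation
#'
#' Interpolates onto a uniform grid spanning the original duration; the first
#' and last samples are preserved.
#'
#' @param x Numeric vector or time x channel matrix.
#' @param from_rate,to_rate Sampling rates, Hz.
#' @return Resampled vector or matrix.
#' @export
resample_series <- function(x, from_rate, to_rate) {
  from_rate <- assert_scalar_pos(from_rate, "from_rate")
  to_rate <- assert_scalar_pos(to_rate, "to_rate")
  vec <- !is.matrix(x)
  x <- as_matrix(x)
  n <- nrow(x)
  if (n < 2L) stopf("series must have at least 2 samples")
  if (from_rate == to_rate) return(if (vec) x[, 1L] else x)
  dur <- (n - 1L) / from_rate
  t_from <- (seq_len(n) - 1L) / from_rate
  n_to <- round(dur * to_rate) + 1L
  t_to <- seq(0, dur, length.out = n_to)
  out <- apply(x, 2L, function(col) {
    stats::approx(t_from, col, xout = t_to)$y
  })
  out <- as_matrix(out)
  dimnames(out) <- list(NULL, colnames(x))
  if (vec) out[, 1L] else out
}

#' Preprocess a session into aligned, normalized envelopes
#'
#' Rectifies and low-pass filters every trial's EMG, normalizes each channel
#' by its peak over the whole session, and resamples EMG, angle and force
#' streams onto a common analysis rate (default 74 Hz, the slowest stream).
#'
#' @param session An `emg_session` from [generate_session()] or
#'   [read_session()].
#' @param cutoff,order,zero_phase Envelope filter settings, see
#'   [lowpass_envelope()].
#' @param rate Common analysis rate, Hz.
#' @return A `prepped_session`: list with `trials` (each with nonnegative
#'   `E`, `angles`, `force` at `rate`, plus `condition`), `peaks`, `rate` and
#'   the filter settings used.
#' @export
preprocess_session <- function(session, cutoff = 5, order = 2L,
                               zero_phase = FALSE, rate = 74) {
  if (!length(session$trials)) stopf("session has no trials")
  envs <- lapply(session$trials, function(tr) {
    lowpass_envelope(rectify(tr$emg), tr$emg_rate, cutoff = cutoff,
                     order = order, zero_phase = zero_phase)
  })
  norm <- normalize_by_task_peak(envs)
  trials <- vector("list", length(session$trials))
  for (i in seq_along(trials)) {
    tr <- session$trials[[i]]
    E <- resample_series(norm$envelopes[[i]], tr$emg_rate, rate)
    ang <- resample_series(tr$angles, tr$angle_rate, rate)
    frc <- if (!is.null(tr$force)) {
      resample_series(tr$force, tr$force_rate, rate)
    }
    nt <- min(nrow(E), nrow(ang), if (is.null(frc)) Inf else length(frc))
    trials[[i]] <- list(condition = tr$condition,
                        E = E[seq_len(nt), , drop = FALSE],
                        angles = ang[seq_len(nt), , drop = FALSE],
                        force = if (!is.null(frc)) frc[seq_len(nt)],
                        rate = rate)
  }
  structure(list(trials = trials, peaks = norm$peaks, rate = rate,
                 filter = list(cutoff = cutoff, order = order,
                               zero_phase = zero_phase)),
            class = "prepped_session")
}

#' @export
print.prepped_session <- function(x, ...) {
  cat(sprintf("preprocessed session: %d trials at %g Hz (%s %d-order %g Hz low-pass)\n",
              length(x$trials), x$rate,
              if (x$filter$zero_phase) "zero-phase" else "causal",
              x$filter$order, x$filter$cutoff))
  invisible(x)
}
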