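#' Construct a labeled synergy set
#'
#' @param S Channel x synergy nonnegative matrix with unit-norm columns.
#' @param roles Character vector, one of "wrist"/"grip" per column.
#' @param channels Channel labels (defaults to rownames of `S`).
#' @return A `synergy_set`.
#' @export
synergy_set <- function(S, roles, channels = rownames(S)) {
  S <- as_matrix(S)
  if (length(roles) != ncol(S)) stopf("one role per synergy column required")
  if (!all(roles %in% c("wrist", "grip"))) {
    stopf("roles must be 'wrist' or 'grip'")
  }
  if (any(S < 0)) stopf("synergy loadings must be nonnegative")
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(nrow(S)))
  rownames(S) <- channels
  structure(list(S = S, roles = roles, channels = channels),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("synergy set: %d channels, %d wrist + %d grip synergies\n",
              nrow(x$S), sum(x$roles == "wrist"), sum(x$roles == "grip")))
  tagged <- x$S
  colnames(tagged) <- paste0(colnames(x$S), " (", x$roles, ")")
  print(round(tagged, 3))
  invisible(x)
}

# indices of the grip (finger-flexor) channels in a label vector
grip_channel_idx <- function(channels) {
  idx <- which(channels %in% grip_channel_labels())
  if (!length(idx)) {
    stopf("no grip channels (%s) found among: %s",
          paste(grip_channel_labels(), collapse = "/"),
          paste(channels, collapse = ", "))
  }
  idx
}

# fraction of each column's squared norm carried by the grip channels
grip_loading_ratio <- function(S, channels) {
  gi <- grip_channel_idx(channels)
  colSums(S[gi, , drop = FALSE]^2) / pmax(colSums(S^2), 1e-300)
}

#' Extract synergies jointly from pooled wrist and grip trials
#'
#' Concatenates the provided trials along time and runs a single HALS NMF
#' with `j_wrist + j_grip` components. The `j_grip` columns with the largest
#' loading ratio on the finger-flexor channels (FDS, FDP) are labeled grip
#' synergies; the rest are wrist synergies.
#'
#' @param trials List of nonnegative envelope matrices sharing channel
#'   columns (typically a combined wrist+grip movement trial and a grip
#'   trial).
#' @param j_wrist Number of wrist synergies.
#' @param j_grip Number of grip synergies (default 1).
#' @param config A [hals_config()].
#' @return A `synergy_set` with grip columns placed last.
#' @export
extract_synergies_joint <- function(trials, j_wrist, j_grip = 1L,
                                    config = hals_config()) {
  if (!length(trials)) stopf("empty trial list")
  j_wrist <- assert_count(j_wrist, "j_wrist")
  j_grip <- assert_count(j_grip, "j_grip")
  trials <- lapply(trials, as_matrix)
  nch <- ncol(trials[[1L]])
  if (any(vapply(trials, ncol, 0L) != nch)) {
    stopf("trials have inconsistent channel counts")
  }
  E <- do.call(rbind, trials)
  channels <- colnames(trials[[1L]])
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(nch))
  fit <- hals_nmf(E, j_wrist + j_grip, config)
  ratio <- grip_loading_ratio(fit$S, channels)
  grip_cols <- order(ratio, decreasing = TRUE)[seq_len(j_grip)]
  ord <- c(setdiff(seq_len(j_wrist + j_grip), grip_cols), grip_cols)
  synergy_set(fit$S[, ord, drop = FALSE],
              roles = rep(c("wrist", "grip"), c(j_wrist, j_grip)),
              channels = channels)
}

#' Extract wrist and grip synergies separately per trial type
#'
#' Runs independent HALS NMF on a wrist-movement trial (`j_wrist`
#' components) and on a grip trial (`j_grip` components), then concatenates
#' the labeled columns into one set. Keeping the grip trial separate
#' preserves the multi-muscle coactivation of gripping inside a single grip
#' synergy instead of letting the factorization split it part-wise.
#'
#' @param wrist_trial,grip_trial Nonnegative envelope matrices with the same
#'   channel columns.
#' @inheritParams extract_synergies_joint
#' @return A `synergy_set` (wrist columns first, grip columns last).
#' @export
extract_synergies_separate <- function(wrist_trial, grip_trial, j_wrist,
                                       j_grip = 1L, config = hals_config()) {
  j_wrist <- assert_count(j_wrist, "j_wrist")
  j_grip <- assert_count(j_grip, "j_grip")
  wrist_trial <- as_matrix(wrist_trial)
  grip_trial <- as_matrix(grip_trial)
  if (ncol(wrist_trial) != ncol(grip_trial)) {
    stopf("wrist and grip trials have different channel counts")
  }
  channels <- colnames(wrist_trial)
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(ncol(wrist_trial)))
  fit_w <- hals_nmf(wrist_trial, j_wrist, config)
  fit_g <- hals_nmf(grip_trial, j_grip, config)
  synergy_set(cbind(fit_w$S, fit_g$S),
              roles = rep(c("wrist", "grip"), c(j_wrist, j_grip)),
              channels = channels)
}

#' Pick the synergy count from a minimum-VAF table
#'
#' The smallest synergy count whose minimum VAF over all datasets (subjects
#' or trials) reaches the threshold, so the chosen count is adequate for
#' every dataset, not just on average.
#'
#' @param min_vaf Named numeric vector: minimum VAF per synergy count, names
#'   are the counts.
#' @param threshold VAF threshold (default 0.9).
#' @return Integer synergy count.
#' @export
select_from_vaf_table <- function(min_vaf, threshold = 0.9) {
  if (!length(min_vaf)) stopf("empty VAF table")
  js <- as.integer(names(min_vaf))
  if (anyNA(js)) stopf("`min_vaf` must be named by synergy count")
  ord <- order(js)
  js <- js[ord]; min_vaf <- min_vaf[ord]
  ok <- which(min_vaf >= threshold)
  if (!length(ok)) {
    cond <- structure(class = c("vaf_selection_error", "error", "condition"),
                      list(message = sprintf(
                        "no synergy count reaches VAF >= %g (best %.4f at j = %d)",
                        threshold, max(min_vaf), js[which.max(min_vaf)]),
                        call = NULL, vaf_table = stats::setNames(min_vaf, js)))
    stop(cond)
  }
  js[ok[1L]]
}

#' Select the wrist synergy count by VAF
#'
#' Fits HALS NMF at every candidate count on every dataset and returns the
#' smallest count whose minimum VAF across datasets reaches the threshold
#' (default 0.9), together with the full VAF-versus-count table.
#'
#' @param datasets List of nonnegative envelope matrices (e.g. one wrist
#'   trial per subject).
#' @param j_range Candidate synergy counts (default 1:6).
#' @param threshold Minimum acceptable VAF (default 0.9).
#' @param config A [hals_config()].
#' @return List of class `synergy_selection`: `j` (chosen count), `table`
#'   (data frame of dataset, j, vaf), `min_vaf` (named vector), `threshold`.
#' @export
select_synergy_count <- function(datasets, j_range = 1:6, threshold = 0.9,
                                 config = hals_config()) {
  if (!length(datasets)) stopf("empty dataset list")
  rows <- list()
  for (d in seq_along(datasets)) {
    E <- as_matrix(datasets[[d]])
    for (j in j_range) {
      fit <- hals_nmf(E, j, config)
      rows[[length(rows) + 1L]] <- data.frame(dataset = d, j = j,
                                              vaf = fit$vaf)
    }
  }
  tab <- do.call(rbind, rows)
  min_vaf <- tapply(tab$vaf, tab$j, min)
  j_sel <- select_from_vaf_table(min_vaf, threshold)
  structure(list(j = j_sel, table = tab,
                 min_vaf = stats::setNames(as.numeric(min_vaf),
                                           names(min_vaf)),
                 threshold = threshold),
            class = "synergy_selection")
}

#' @export
print.synergy_selection <- function(x, ...) {
  cat(sprintf("selected %d wrist synergies (min VAF >= %g)\n", x$j,
              x$threshold))
  print(round(x$min_vaf, 4))
  invisible(x)
}
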