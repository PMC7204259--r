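#' Write a time series to delimited text with a commented header
#'
#' Plain tab-separated values preceded by `#`-prefixed header lines carrying
#' the channel names, sampling rate and optional condition label, so every
#' stream file is self-describing and inspectable.
#'
#' @param path Output file path.
#' @param data Numeric vector or time x channel matrix.
#' @param rate Sampling rate, Hz.
#' @param channels Channel names (default: column names or ch1..chN).
#' @param condition Optional condition label.
#' @param extra Optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(path, data, rate, channels = NULL,
                             condition = NULL, extra = NULL) {
  data <- as_matrix(data)
  if (is.null(channels)) channels <- colnames(data)
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(ncol(data)))
  if (length(channels) != ncol(data)) {
    stopf("channel label count (%d) does not match columns (%d)",
          length(channels), ncol(data))
  }
  hdr <- c(sprintf("# channels: %s", paste(channels, collapse = ",")),
           sprintf("# rate: %s", format(rate, digits = 15)))
  if (!is.null(condition)) hdr <- c(hdr, sprintf("# condition: %s", condition))
  if (!is.null(extra)) {
    hdr <- c(hdr, sprintf("# %s: %s", names(extra), extra))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' @param path File path.
#' @return List with `data` (time x channel matrix, channel names as column
#'   names), `rate`, `channels`, `condition` (or NA) and any extra header
#'   fields under `meta`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- match(FALSE, is_hdr, nomatch = length(lines) + 1L) - 1L
  hdr <- lines[seq_len(n_hdr)]
  body <- lines[-seq_len(n_hdr)]
  body <- body[nzchar(trimws(body))]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  for (req in c("channels", "rate")) {
    if (is.null(meta[[req]])) {
      stopf("format error in %s: missing '%s' header field", path, req)
    }
  }
  channels <- strsplit(meta$channels, ",", fixed = TRUE)[[1L]]
  rate <- as.numeric(meta$rate)
  if (is.na(rate) || rate <= 0) stopf("format error in %s: bad rate", path)
  if (!length(body)) stopf("format error in %s: empty data section", path)
  rows <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != length(channels))
  if (length(bad)) {
    stopf("format error in %s: line %d has %d fields, expected %d",
          path, n_hdr + bad[1L], nf[bad[1L]], length(channels))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad_row <- which(vapply(rows, function(r) anyNA(suppressWarnings(as.numeric(r))),
                            TRUE))[1L]
    stopf("format error in %s: non-numeric value on line %d",
          path, n_hdr + bad_row)
  }
  data <- matrix(vals, ncol = length(channels), byrow = TRUE,
                 dimnames = list(NULL, channels))
  list(data = data, rate = rate, channels = channels,
       condition = if (is.null(meta$condition)) NA_character_ else meta$condition,
       meta = meta)
}

#' Write a session to a directory of stream files plus a manifest
#'
#' One file per stream per trial (EMG, angles and - where present - force),
#' and a YAML manifest recording conditions, file names, rates and
#' provenance.
#'
#' @param session An `emg_session`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(session$trials))
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    base <- sprintf("trial%02d", i)
    files <- list(emg = paste0(base, "_emg.tsv"),
                  angles = paste0(base, "_angles.tsv"))
    write_timeseries(file.path(dir, files$emg), tr$emg, tr$emg_rate,
                     channels = tr$channels, condition = tr$condition)
    write_timeseries(file.path(dir, files$angles), tr$angles, tr$angle_rate,
                     channels = c("x", "y"), condition = tr$condition)
    if (!is.null(tr$force)) {
      files$force <- paste0(base, "_force.tsv")
      write_timeseries(file.path(dir, files$force), tr$force, tr$force_rate,
                       channels = "force", condition = tr$condition)
    }
    entries[[i]] <- list(condition = tr$condition, files = files,
                         rates = list(emg = tr$emg_rate,
                                      angles = tr$angle_rate,
                                      force = tr$force_rate))
  }
  manifest <- list(
    provenance = if (is.null(session$ground_truth)) "recorded"
                 else "synthetic generator",
    seed = session$seed,
    channels = session$trials[[1L]]$channels,
    trials = entries)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory containing `manifest.yaml`.
#' @return An `emg_session` (without ground truth).
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stopf("no manifest.yaml in %s", dir)
  manifest <- yaml::read_yaml(mf)
  trials <- lapply(manifest$trials, function(en) {
    for (f in unlist(en$files)) {
      if (!file.exists(file.path(dir, f))) {
        stopf("manifest references missing file: %s", f)
      }
    }
    emg <- read_timeseries(file.path(dir, en$files$emg))
    ang <- read_timeseries(file.path(dir, en$files$angles))
    frc <- if (!is.null(en$files$force)) {
      read_timeseries(file.path(dir, en$files$force))
    }
    list(condition = en$condition,
         emg = emg$data, emg_rate = emg$rate,
         angles = ang$data, angle_rate = ang$rate,
         force = if (!is.null(frc)) frc$data[, 1L],
         force_rate = if (!is.null(frc)) frc$rate else en$rates$force,
         channels = emg$channels)
  })
  structure(list(trials = trials, ground_truth = NULL, protocol = NULL,
                 seed = manifest$seed),
            class = "emg_session")
}

#' Write a labeled synergy set as delimited text
#'
#' @param path Output path.
#' @param S A `synergy_set`.
#' @param extra Optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_synergy_set <- function(path, S, extra = NULL) {
  if (!inherits(S, "synergy_set")) stopf("`S` must be a synergy_set")
  # rows = synergies, columns = channels; rate is not meaningful here and
  # is written as 1 to keep the stream format uniform
  write_timeseries(path, t(S$S), rate = 1,
                   channels = S$channels,
                   extra = c(roles = paste(S$roles, collapse = ","), extra))
}
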