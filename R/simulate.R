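#' Construct a ground-truth synergy structure for simulation
#'
#' Builds a nonnegative channel-by-synergy mixing matrix with unit-norm
#' columns, emulating a seven-muscle forearm montage. Wrist synergies are
#' direction-tuned: each has a preferred movement direction in the
#' (flexion-extension, radial-ulnar) plane and loads the muscle group that
#' acts in that direction (extension -> ECR/ECU, flexion -> FCU/FCR,
#' radial -> ECR/FCR/APL, ulnar -> ECU/FCU). Exactly `j_grip` columns are
#' grip synergies loading the finger flexors (FDS, FDP), with an optional
#' small spillover onto the wrist channels that emulates electrode crosstalk
#' from deep finger muscles.
#'
#' @param n_channels Number of EMG channels (default 7, the forearm montage).
#' @param j_wrist Number of wrist synergies (1..4 use the four canonical
#'   directions in order extension, flexion, radial, ulnar; more than 4 adds
#'   randomly tuned wrist synergies).
#' @param j_grip Number of grip synergies (default 1).
#' @param seed Integer seed; identical arguments give identical output.
#' @param grip_spillover Upper bound on each wrist-channel loading of a grip
#'   synergy (pre-normalization). 0 gives a grip column supported only on
#'   FDS/FDP.
#' @param loading_jitter Log-normal sd applied to nonzero template loadings,
#'   so that different seeds give distinct but anatomically consistent
#'   synergies.
#' @param snr_db Envelope signal-to-noise ratio in dB used by
#'   [generate_session()]; `Inf` means noiseless.
#' @param grip_crosstalk Gain of a supra-linear (quadratic) crosstalk from
#'   grip activation into the wrist channels, emulating the extra wrist-
#'   muscle recruitment of forceful grips. 0 (default) disables it; with it
#'   on, strong grips perturb the wrist channels disproportionately more
#'   than light grips, which no linear compensation can fully remove.
#' @return An object of class `ground_truth`: list with `S_true` (channels x
#'   synergies, unit-norm columns), `tuning_map` (data frame of per-synergy
#'   role and preferred direction), `channels`, `snr_db`, `grip_spillover`,
#'   `seed`.
#' @export
make_ground_truth <- function(n_channels = 7L, j_wrist = 4L, j_grip = 1L,
                              seed = 1L, grip_spillover = 0.05,
                              loading_jitter = 0.1, snr_db = 20,
                              grip_crosstalk = 0) {
  n_channels <- assert_count(n_channels, "n_channels")
  j_wrist <- assert_count(j_wrist, "j_wrist")
  j_grip <- assert_count(j_grip, "j_grip")
  if (n_channels != 7L) {
    stopf("only the 7-channel forearm montage is supported (got %d channels)",
          n_channels)
  }
  if (grip_spillover < 0) stopf("`grip_spillover` must be >= 0")
  j <- j_wrist + j_grip
  if (j > n_channels) {
    warnf("%d synergies exceed %d channels; factorization is overcomplete",
          j, n_channels)
  }
  channels <- forearm_channels()
  grip_idx <- match(grip_channel_labels(), channels)
  wrist_idx <- setdiff(seq_len(n_channels), grip_idx)

  # canonical direction templates on (ECR, ECU, FCU, FCR, APL);
  # preferred direction in degrees, extension = 0, radial = 90
  templates <- list(
    extension = list(angle = 0,   w = c(ECR = 0.80, ECU = 0.45, APL = 0.20)),
    flexion   = list(angle = 180, w = c(FCU = 0.80, FCR = 0.55)),
    radial    = list(angle = 90,  w = c(ECR = 0.50, FCR = 0.45, APL = 0.70)),
    ulnar     = list(angle = 270, w = c(ECU = 0.75, FCU = 0.50))
  )

  set.seed(seed)
  S <- matrix(0, n_channels, j, dimnames = list(channels, NULL))
  roles <- character(j)
  dirs <- character(j)
  angles <- numeric(j)
  for (k in seq_len(j_wrist)) {
    if (k <= 4L) {
      tpl <- templates[[k]]
      dirs[k] <- names(templates)[k]
    } else {
      # extra synergies: random preferred direction, random wrist loadings
      tpl <- list(angle = stats::runif(1, 0, 360),
                  w = stats::setNames(stats::runif(5, 0.1, 0.8),
                                      channels[wrist_idx]))
      dirs[k] <- "mixed"
    }
    w <- tpl$w * exp(stats::rnorm(length(tpl$w), 0, loading_jitter))
    S[names(w), k] <- w
    roles[k] <- "wrist"
    angles[k] <- tpl$angle
  }
  for (g in seq_len(j_grip)) {
    k <- j_wrist + g
    w <- c(FDS = 0.75, FDP = 0.66) * exp(stats::rnorm(2, 0, loading_jitter))
    S[names(w), k] <- w
    if (grip_spillover > 0) {
      S[wrist_idx, k] <- stats::runif(length(wrist_idx), 0, grip_spillover)
    }
    roles[k] <- "grip"
    dirs[k] <- "grip"
    angles[k] <- NA_real_
  }
  S <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  colnames(S) <- sprintf("syn%d", seq_len(j))
  # crosstalk pattern on the wrist channels (unit norm), driven by grip^2
  ct <- numeric(n_channels)
  if (grip_crosstalk > 0) {
    ct[wrist_idx] <- stats::runif(length(wrist_idx), 0.2, 1)
    ct <- ct / sqrt(sum(ct^2))
  }
  structure(list(
    S_true = S,
    grip_crosstalk = grip_crosstalk,
    crosstalk_pattern = ct,
    tuning_map = data.frame(synergy = colnames(S), role = roles,
                            direction = dirs, angle_deg = angles),
    channels = channels,
    snr_db = snr_db,
    grip_spillover = grip_spillover,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d channels, %d wrist + %d grip synergies, SNR %s dB\n",
              nrow(x$S_true), sum(x$tuning_map$role == "wrist"),
              sum(x$tuning_map$role == "grip"),
              format(x$snr_db)))
  print(round(x$S_true, 3))
  invisible(x)
}

trial_conditions <- function() {
  c("comfortable_max", "comfortable_half", "stiffened", "max_with_grip",
    "grip_only", "force_max", "force_half", "force_quarter")
}

#' Specify one simulated trial
#'
#' @param condition One of the protocol conditions: three wrist-movement
#'   conditions (`comfortable_max`, `comfortable_half`, `stiffened`), combined
#'   movement with grip (`max_with_grip`), gripping without movement
#'   (`grip_only`, alternating strong and weak grips), and graded isometric
#'   force trials (`force_max`, `force_half`, `force_quarter`).
#' @param n_reps Repetitions per movement direction (or grip pulses per
#'   level), default 3.
#' @param emg_rate,angle_rate,force_rate Sampling rates in Hz for the three
#'   streams (defaults 2000, 74 and 100).
#' @param diagonal_bias Half-width (radians) of the uniform per-repetition
#'   jitter of the executed movement direction, emulating the diagonal drift
#'   of self-paced movements.
#' @param amplitude_deg Full excursion amplitude of a comfortable-maximum
#'   movement, degrees (default 45, half of the 90-degree wrist range).
#' @return A `trial_spec` list.
#' @export
trial_spec <- function(condition, n_reps = 3L, emg_rate = 2000, angle_rate = 74,
                       force_rate = 100, diagonal_bias = 0.3,
                       amplitude_deg = 45) {
  condition <- match.arg(condition, trial_conditions())
  n_reps <- assert_count(n_reps, "n_reps")
  for (r in c(emg_rate = emg_rate, angle_rate = angle_rate,
              force_rate = force_rate)) {
    assert_scalar_pos(r, "sampling rate")
  }
  assert_scalar_pos(amplitude_deg, "amplitude_deg")
  if (diagonal_bias < 0) stopf("`diagonal_bias` must be >= 0")
  structure(list(condition = condition, n_reps = n_reps,
                 emg_rate = emg_rate, angle_rate = angle_rate,
                 force_rate = force_rate, diagonal_bias = diagonal_bias,
                 amplitude_deg = amplitude_deg),
            class = "trial_spec")
}

#' Default session protocol
#'
#' Three trials each of the three movement conditions, combined
#' movement-with-grip, gripping in the centre position, and the three graded
#' force levels: 24 trials in all.
#'
#' @param n_trials Trials per condition (default 3).
#' @param ... Passed on to [trial_spec()].
#' @return List of `trial_spec`.
#' @export
default_protocol <- function(n_trials = 3L, ...) {
  n_trials <- assert_count(n_trials, "n_trials")
  specs <- lapply(trial_conditions(), function(cond) {
    lapply(seq_len(n_trials), function(i) trial_spec(cond, ...))
  })
  unlist(specs, recursive = FALSE)
}

# per-condition generative parameters
condition_params <- function(condition, n_reps) {
  switch(condition,
    comfortable_max  = list(amp = 1.0, tonic = 0,    grip = "none"),
    comfortable_half = list(amp = 0.5, tonic = 0,    grip = "none"),
    stiffened        = list(amp = 1.0, tonic = 0.15, grip = "none"),
    max_with_grip    = list(amp = 1.0, tonic = 0,    grip = "constant",
                            grip_level = 0.5),
    grip_only        = list(amp = 0,   tonic = 0,    grip = "pulses",
                            levels = rep(c(1.0, 0.3), each = n_reps)),
    force_max        = list(amp = 0,   tonic = 0,    grip = "pulses",
                            levels = rep(1.0, n_reps)),
    force_half       = list(amp = 0,   tonic = 0,    grip = "pulses",
                            levels = rep(0.5, n_reps)),
    force_quarter    = list(amp = 0,   tonic = 0,    grip = "pulses",
                            levels = rep(0.25, n_reps))
  )
}

# timing constants (seconds); all multiples of 0.5 s so that sample counts
# are integral at 2000, 100 and 74 Hz
MOVE_LEAD <- 0.5
MOVE_DUR <- 2.0
MOVE_REST <- 0.5
PULSE_DUR <- 2.0   # 0.5 up, 1.0 hold, 0.5 down
PULSE_REST <- 0.5

# deterministic trial schedule: movement segments (onset, duration,
# executed direction, amplitude) and grip profile description
trial_schedule <- function(spec, seed) {
  par <- condition_params(spec$condition, spec$n_reps)
  set.seed(seed)
  moves <- NULL
  if (par$amp > 0) {
    nominal <- c(extension = 0, flexion = pi, radial = pi / 2,
                 ulnar = 3 * pi / 2)
    onset <- MOVE_LEAD
    rows <- list()
    for (d in seq_along(nominal)) {
      for (r in seq_len(spec$n_reps)) {
        jit <- if (spec$diagonal_bias > 0)
          stats::runif(1, -spec$diagonal_bias, spec$diagonal_bias) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          onset = onset, duration = MOVE_DUR,
          angle = nominal[[d]] + jit,
          amplitude = par$amp * spec$amplitude_deg)
        onset <- onset + MOVE_DUR + MOVE_REST
      }
    }
    moves <- do.call(rbind, rows)
    duration <- onset
  } else {
    duration <- MOVE_LEAD
  }
  grip <- NULL
  if (par$grip == "pulses") {
    onset <- MOVE_LEAD
    rows <- list()
    for (lv in par$levels) {
      rows[[length(rows) + 1L]] <- data.frame(onset = onset,
                                              duration = PULSE_DUR,
                                              level = lv)
      onset <- onset + PULSE_DUR + PULSE_REST
    }
    grip <- do.call(rbind, rows)
    duration <- max(duration, onset)
  } else if (par$grip == "constant") {
    grip <- data.frame(onset = MOVE_LEAD, duration = duration - MOVE_LEAD,
                       level = par$grip_level)
  }
  list(duration = duration, moves = moves, grip = grip,
       grip_mode = par$grip, tonic = par$tonic,
       amplitude_deg = spec$amplitude_deg)
}

# raised-cosine out-and-back profile on [0, dur], peak 1 at dur/2
move_profile <- function(t, dur) 0.5 * (1 - cos(2 * pi * t / dur))

# trapezoid with raised-cosine edges: 0.5 s up, hold, 0.5 s down
pulse_profile <- function(t, dur) {
  edge <- 0.5
  up <- t < edge
  down <- t > dur - edge
  p <- rep(1, length(t))
  p[up] <- 0.5 * (1 - cos(pi * t[up] / edge))
  p[down] <- 0.5 * (1 - cos(pi * (dur - t[down]) / edge))
  p
}

sample_angles <- function(sched, rate) {
  n <- round(sched$duration * rate) + 1L
  tt <- (seq_len(n) - 1L) / rate
  theta <- matrix(0, n, 2L, dimnames = list(NULL, c("x", "y")))
  if (!is.null(sched$moves)) {
    for (i in seq_len(nrow(sched$moves))) {
      mv <- sched$moves[i, ]
      sel <- tt >= mv$onset & tt <= mv$onset + mv$duration
      p <- move_profile(tt[sel] - mv$onset, mv$duration) * mv$amplitude
      theta[sel, 1L] <- theta[sel, 1L] + p * cos(mv$angle)
      theta[sel, 2L] <- theta[sel, 2L] + p * sin(mv$angle)
    }
  }
  theta
}

sample_grip <- function(sched, rate) {
  n <- round(sched$duration * rate) + 1L
  tt <- (seq_len(n) - 1L) / rate
  g <- numeric(n)
  if (!is.null(sched$grip)) {
    for (i in seq_len(nrow(sched$grip))) {
      pl <- sched$grip[i, ]
      sel <- tt >= pl$onset & tt <= pl$onset + pl$duration
      prof <- if (sched$grip_mode == "pulses")
        pulse_profile(tt[sel] - pl$onset, pl$duration)
      else
        pmin(1, (tt[sel] - pl$onset) / 0.5)  # smooth-on constant grip
      g[sel] <- pmax(g[sel], prof * pl$level)
    }
  }
  g
}

#' Simulate a wrist-angle trajectory for one trial
#'
#' Raised-cosine excursions from the centre to each of the four movement
#' directions and back, `n_reps` repetitions each, with the executed
#' direction jittered by `diagonal_bias`. Extension is positive on axis x,
#' radial deviation positive on axis y. Conditions without wrist movement
#' give an identically-zero trajectory of the trial's duration.
#'
#' @param spec A [trial_spec()].
#' @param seed Integer seed (controls the direction jitter).
#' @param rate Output sampling rate, Hz; defaults to `spec$angle_rate`.
#' @return List with `theta` (time x 2 matrix, degrees, columns x/y) and
#'   `rate`.
#' @export
simulate_wrist_trajectory <- function(spec, seed = 1L, rate = spec$angle_rate) {
  sched <- trial_schedule(spec, seed)
  list(theta = sample_angles(sched, rate), rate = rate)
}

#' Simulate the grip-force profile for one trial
#'
#' Trapezoidal pulses (raised-cosine edges, 1 s plateau) at the condition's
#' force levels, normalized so that maximum grip strength is 1.
#'
#' @inheritParams simulate_wrist_trajectory
#' @return List with `force` (numeric vector, normalized units) and `rate`.
#' @export
simulate_grip_profile <- function(spec, seed = 1L, rate = spec$force_rate) {
  sched <- trial_schedule(spec, seed)
  list(force = sample_grip(sched, rate), rate = rate)
}

# rectified direction tuning: wrist synergy k with preferred angle phi has
# activation [cos(phi) x + sin(phi) y]_+ on the amplitude-normalized angles
true_activations <- function(ground_truth, sched, theta, grip) {
  tm <- ground_truth$tuning_map
  j <- nrow(tm)
  n <- nrow(theta)
  M <- matrix(0, n, j, dimnames = list(NULL, tm$synergy))
  xn <- theta[, 1L] / sched$amplitude_deg
  yn <- theta[, 2L] / sched$amplitude_deg
  for (k in seq_len(j)) {
    if (tm$role[k] == "wrist") {
      phi <- tm$angle_deg[k] * pi / 180
      M[, k] <- pmax(cos(phi) * xn + sin(phi) * yn, 0) + sched$tonic
    } else {
      M[, k] <- grip
    }
  }
  M
}

#' Generate a synthetic recording session
#'
#' For each trial in the protocol, wrist kinematics and grip force are
#' simulated, converted to nonnegative synergy activations by rectified
#' direction tuning (wrist) and the force profile (grip), and mixed through
#' the ground-truth synergy matrix to give 7-channel envelope-like EMG at the
#' EMG rate; additive Gaussian noise at the ground truth's SNR is applied and
#' floored at zero. Angle and force streams are emitted at their own rates.
#'
#' @param ground_truth A [make_ground_truth()] object.
#' @param protocol List of [trial_spec()] (default [default_protocol()]).
#' @param seed Integer master seed; all per-trial randomness derives from it.
#' @param keep_truth Keep the true activation matrices in each trial (for
#'   validation), default TRUE.
#' @return An `emg_session`: list with `trials` (each carrying `emg`,
#'   `emg_rate`, `angles`, `angle_rate`, `force`, `force_rate`, `condition`,
#'   `channels` and optionally `truth`), plus `ground_truth`, `protocol`,
#'   `seed`.
#' @export
generate_session <- function(ground_truth, protocol = default_protocol(),
                             seed = 1L, keep_truth = TRUE) {
  if (!inherits(ground_truth, "ground_truth")) {
    stopf("`ground_truth` must come from make_ground_truth()")
  }
  if (!length(protocol)) stopf("empty protocol")
  n_ch <- nrow(ground_truth$S_true)
  set.seed(seed)
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   2L * length(protocol)),
                        nrow = 2L)
  trials <- vector("list", length(protocol))
  for (i in seq_along(protocol)) {
    spec <- protocol[[i]]
    sched <- trial_schedule(spec, trial_seeds[1L, i])
    theta_emg <- sample_angles(sched, spec$emg_rate)
    grip_emg <- sample_grip(sched, spec$emg_rate)
    M <- true_activations(ground_truth, sched, theta_emg, grip_emg)
    E <- M %*% t(ground_truth$S_true)
    if (isTRUE(ground_truth$grip_crosstalk > 0)) {
      E <- E + ground_truth$grip_crosstalk *
        (grip_emg^2 %o% ground_truth$crosstalk_pattern)
    }
    if (is.finite(ground_truth$snr_db)) {
      # envelope noise is post-filter by definition, i.e. band-limited:
      # white Gaussian noise shaped by the same 5 Hz envelope filter, scaled
      # to the target SNR, added and floored at zero
      noise_rms <- sqrt(mean(E^2)) * 10^(-ground_truth$snr_db / 20)
      set.seed(trial_seeds[2L, i])
      noise <- matrix(stats::rnorm(length(E)), nrow(E), ncol(E))
      bf <- signal::butter(2, min(5 / (spec$emg_rate / 2), 0.99),
                           type = "low")
      noise <- apply(noise, 2L, function(col) signal::filtfilt(bf, col))
      noise <- noise * (noise_rms / sqrt(mean(noise^2)))
      E <- pmax(E + noise, 0)
    }
    colnames(E) <- ground_truth$channels
    has_grip <- sched$grip_mode != "none"
    trials[[i]] <- list(
      condition = spec$condition,
      emg = E, emg_rate = spec$emg_rate,
      angles = sample_angles(sched, spec$angle_rate),
      angle_rate = spec$angle_rate,
      force = if (has_grip) sample_grip(sched, spec$force_rate) else NULL,
      force_rate = spec$force_rate,
      channels = ground_truth$channels
    )
    if (keep_truth) {
      trials[[i]]$truth <- list(activations = M, seed = trial_seeds[1L, i])
    }
  }
  structure(list(trials = trials, ground_truth = ground_truth,
                 protocol = protocol, seed = as.integer(seed)),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  conds <- vapply(x$trials, `[[`, "", "condition")
  cat(sprintf("synthetic EMG session: %d trials, seed %d\n",
              length(x$trials), x$seed))
  print(table(conds))
  invisible(x)
}
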