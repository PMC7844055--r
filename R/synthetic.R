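#' Configuration for synthetic decoding sessions
#'
#' Describes an event-locked synthetic session emulating a cued
#' grasp-and-lift experiment: trials at regular intervals (with jittered
#' onsets), input channels carrying event-locked band-limited oscillatory
#' bursts in white noise, rectified muscle-activity-like target envelopes
#' and smooth kinematics-like target trajectories that causally follow each
#' onset. Every random draw flows from the single `seed`.
#'
#' @param n_channels_in number of input channels.
#' @param n_targets_emg number of rectified envelope targets.
#' @param n_targets_kin number of smooth trajectory targets.
#' @param sample_rate sampling rate, Hz.
#' @param n_trials number of trials in the session.
#' @param trial_length trial duration, seconds.
#' @param inter_trial_gap rest between trials, seconds.
#' @param carrier_band input burst carrier frequency range, Hz.
#' @param burst_length input burst envelope length, seconds (Hanning bump).
#' @param snr linear amplitude signal-to-noise ratio of the input bursts.
#' @param onset_jitter uniform jitter of each trial onset after the trial
#'   start, seconds.
#' @param seed integer seed.
#' @return An object of class `synth_config` (named list).
#' @export
synth_config <- function(n_channels_in = 8,
                         n_targets_emg = 2,
                         n_targets_kin = 2,
                         sample_rate = 100,
                         n_trials = 30,
                         trial_length = 2,
                         inter_trial_gap = 1,
                         carrier_band = c(10, 30),
                         burst_length = 0.5,
                         snr = 5,
                         onset_jitter = 0.1,
                         seed = 1) {
  cfg <- list(n_channels_in = n_channels_in, n_targets_emg = n_targets_emg,
              n_targets_kin = n_targets_kin, sample_rate = sample_rate,
              n_trials = n_trials, trial_length = trial_length,
              inter_trial_gap = inter_trial_gap, carrier_band = carrier_band,
              burst_length = burst_length, snr = snr,
              onset_jitter = onset_jitter, seed = seed)
  stopifnot(n_channels_in >= 1, n_targets_emg + n_targets_kin >= 1,
            sample_rate > 0, n_trials >= 0, trial_length > 0,
            inter_trial_gap >= 0, snr > 0, onset_jitter >= 0,
            length(carrier_band) == 2, carrier_band[1] <= carrier_band[2])
  class(cfg) <- "synth_config"
  cfg
}

# raised-cosine (Hanning) bump of given length on a time axis, unit peak
hann_bump <- function(t, start, length) {
  u <- (t - start) / length
  ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
}

# smooth rise/fall trapezoid: raised-cosine edges, unit plateau
smooth_trapezoid <- function(t, start, rise, plateau, fall) {
  u <- t - start
  out <- numeric(length(t))
  r <- u >= 0 & u < rise
  out[r] <- 0.5 - 0.5 * cos(pi * u[r] / rise)
  p <- u >= rise & u < rise + plateau
  out[p] <- 1
  f <- u >= rise + plateau & u < rise + plateau + fall
  out[f] <- 0.5 + 0.5 * cos(pi * (u[f] - rise - plateau) / fall)
  out
}

#' Generate a synthetic decoding session
#'
#' Builds the full session from a [synth_config()]: a montage placing input
#' channels on the superficial shell of the default head ellipsoid (one per
#' octant direction), input signals as event-locked oscillatory bursts plus
#' white noise at the configured SNR, rectified envelope targets
#' (rise-plateau-fall, delayed after each onset) and smooth trajectory
#' targets (sigmoid rise and fall). Ground-truth noise-free envelopes and
#' trial events are returned alongside the signals.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_session`: list with `inputs` and
#'   `targets` ([continuous_signal()]s), `events` (data.frame `trial`,
#'   `start`, `onset`, `end`), `montage`, `envelopes` (noise-free target
#'   ground truth), `target_kind` (named character, `"emg"` or `"kin"`) and
#'   the generating `config`.
#' @export
#' @examples
#' ses <- generate_session(synth_config(n_trials = 2, seed = 7))
#' ses$inputs
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sr <- config$sample_rate
  gap <- config$inter_trial_gap
  len <- config$trial_length
  n_tr <- config$n_trials
  duration <- gap + max(n_tr, 1) * (len + gap)
  n <- as.integer(round(duration * sr)) + 1L
  t <- (seq_len(n) - 1) / sr

  # each trial has two cue-locked events, mirroring a grasp-and-lift cycle:
  # the grasp onset and the release that ends the hold phase
  starts <- if (n_tr > 0) gap + (seq_len(n_tr) - 1) * (len + gap) else numeric(0)
  onsets <- starts + stats::runif(n_tr, 0, config$onset_jitter)
  releases <- onsets + min(1, len / 2)
  events <- data.frame(trial = seq_len(n_tr), start = starts, onset = onsets,
                       release = releases, end = starts + len)

  # montage: unit octant directions scaled onto the shell of the default
  # head ellipsoid, recycled with a small azimuthal twist beyond 8 channels
  dirs <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  dirs <- dirs / sqrt(3)
  ax <- c(60, 80, 50)
  k <- config$n_channels_in
  idx <- ((seq_len(k) - 1) %% 8) + 1
  twist <- 0.15 * ((seq_len(k) - 1) %/% 8)
  montage <- data.frame(
    label = sprintf("in%d", seq_len(k)),
    x = 0.85 * ax[1] * (dirs[idx, 1] + twist),
    y = 0.85 * ax[2] * dirs[idx, 2],
    z = 0.85 * ax[3] * dirs[idx, 3]
  )

  # inputs: per-channel carrier within the band, fixed phase, per-channel
  # gain; every trial contributes one onset-locked burst
  gains <- stats::runif(k, 0.8, 1.2)
  freqs <- stats::runif(k, config$carrier_band[1], config$carrier_band[2])
  phases <- stats::runif(k, 0, 2 * pi)
  inputs <- matrix(0, n, k)
  for (j in seq_len(k)) {
    x <- numeric(n)
    for (i in seq_len(n_tr)) {
      env <- hann_bump(t, onsets[i], config$burst_length) +
        0.9 * hann_bump(t, releases[i], config$burst_length)
      x <- x + env * sin(2 * pi * freqs[j] * (t - onsets[i]) + phases[j])
    }
    inputs[, j] <- gains[j] * x + stats::rnorm(n, 0, gains[j] / config$snr)
  }
  colnames(inputs) <- montage$label

  # targets: envelopes causally follow the onset (delay >= 0)
  n_emg <- config$n_targets_emg
  n_kin <- config$n_targets_kin
  p <- n_emg + n_kin
  tg_labels <- c(if (n_emg) sprintf("emg%d", seq_len(n_emg)),
                 if (n_kin) sprintf("kin%d", seq_len(n_kin)))
  tg_kind <- c(rep("emg", n_emg), rep("kin", n_kin))
  names(tg_kind) <- tg_labels
  env_mat <- matrix(0, n, p)
  for (j in seq_len(p)) {
    env <- numeric(n)
    if (tg_kind[j] == "emg") {
      # muscle activity: rises just after grasp and persists through the
      # release movement (forearm muscles act in both phases)
      delay <- 0.1 + 0.05 * (j - 1)
      for (i in seq_len(n_tr)) {
        a <- onsets[i] + delay
        env <- env + smooth_trapezoid(t, a, rise = 0.3,
                                      plateau = max(releases[i] + 0.2 - a - 0.3, 0),
                                      fall = 0.3)
      }
    } else {
      # position-like trajectory: lifts after grasp, returns after release
      delay <- 0.2 + 0.15 * (j - n_emg - 1)
      for (i in seq_len(n_tr)) {
        a <- onsets[i] + delay
        env <- env + smooth_trapezoid(t, a, rise = 0.4,
                                      plateau = max(releases[i] + 0.1 - a - 0.4, 0),
                                      fall = 0.4)
      }
    }
    env_mat[, j] <- env
  }
  colnames(env_mat) <- tg_labels
  # EMG-like targets are amplitude-modulated rectified activity: a fast
  # ripple multiplies the envelope (so spiking activity persists through the
  # plateau, as in rectified EMG), plus a small smoothed baseline noise.
  # Kinematics-like targets are the smooth trajectory plus slow noise.
  ma <- function(x, w) as.numeric(stats::filter(x, rep(1 / w, w),
                                                circular = TRUE))
  targets <- env_mat
  for (j in seq_len(p)) {
    if (tg_kind[j] == "emg") {
      ripple <- ma(stats::rnorm(n), 3)
      base <- ma(stats::rnorm(n, 0, 1 / (4 * config$snr)), 5)
      targets[, j] <- pmax(env_mat[, j] * (1 + ripple / config$snr) + base, 0)
    } else {
      # kinematic sensors: low-amplitude, slowly varying noise
      slow <- ma(stats::rnorm(n, 0, 1 / (2 * config$snr)), 20)
      targets[, j] <- env_mat[, j] + slow
    }
  }

  structure(list(
    inputs = continuous_signal(inputs, sr),
    targets = continuous_signal(targets, sr),
    events = events,
    montage = montage,
    envelopes = continuous_signal(env_mat, sr),
    target_kind = tg_kind,
    config = config
  ), class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf(
    "<synth_session> %d trials, %d input + %d target channels, %.1f s @ %g Hz\n",
    nrow(x$events), ncol(x$inputs$values), ncol(x$targets$values),
    nrow(x$inputs$values) / x$inputs$sample_rate, x$inputs$sample_rate))
  invisible(x)
}

#' Trial-shuffled negative control for a session
#'
#' Circularly shifts every target channel (and its ground-truth envelope)
#' by an independent random offset of at least one trial length, destroying
#' the input-target alignment while leaving all marginal statistics and the
#' inputs themselves untouched. Used as the chance-level reference when
#' scoring decoders.
#'
#' @param session a [generate_session()] result.
#' @param seed integer seed for the shift draws.
#' @return A `synth_session` with shifted targets.
#' @export
shuffled_control <- function(session, seed = 1) {
  stopifnot(inherits(session, "synth_session"))
  if (nrow(session$events) < 2)
    stop("shuffled control needs at least 2 trials", call. = FALSE)
  set.seed(seed)
  sr <- session$targets$sample_rate
  n <- nrow(session$targets$values)
  min_shift <- as.integer(round(session$config$trial_length * sr))
  out <- session
  for (j in seq_len(ncol(session$targets$values))) {
    shift <- sample.int(n - 2L * min_shift, 1L) + min_shift
    ix <- ((seq_len(n) - 1L + shift) %% n) + 1L
    out$targets$values[, j] <- session$targets$values[ix, j]
    out$envelopes$values[, j] <- session$envelopes$values[ix, j]
  }
  out
}

#' Crop a session to a range of trials
#'
#' Returns the sub-session spanning trials `from` to `to`, from one
#' inter-trial gap before the first trial's start to the end of the last
#' trial, with times re-anchored at zero. Used to split a session into
#' training and test portions.
#'
#' @param session a `synth_session`.
#' @param from,to trial indices (inclusive).
#' @return A `synth_session` covering the requested trials.
#' @export
session_window <- function(session, from, to) {
  ev <- session$events
  stopifnot(from >= 1, to <= nrow(ev), from <= to)
  sr <- session$inputs$sample_rate
  t_from <- ev$start[from] - session$config$inter_trial_gap
  t_to <- ev$end[to]
  i0 <- as.integer(round(t_from * sr)) + 1L
  i1 <- as.integer(round(t_to * sr)) + 1L
  crop <- function(sig) continuous_signal(sig$values[i0:i1, , drop = FALSE],
                                          sr, sig$channel_labels)
  out <- session
  out$inputs <- crop(session$inputs)
  out$targets <- crop(session$targets)
  out$envelopes <- crop(session$envelopes)
  ev <- ev[ev$trial >= from & ev$trial <= to, , drop = FALSE]
  ev$start <- ev$start - t_from
  ev$onset <- ev$onset - t_from
  ev$end <- ev$end - t_from
  ev$trial <- seq_len(nrow(ev))
  out$events <- ev
  out$config$n_trials <- nrow(ev)
  out
}
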