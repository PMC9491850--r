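# Synthetic multi-channel sEMG + force generator.
#
# Emulates the statistical structure of upper-arm recordings during 2 s
# effort / 2 s rest bouts: band-limited stochastic carriers (20-150 Hz)
# amplitude-modulated by task activation envelopes, 50 Hz powerline pickup,
# a narrowband ~110 Hz ECG-like artifact, and additive white noise at a
# controlled SNR. The force trace is a saturating function of the planted
# per-muscle activations, so the dominant muscle of each task is known
# ground truth for validating importance rankings.

semg_tasks <- c("flexion", "extension", "pronation", "supination")

# dominant muscle per task: biceps brachii, triceps brachii,
# brachioradialis, brachialis
semg_task_dominant <- c(
  flexion = "BB", extension = "TB", pronation = "BRD", supination = "BR"
)

#' Per-task muscle weight vector with a planted dominant channel
#'
#' Returns the force weights used by the generator: the task's dominant
#' muscle gets weight 1 and the remaining channels get decreasing
#' co-activation weights (0.35, 0.20, 0.10, ...) in label order --
#' physiological co-contraction levels for isometric elbow tasks -- so
#' exactly one channel is maximal.
#'
#' @param task One of `"flexion"`, `"extension"`, `"pronation"`,
#'   `"supination"`.
#' @param channel_labels Character vector of muscle labels.
#' @return Named numeric vector of per-channel weights in `[0, 1]`.
#' @export
task_weights <- function(task, channel_labels = c("BB", "TB", "BR", "BRD")) {
  task <- check_task(task)
  dominant <- semg_task_dominant[[task]]
  w <- stats::setNames(numeric(length(channel_labels)), channel_labels)
  co <- c(0.35, 0.20, 0.10, 0.06, 0.04)
  others <- setdiff(channel_labels, dominant)
  w[others] <- co[seq_along(others)]
  if (dominant %in% channel_labels) {
    w[dominant] <- 1
  } else {
    # unlabelled channel sets: plant the dominant on the task's index
    w[(match(task, semg_tasks) - 1L) %% length(w) + 1L] <- 1
  }
  w
}

check_task <- function(task) {
  if (length(task) != 1L || !task %in% semg_tasks) {
    abort(sprintf(
      "Unknown task '%s'. Valid tasks: %s.",
      as.character(task)[1], paste(semg_tasks, collapse = ", ")
    ))
  }
  task
}

#' Synthetic recording configuration
#'
#' Bundles every parameter of the synthetic sEMG generator. Defaults are the
#' package's reference acquisition conditions: 4 upper-arm channels sampled
#' at 1000 Hz, carriers band-limited to 20-150 Hz with moderate inter-channel
#' correlation, 2 s effort / 2 s rest bouts, 50 Hz powerline and ~110 Hz
#' ECG-like contamination, and 20 dB additive white noise.
#'
#' @param duration Recording length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param n_channels Number of muscle channels.
#' @param channel_labels Muscle names, one per channel.
#' @param task Contraction task; decides the planted dominant muscle.
#' @param weight_vector Per-channel force weights (>= 0, exactly one
#'   maximum). `NULL` uses [task_weights()].
#' @param powerline_hz,powerline_amplitude Powerline interference frequency
#'   (Hz) and amplitude relative to the channel's carrier RMS.
#' @param ecg_artifact_hz,ecg_amplitude ECG-like narrowband artifact
#'   frequency (Hz) and relative amplitude.
#' @param snr_db Signal-to-noise ratio (dB) of the additive white noise;
#'   `Inf` or `NULL` disables it.
#' @param seed Integer RNG seed; the whole recording is a deterministic
#'   function of the config.
#' @param carrier_band Band-pass edges (Hz) of the stochastic carrier.
#' @param carrier_cor Fraction of carrier variance shared across channels.
#' @param bout_s,rest_s,ramp_s Effort-bout length, rest length, and
#'   raised-cosine ramp length, all in seconds.
#' @param force_scale Peak force scale in Newtons.
#' @param force_saturation Shape parameter of the saturating
#'   activation-to-force map `g(u) = tanh(s u) / tanh(s)`.
#' @param force_noise_sd Standard deviation (N) of load-cell noise.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration = 60, fs = 1000, n_channels = 4,
                         channel_labels = c("BB", "TB", "BR", "BRD"),
                         task = "flexion", weight_vector = NULL,
                         powerline_hz = 50, powerline_amplitude = 0.5,
                         ecg_artifact_hz = 110, ecg_amplitude = 0.4,
                         snr_db = 20, seed = 1,
                         carrier_band = c(20, 150), carrier_cor = 0.3,
                         bout_s = 2, rest_s = 2, ramp_s = 0.25,
                         force_scale = 10, force_saturation = 1.5,
                         force_noise_sd = 0.05) {
  task <- check_task(task)
  stopifnot(length(channel_labels) == n_channels)
  if (is.null(weight_vector)) {
    weight_vector <- unname(task_weights(task, channel_labels))
  }
  cfg <- structure(list(
    duration = duration, fs = fs, n_channels = n_channels,
    channel_labels = channel_labels, task = task,
    weight_vector = weight_vector,
    powerline_hz = powerline_hz, powerline_amplitude = powerline_amplitude,
    ecg_artifact_hz = ecg_artifact_hz, ecg_amplitude = ecg_amplitude,
    snr_db = if (is.null(snr_db)) Inf else snr_db, seed = as.integer(seed),
    carrier_band = carrier_band, carrier_cor = carrier_cor,
    bout_s = bout_s, rest_s = rest_s, ramp_s = ramp_s,
    force_scale = force_scale, force_saturation = force_saturation,
    force_noise_sd = force_noise_sd
  ), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (cfg$duration <= 0 || cfg$fs <= 0) {
    abort("duration and fs must be positive.")
  }
  if (cfg$duration < cfg$bout_s) {
    abort(sprintf("duration must cover at least one %g s effort bout.",
                  cfg$bout_s))
  }
  f_max <- max(cfg$carrier_band[2], cfg$powerline_hz, cfg$ecg_artifact_hz)
  if (cfg$fs <= 2 * f_max) {
    abort(sprintf("fs = %g Hz cannot represent content up to %g Hz.",
                  cfg$fs, f_max))
  }
  w <- cfg$weight_vector
  if (length(w) != cfg$n_channels || any(w < 0)) {
    abort("weight_vector needs one non-negative entry per channel.")
  }
  if (sum(w == max(w)) != 1L) {
    abort("weight_vector must have exactly one maximal entry (the planted dominant muscle).")
  }
  if (cfg$powerline_amplitude < 0 || cfg$ecg_amplitude < 0) {
    abort("artifact amplitudes must be >= 0.")
  }
  cfg
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-channel rest/effort envelopes in [0, 1]: raised-cosine ramps, a shared
# random amplitude per effort bout, and muscle-specific per-bout jitter.
# The jitter is what makes per-muscle contributions identifiable: perfectly
# shared envelopes would leave the channels collinear and no importance
# method could attribute force among them. Jitter columns are assigned by
# weight rank so that permuting channels together with the weight vector
# permutes the envelopes identically (and leaves the force unchanged).
# Deterministic given the current RNG state.
make_envelopes <- function(n, fs, bout_s, rest_s, ramp_s, weight_vector) {
  n_ch <- length(weight_vector)
  cycle <- round((rest_s + bout_s) * fs)
  rest_n <- round(rest_s * fs)
  bout_n <- round(bout_s * fs)
  ramp_n <- max(1L, min(round(ramp_s * fs), floor(bout_n / 2)))
  shape <- rep(1, bout_n)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
  shape[seq_len(ramp_n)] <- up
  shape[bout_n + 1L - seq_len(ramp_n)] <- up
  n_bouts <- ceiling(n / cycle)

  amps <- runif(n_bouts, 0.7, 1)
  jitter <- matrix(runif(n_bouts * n_ch, 0.7, 1.3), n_bouts, n_ch)
  ord <- order(weight_vector, decreasing = TRUE)
  amp_ch <- matrix(0, n_bouts, n_ch)
  for (j in seq_len(n_ch)) {
    amp_ch[, ord[j]] <- pmin(amps * jitter[, j], 1)
  }
  involvement <- weight_vector / max(weight_vector)

  # slow (< 1 Hz) muscle-specific drive wander inside effort bouts
  lp <- signal::butter(2, min(1 / (fs / 2), 0.99), type = "low")
  wander <- matrix(rnorm(n * n_ch), n, n_ch)
  wander_ch <- matrix(0, n, n_ch)
  for (j in seq_len(n_ch)) {
    w <- signal::filtfilt(lp, wander[, j])
    wander_ch[, ord[j]] <- w / max(sd(w), 1e-12)
  }

  env <- matrix(0, n, n_ch)
  for (b in seq_len(n_bouts)) {
    start <- (b - 1L) * cycle + rest_n + 1L
    if (start > n) next
    idx <- start:min(start + bout_n - 1L, n)
    env[idx, ] <- outer(shape[seq_along(idx)], amp_ch[b, ] * involvement) *
      pmax(1 + 0.15 * wander_ch[idx, , drop = FALSE], 0)
  }
  pmin(pmax(env, 0), 1)
}

#' Per-channel activation envelopes for a contraction task
#'
#' Builds smooth (band-limited below 5 Hz) activation envelopes in `[0, 1]`:
#' alternating rest and effort bouts with raised-cosine ramps, a shared
#' random amplitude per bout with muscle-specific jitter (so channels are
#' correlated but not collinear), scaled per channel by its involvement in
#' the task (the channel's force weight relative to the dominant
#' muscle's).
#'
#' @inheritParams task_weights
#' @param duration Length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param seed Integer RNG seed.
#' @param weight_vector Optional per-channel weights; defaults to
#'   [task_weights()].
#' @param bout_s,rest_s,ramp_s Bout timing in seconds.
#' @return A `duration * fs` by `n_channels` matrix of envelopes.
#' @export
generate_activation <- function(task, duration, fs, seed,
                                channel_labels = c("BB", "TB", "BR", "BRD"),
                                weight_vector = NULL,
                                bout_s = 2, rest_s = 2, ramp_s = 0.25) {
  task <- check_task(task)
  if (duration < bout_s) abort("duration must cover at least one effort bout.")
  if (is.null(weight_vector)) {
    weight_vector <- unname(task_weights(task, channel_labels))
  }
  n <- round(duration * fs)
  with_seed(seed, {
    env <- make_envelopes(n, fs, bout_s, rest_s, ramp_s, weight_vector)
    colnames(env) <- channel_labels
    env
  })
}

# Unit-RMS stochastic carrier band-limited to `band` Hz.
bandpass_carrier <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate a synthetic sEMG recording with a synchronized force trace
#'
#' Each channel is an envelope-modulated band-limited stochastic carrier
#' (power concentrated in the configured 20-150 Hz band) plus a powerline
#' sinusoid, a narrowband ECG-like artifact, and white noise at the
#' configured SNR. The force trace is
#' `force_scale * sum_c w_c g(envelope_c) + noise` with `g` a monotone
#' saturating map, so per-muscle force contributions are known ground truth.
#'
#' @param config A [synth_config()].
#' @return A tibble of class `semg_recording` with columns `time`, one per
#'   channel label, and `force`; the generating config is attached as the
#'   `truth` attribute.
#' @examples
#' rec <- generate_recording(synth_config(duration = 4, seed = 1))
#' dim(rec)
#' @export
generate_recording <- function(config) {
  cfg <- validate_synth_config(config)
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  with_seed(cfg$seed, {
    env <- make_envelopes(n, cfg$fs, cfg$bout_s, cfg$rest_s, cfg$ramp_s,
                          cfg$weight_vector)

    common <- bandpass_carrier(n, cfg$fs, cfg$carrier_band)
    rho <- cfg$carrier_cor
    clean <- matrix(0, n, cfg$n_channels)
    phases <- matrix(0, 2, cfg$n_channels)
    for (c in seq_len(cfg$n_channels)) {
      own <- bandpass_carrier(n, cfg$fs, cfg$carrier_band)
      carrier <- sqrt(1 - rho) * own + sqrt(rho) * common
      clean[, c] <- carrier * env[, c]
      phases[, c] <- runif(2, 0, 2 * pi)
    }
    # artifact amplitudes are relative to each channel's own activity level
    # so contamination severity is uniform across channels
    rms_ch <- sqrt(colMeans(clean^2))
    # slow amplitude modulation keeps the ECG-like artifact narrowband but
    # not a pure tone
    am <- 1 + 0.2 * signal::filtfilt(
      signal::butter(2, 2 / (cfg$fs / 2), type = "low"), rnorm(n))
    for (c in seq_len(cfg$n_channels)) {
      clean[, c] <- clean[, c] +
        cfg$powerline_amplitude * rms_ch[c] *
          sin(2 * pi * cfg$powerline_hz * t + phases[1, c]) +
        cfg$ecg_amplitude * rms_ch[c] * am *
          sin(2 * pi * cfg$ecg_artifact_hz * t + phases[2, c])
    }

    signals <- clean
    if (is.finite(cfg$snr_db)) {
      for (c in seq_len(cfg$n_channels)) {
        signals[, c] <- add_noise_snr(clean[, c], cfg$snr_db, seed = NULL)
      }
    }

    g <- function(u) tanh(cfg$force_saturation * u) / tanh(cfg$force_saturation)
    force <- cfg$force_scale * as.vector(g(env) %*% cfg$weight_vector) +
      rnorm(n, sd = cfg$force_noise_sd)

    new_recording(signals, force, cfg$fs, cfg$channel_labels, truth = cfg)
  })
}

#' Construct an sEMG recording tibble
#'
#' @param signals Time-by-channel numeric matrix.
#' @param force Force vector (N), same length as `signals` rows.
#' @param fs Sampling frequency in Hz.
#' @param labels Channel names.
#' @param truth Optional provenance (a [synth_config()]).
#' @return A `semg_recording` tibble with columns `time`, channels, `force`.
#' @export
new_recording <- function(signals, force, fs, labels, truth = NULL) {
  signals <- as.matrix(signals)
  if (nrow(signals) != length(force)) {
    abort("signals and force must have identical length.")
  }
  if (fs <= 0) abort("fs must be positive.")
  if (length(labels) != ncol(signals)) {
    abort("labels length must equal the channel count.")
  }
  colnames(signals) <- labels
  out <- bind_cols(
    tibble(time = (seq_len(nrow(signals)) - 1) / fs),
    as_tibble(signals),
    tibble(force = as.numeric(force))
  )
  attr(out, "fs") <- fs
  attr(out, "channel_labels") <- labels
  attr(out, "truth") <- truth
  class(out) <- c("semg_recording", class(out))
  out
}

rec_fs <- function(recording) attr(recording, "fs")
rec_labels <- function(recording) attr(recording, "channel_labels")

rec_signals <- function(recording) {
  as.matrix(recording[, rec_labels(recording), drop = FALSE])
}

rec_force <- function(recording) recording[["force"]]

#' Scale one or more channels of a recording
#'
#' Multiplies the named or indexed channels by `factor`, leaving force and
#' the remaining channels untouched. Used by the muscle-level Mean Impact
#' Value procedure, which perturbs raw channels before windowing/reduction.
#'
#' @param recording A `semg_recording`.
#' @param channels Channel names or indices.
#' @param factor Multiplicative factor.
#' @return The perturbed recording.
#' @export
scale_channels <- function(recording, channels, factor) {
  labels <- rec_labels(recording)
  if (is.numeric(channels)) channels <- labels[channels]
  stopifnot(all(channels %in% labels))
  for (ch in channels) recording[[ch]] <- recording[[ch]] * factor
  recording
}

#' Generate one recording per contraction task
#'
#' Produces four recordings (flexion, extension, pronation, supination)
#' sharing the base config's duration and sampling rate, each with its
#' task's planted dominant muscle and a distinct per-task seed derived from
#' the base seed.
#'
#' @param base_config A [synth_config()]; its `task`/`weight_vector` are
#'   replaced per task.
#' @return Named list of `semg_recording`, one per task.
#' @export
generate_task_suite <- function(base_config) {
  cfg <- validate_synth_config(base_config)
  recs <- lapply(seq_along(semg_tasks), function(i) {
    task <- semg_tasks[i]
    cfg_i <- cfg
    cfg_i$task <- task
    cfg_i$weight_vector <- unname(task_weights(task, cfg$channel_labels))
    cfg_i$seed <- cfg$seed + (i - 1L) * 101L
    generate_recording(validate_synth_config(cfg_i))
  })
  stats::setNames(recs, semg_tasks)
}
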