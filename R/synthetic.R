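#' Standard 32-channel 10-20 montage
#'
#' The default electrode layout used by the synthetic generator: a common
#' 32-channel extended 10-20 montage including the occipital sites O1, Oz
#' and O2 over visual cortex, where the SSVEP response is strongest.
#'
#' @return character vector of 32 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1",
    "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
    "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1",
    "Oz", "O2")
}

#' Default occipital gain profile
#'
#' Per-channel multiplier applied to the evoked sinusoid: 1.0 on the
#' occipital channels (O1/O2/Oz), 0.3 on parietal channels, 0.05 elsewhere.
#' This topography makes occipital-channel averaging meaningfully better
#' than whole-head averaging, as the decoder's channel choice presumes.
#'
#' @param channel_labels character vector of 10-20 labels.
#' @return named numeric vector of gains, one per channel.
#' @export
occipital_gain_profile <- function(channel_labels) {
  g <- rep(0.05, length(channel_labels))
  g[grepl("^P", channel_labels)] <- 0.3
  g[channel_labels %in% c("O1", "O2", "Oz")] <- 1.0
  names(g) <- channel_labels
  g
}

#' Configuration for the synthetic SSVEP session generator
#'
#' Describes one multi-participant SSVEP experiment: stimulation frequencies,
#' trial structure, electrode montage, and the amplitudes of the evoked
#' response, the background noise and the shared (inter-brain coupled)
#' component.
#'
#' @param sampling_rate acquisition rate in Hz (default 1000, the client-side
#'   maximum).
#' @param channel_labels electrode labels; must contain O1, O2 and Oz.
#' @param target_frequencies stimulus flicker frequencies in Hz
#'   (default `c(8, 10, 13)`).
#' @param trial_duration seconds per trial (default 10).
#' @param trials_per_target number of trials per stimulus target (default 10).
#' @param ssvep_amplitude amplitude (microvolts) of the evoked sinusoid on a
#'   unit-gain channel.
#' @param occipital_gain_profile per-channel multiplier of the evoked
#'   sinusoid; `NULL` uses [occipital_gain_profile()].
#' @param noise_amplitude standard deviation (microvolts) of the per-channel
#'   independent background noise (an equal-power mixture of 1/f-shaped and
#'   white Gaussian noise).
#' @param coupling_gain amplitude scale of the broadband component shared
#'   across participants (0 = fully independent brains). The shared waveform
#'   carries a random per-channel gain, redrawn each trial but identical
#'   across participants, so that inter-participant band-power correlation
#'   rises steeply with this knob.
#' @param n_participants number of participants in the session.
#' @param seed master seed; all randomness is derived from it by fixed
#'   arithmetic so results are fully reproducible.
#' @return an object of class `ssvep_config`.
#' @export
synthetic_config <- function(sampling_rate = 1000,
                             channel_labels = default_montage(),
                             target_frequencies = c(8, 10, 13),
                             trial_duration = 10,
                             trials_per_target = 10,
                             ssvep_amplitude = 5,
                             occipital_gain_profile = NULL,
                             noise_amplitude = 5,
                             coupling_gain = 0,
                             n_participants = 1,
                             seed = 1) {
  cfg <- list(sampling_rate = sampling_rate,
              channel_labels = as.character(channel_labels),
              target_frequencies = as.numeric(target_frequencies),
              trial_duration = trial_duration,
              trials_per_target = as.integer(trials_per_target),
              ssvep_amplitude = ssvep_amplitude,
              occipital_gain_profile = occipital_gain_profile,
              noise_amplitude = noise_amplitude,
              coupling_gain = coupling_gain,
              n_participants = as.integer(n_participants),
              seed = as.integer(seed))
  class(cfg) <- "ssvep_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (f in c("sampling_rate", "trial_duration", "ssvep_amplitude",
              "noise_amplitude", "coupling_gain", "seed"))
    stopifnot_scalar_number(cfg[[f]], f)
  if (length(cfg$target_frequencies) < 1L || any(cfg$target_frequencies <= 0))
    abort("invariant violated: target_frequencies must be positive")
  if (cfg$sampling_rate <= 2 * max(cfg$target_frequencies))
    abort("invariant violated: sampling_rate must exceed 2 x max(target_frequencies) (Nyquist)")
  if (!all(c("O1", "O2", "Oz") %in% cfg$channel_labels))
    abort("invariant violated: channel_labels must contain O1, O2 and Oz")
  if (anyDuplicated(cfg$channel_labels))
    abort("invariant violated: channel_labels must be unique")
  if (cfg$coupling_gain < 0)
    abort("invariant violated: coupling_gain must be >= 0")
  if (is.na(cfg$trials_per_target) || cfg$trials_per_target < 1L)
    abort("invariant violated: trials_per_target must be >= 1")
  if (is.na(cfg$n_participants) || cfg$n_participants < 1L)
    abort("invariant violated: n_participants must be >= 1")
  if (cfg$noise_amplitude < 0 || cfg$ssvep_amplitude < 0)
    abort("invariant violated: amplitudes must be >= 0")
  n <- cfg$sampling_rate * cfg$trial_duration
  if (abs(n - round(n)) > 1e-9)
    abort("invariant violated: trial_duration x sampling_rate must be an integer sample count")
  if (is.null(cfg$occipital_gain_profile)) {
    cfg$occipital_gain_profile <- occipital_gain_profile(cfg$channel_labels)
  } else {
    if (length(cfg$occipital_gain_profile) != length(cfg$channel_labels))
      abort("invariant violated: occipital_gain_profile length must match channel_labels")
    names(cfg$occipital_gain_profile) <- cfg$channel_labels
  }
  cfg
}

#' @export
print.ssvep_config <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_config> %d participant(s), targets %s Hz, ",
                     "%d x %gs trials/target @ %g Hz, %d channels\n"),
              x$n_participants,
              paste(x$target_frequencies, collapse = "/"),
              x$trials_per_target, x$trial_duration, x$sampling_rate,
              length(x$channel_labels)))
  cat(sprintf("  ssvep_amplitude=%g noise_amplitude=%g coupling_gain=%g seed=%d\n",
              x$ssvep_amplitude, x$noise_amplitude, x$coupling_gain, x$seed))
  invisible(x)
}

#' The trial schedule of a session
#'
#' Targets are presented round-robin (e.g. 8, 10, 13, 8, 10, 13, ...) with
#' back-to-back trials; every participant of a session shares this schedule
#' (stimulation modes are synchronized across the group).
#'
#' @param config an `ssvep_config`.
#' @return data.frame with columns `trial`, `onset`, `duration`, `frequency`.
#' @export
trial_schedule <- function(config) {
  freqs <- rep(config$target_frequencies, times = config$trials_per_target)
  data.frame(trial = seq_along(freqs),
             onset = (seq_along(freqs) - 1) * config$trial_duration,
             duration = config$trial_duration,
             frequency = freqs)
}

# 1/f-shaped ("pink") Gaussian noise, one unit-variance column per channel.
pink_noise <- function(n, n_channels) {
  z <- matrix(rnorm(n * n_channels), nrow = n)
  zf <- mvfft(z)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # symmetric frequency index, DC at 0
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(mvfft(zf * scale, inverse = TRUE)) / n
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

# Independent pink+white mixture with overall unit variance per channel.
broadband_noise <- function(n, n_channels) {
  (pink_noise(n, n_channels) +
     matrix(rnorm(n * n_channels), nrow = n)) / sqrt(2)
}

#' Generate one participant's synthetic SSVEP recording
#'
#' Builds a continuous multi-channel EEG recording for the session described
#' by `config`: for each trial the occipital channels carry a sinusoid at
#' the trial's target frequency (amplitude `ssvep_amplitude` scaled by the
#' occipital gain profile, random phase per trial), superposed on independent
#' 1/f + white background noise and, when `coupling_gain > 0`, a broadband
#' component shared by all participants of the session. Deterministic given
#' `(config$seed, participant_index)`; adding participants never changes the
#' data of existing ones.
#'
#' @param config an `ssvep_config`.
#' @param participant_index 1-based participant index
#'   (`<= config$n_participants`).
#' @return an `eeg_recording` with trial annotations.
#' @export
generate_recording <- function(config, participant_index = 1L) {
  config <- validate_config(config)
  if (participant_index < 1L || participant_index > config$n_participants)
    abort("participant_index must be in 1..n_participants (= %d)",
          config$n_participants)
  sched <- trial_schedule(config)
  fs <- config$sampling_rate
  n <- as.integer(round(config$trial_duration * fs))
  nch <- length(config$channel_labels)
  gain <- config$occipital_gain_profile
  t_axis <- (seq_len(n) - 1) / fs

  blocks <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    f <- sched$frequency[i]
    trial <- with_seed(mix_seed(config$seed, participant_index, i), {
      phase <- runif(1, 0, 2 * pi)
      noise <- if (config$noise_amplitude > 0)
        config$noise_amplitude * t(broadband_noise(n, nch))
      else matrix(0, nch, n)
      sig <- config$ssvep_amplitude *
        outer(unname(gain), sin(2 * pi * f * t_axis + phase))
      sig + noise
    })
    if (config$coupling_gain > 0) {
      shared <- with_seed(mix_seed(config$seed, 0L, i), {
        gamma_ch <- rnorm(nch)            # per-channel shared gain profile
        gamma_ch * t(broadband_noise(n, nch))   # recycles by row = channel
      })
      trial <- trial + config$coupling_gain * shared
    }
    blocks[[i]] <- trial
  }
  samples <- do.call(cbind, blocks)
  new_recording(participant_id = sprintf("sub-%02d", participant_index),
                channel_labels = config$channel_labels,
                sampling_rate = fs,
                samples = samples,
                annotations = data.frame(onset = sched$onset,
                                         duration = sched$duration,
                                         label = sprintf("target:%g",
                                                         sched$frequency)))
}

#' Generate a whole multi-participant session
#'
#' All participants share the same trial schedule (same target sequence and
#' onsets) and the same shared-noise streams, so `coupling_gain` acts
#' identically across the group.
#'
#' @param config an `ssvep_config`.
#' @return list of `eeg_recording`, one per participant.
#' @export
generate_group_session <- function(config) {
  config <- validate_config(config)
  lapply(seq_len(config$n_participants),
         function(p) generate_recording(config, p))
}

#' EEG recording container
#'
#' @param participant_id string identifier.
#' @param channel_labels ordered channel labels.
#' @param sampling_rate Hz.
#' @param samples channels x time numeric matrix (microvolt scale).
#' @param annotations data.frame with columns onset, duration, label
#'   (trial markers; labels `"target:<Hz>"` encode the true frequency).
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(participant_id, channel_labels, sampling_rate,
                          samples, annotations = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels))
    abort("samples has %d rows but there are %d channel labels",
          nrow(samples), length(channel_labels))
  ann <- annotations %||%
    data.frame(onset = numeric(), duration = numeric(), label = character())
  dur <- ncol(samples) / sampling_rate
  if (nrow(ann) && any(ann$onset < 0 | ann$onset + ann$duration > dur + 1e-9))
    abort("annotations must lie within [0, %g] s", dur)
  rownames(samples) <- channel_labels
  structure(list(participant_id = participant_id,
                 channel_labels = as.character(channel_labels),
                 sampling_rate = sampling_rate,
                 samples = samples,
                 annotations = ann),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d ch x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              x$participant_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, ncol(x$samples) / x$sampling_rate,
              nrow(x$annotations)))
  invisible(x)
}

# Parse the true target frequency out of an annotation label.
annotation_frequency <- function(label) {
  as.numeric(sub("^target:", "", label))
}
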