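#' Welch power spectral density of an epoch
#'
#' Mean of Hann-windowed, mean-detrended periodograms over (possibly
#' overlapping) segments, scaled as power per Hz (one-sided). The default
#' segment length is the full epoch, in which case the estimate degenerates
#' to a single modified periodogram: a 1-s epoch at 512 Hz then yields a
#' 1 Hz grid on which the 8/10/13 Hz targets are exact bins.
#'
#' @param epoch an `eeg_epoch`, or a channels x time numeric matrix (then
#'   `sampling_rate` must be given).
#' @param segment_length samples per Welch segment (default: epoch length).
#' @param overlap_fraction fractional overlap between segments, in `[0, 1)`.
#' @param window `"hann"` (periodic) or `"rectangular"`.
#' @param sampling_rate required when `epoch` is a bare matrix.
#' @return a `psd_matrix` (channels x frequencies, non-negative, grid
#'   spacing `sampling_rate / segment_length`).
#' @export
welch_psd <- function(epoch, segment_length = NULL, overlap_fraction = 0,
                      window = c("hann", "rectangular"),
                      sampling_rate = NULL) {
  window <- match.arg(window)
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples
    fs <- epoch$sampling_rate
    labels <- epoch$channel_labels
    info <- epoch[c("participant_id", "trial_index", "epoch_index",
                    "true_frequency")]
  } else {
    x <- as.matrix(epoch)
    fs <- sampling_rate
    if (is.null(fs)) abort("sampling_rate required for matrix input")
    labels <- rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x)))
    info <- NULL
  }
  n <- ncol(x)
  nseg <- as.integer(segment_length %||% n)
  if (nseg > n)
    abort("segment_length (%d) exceeds epoch length (%d)", nseg, n)
  if (nseg < 2L) abort("segment_length must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort("overlap_fraction must be in [0, 1)")
  step <- max(1L, as.integer(round(nseg * (1 - overlap_fraction))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg)   # periodic Hann
  else rep(1, nseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nseg %/% 2L + 1L
  acc <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)            # constant detrend
    X <- mvfft(t(seg * rep(w, each = nrow(seg))))
    P <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) * scale
    # one-sided: double everything but DC (and Nyquist when nseg is even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nseg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + t(P * dbl)
  }
  psd <- acc / length(starts)
  new_psd_matrix(labels, (seq_len(nfreq) - 1L) * fs / nseg, psd, info)
}

#' Per-channel PSD container
#'
#' @param channel_labels ordered channel labels.
#' @param frequencies uniform Hz grid starting at 0.
#' @param power channels x frequencies matrix of PSD values (power per Hz).
#' @param epoch_info optional provenance list (participant, trial, epoch,
#'   true frequency) carried along from the source epoch.
#' @return object of class `psd_matrix`.
#' @export
new_psd_matrix <- function(channel_labels, frequencies, power,
                           epoch_info = NULL) {
  power <- as.matrix(power)
  if (nrow(power) != length(channel_labels) ||
      ncol(power) != length(frequencies))
    abort("power must be channels x frequencies")
  if (any(power < 0)) abort("PSD values must be non-negative")
  rownames(power) <- channel_labels
  structure(list(channel_labels = as.character(channel_labels),
                 frequencies = as.numeric(frequencies),
                 power = power,
                 epoch_info = epoch_info),
            class = "psd_matrix")
}

#' @export
print.psd_matrix <- function(x, ...) {
  cat(sprintf("<psd_matrix> %d ch x %d bins (0-%g Hz, df=%g Hz)\n",
              nrow(x$power), length(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Band power at a target frequency
#'
#' Returns the PSD value at the grid bin nearest to `frequency`, per
#' channel; ties between two equidistant bins resolve toward the lower
#' frequency. On the default 1 Hz grid the 8/10/13 Hz targets are exact
#' bins, so no rounding occurs.
#'
#' @param psd a `psd_matrix`.
#' @param frequency query frequency in Hz, within the grid range.
#' @return named numeric vector, one PSD value per channel.
#' @export
band_power <- function(psd, frequency) {
  stopifnot_scalar_number(frequency, "frequency")
  if (frequency < 0 || frequency > max(psd$frequencies))
    abort("frequency %g Hz outside the PSD grid [0, %g]",
          frequency, max(psd$frequencies))
  idx <- which.min(abs(psd$frequencies - frequency))  # first = lower on ties
  stats::setNames(psd$power[, idx], psd$channel_labels)
}
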