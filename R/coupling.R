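#' Per-trial channel-wise band-power vector
#'
#' Band power at the target frequency for each channel, averaged over the
#' trial's (1-s) epochs: the per-trial quantity whose across-channel profile
#' is correlated between participants in the coupling analysis.
#'
#' @param epoch_psds non-empty list of `psd_matrix` for the epochs of one
#'   trial of one participant (shared channel set and frequency grid).
#' @param target_frequency Hz.
#' @return named numeric vector, one value per channel.
#' @export
trial_band_power_vector <- function(epoch_psds, target_frequency) {
  if (length(epoch_psds) == 0L) abort("empty epoch list")
  ref <- epoch_psds[[1]]
  for (p in epoch_psds) {
    if (!identical(p$channel_labels, ref$channel_labels) ||
        !isTRUE(all.equal(p$frequencies, ref$frequencies)))
      abort("epochs have mismatched channels or frequency grids")
  }
  vals <- vapply(epoch_psds, band_power, numeric(length(ref$channel_labels)),
                 frequency = target_frequency)
  rowMeans(as.matrix(vals))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    abort("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    abort("degenerate variance: constant input vector")
  stats::cor(x, y)
}

#' Fisher Z transformation and its inverse
#'
#' `z = atanh(r)`, after clamping `|r|` to `1 - 1e-7` so that numerically
#' perfect correlations stay finite; the inverse is `tanh(z)`.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @return Fisher Z value.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) abort("|r| must not exceed 1")
  atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
}

#' @rdname fisher_z
#' @param z Fisher Z value.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Inter-brain coupling analysis for one participant pair
#'
#' For each trial, correlates the two participants' channel-wise band-power
#' vectors at the target frequency (Pearson r), transforms to Fisher Z, and
#' averages the Z values over the m trials. Significance is assessed against
#' the null of no coupling using the normal theory of the Fisher transform:
#' each per-trial z is approximately N(0, 1/(n_channels - 3)), so the mean
#' of m independent trials has standard error `1 / sqrt(m (n_channels - 3))`
#' and the one-sided upper-tail p-value answers whether synchrony exceeds
#' chance.
#'
#' @param participant_a_trials,participant_b_trials lists of trials, each
#'   trial itself a list of `psd_matrix` epochs (same trial count, same
#'   channels).
#' @param target_frequency Hz at which band power is extracted.
#' @param channel_subset optional channel labels to restrict the correlation
#'   to (default: all channels, at least 4 after subsetting).
#' @return a `coupling_result` with per-trial r and z, their mean, the
#'   back-transformed mean correlation, and the p-value.
#' @export
coupling_analysis <- function(participant_a_trials, participant_b_trials,
                              target_frequency, channel_subset = NULL) {
  m <- length(participant_a_trials)
  if (length(participant_b_trials) != m)
    abort("trial-count mismatch: %d vs %d", m, length(participant_b_trials))
  if (m < 2L) abort("need at least 2 trials")
  labels <- participant_a_trials[[1]][[1]]$channel_labels
  if (!identical(labels, participant_b_trials[[1]][[1]]$channel_labels))
    abort("participants have mismatched channel sets")
  keep <- channel_subset %||% labels
  missing <- setdiff(keep, labels)
  if (length(missing))
    abort("channel(s) not present: %s", paste(missing, collapse = ", "))
  nch <- length(keep)
  if (nch < 4L) abort("need at least 4 channels, got %d", nch)

  r <- z <- numeric(m)
  for (i in seq_len(m)) {
    va <- trial_band_power_vector(participant_a_trials[[i]], target_frequency)[keep]
    vb <- trial_band_power_vector(participant_b_trials[[i]], target_frequency)[keep]
    r[i] <- pearson_r(va, vb)
    z[i] <- fisher_z(r[i])
  }
  mean_z <- mean(z)
  se <- 1 / sqrt(m * (nch - 3))
  p <- pnorm(mean_z / se, lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)        # p-value lives in (0, 1]
  ids <- c(participant_a_trials[[1]][[1]]$epoch_info$participant_id %||% "A",
           participant_b_trials[[1]][[1]]$epoch_info$participant_id %||% "B")
  structure(list(participant_pair = ids,
                 target_frequency = target_frequency,
                 per_trial_r = r,
                 per_trial_z = z,
                 mean_z = mean_z,
                 mean_r = tanh(mean_z),
                 p_value = p,
                 n_trials = m,
                 n_channels = nch),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(paste0("<coupling_result> %s vs %s @ %g Hz: mean r = %.3f ",
                     "(mean Z = %.3f over %d trials, %d channels), p = %.3g\n"),
              x$participant_pair[1], x$participant_pair[2],
              x$target_frequency, x$mean_r, x$mean_z, x$n_trials,
              x$n_channels, x$p_value))
  invisible(x)
}

#' Group per-epoch PSDs of one participant into trials
#'
#' Uses the epoch provenance carried by [welch_psd()] to nest a flat list of
#' epoch PSDs into a list of trials (each a list of epoch PSDs), the input
#' shape of [coupling_analysis()].
#'
#' @param psds flat list of `psd_matrix` with `epoch_info`.
#' @return list of trials.
#' @export
group_psds_by_trial <- function(psds) {
  trials <- vapply(psds, function(p) {
    if (is.null(p$epoch_info)) abort("PSD without epoch provenance")
    p$epoch_info$trial_index
  }, integer(1))
  lapply(sort(unique(trials)), function(tr) psds[trials == tr])
}

#' Coupling analysis straight from two recordings
#'
#' Runs the preprocessing chain and per-epoch Welch PSD on both recordings,
#' groups epochs into trials, restricts to trials of the target frequency,
#' and calls [coupling_analysis()].
#'
#' @param recording_a,recording_b annotated recordings of the two
#'   participants (shared trial schedule).
#' @param target_frequency Hz; only trials with this target enter.
#' @param rate,band,epoch_duration preprocessing parameters.
#' @param channel_subset optional channel restriction.
#' @return a `coupling_result`.
#' @export
coupling_from_recordings <- function(recording_a, recording_b,
                                     target_frequency,
                                     rate = 512, band = c(4, 45),
                                     epoch_duration = 1,
                                     channel_subset = NULL) {
  prep <- function(rec) {
    ep <- preprocess_pipeline(rec, rate, band, epoch_duration)
    psds <- lapply(ep, welch_psd)
    tr <- group_psds_by_trial(psds)
    tr[vapply(tr, function(t) t[[1]]$epoch_info$true_frequency,
              numeric(1)) == target_frequency]
  }
  coupling_analysis(prep(recording_a), prep(recording_b),
                    target_frequency, channel_subset)
}
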