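#' Individual SSVEP frequency recognition
#'
#' For each candidate frequency, pools band power as the mean over the
#' occipital channels; the prediction is the candidate with maximal pooled
#' power, with ties broken toward the lowest frequency.
#'
#' @param psd a `psd_matrix` (typically from [welch_psd()] on one epoch).
#' @param occipital_channels channel labels to pool (default O1/O2/Oz).
#' @param candidates candidate target frequencies in Hz.
#' @param true_frequency optional ground-truth frequency; defaults to the
#'   PSD's carried epoch metadata, if any.
#' @return a `decoding_result`.
#' @export
decode_individual <- function(psd,
                              occipital_channels = c("O1", "O2", "Oz"),
                              candidates = c(8, 10, 13),
                              true_frequency = NULL) {
  decode_pooled(list(psd), occipital_channels, candidates,
                true_frequency, mode = "individual")
}

#' Collaborative SSVEP frequency recognition
#'
#' Pools band power as a single grand mean over the stated channels of all
#' participants (channels x participants), then takes the same argmax as
#' [decode_individual()]. With one participant this reduces exactly to
#' individual decoding, and the result is invariant to participant order.
#'
#' @param psds list of `psd_matrix`, one per participant, sharing channel
#'   labels and frequency grid.
#' @inheritParams decode_individual
#' @return a `decoding_result`.
#' @export
decode_collaborative <- function(psds,
                                 occipital_channels = c("O1", "O2", "Oz"),
                                 candidates = c(8, 10, 13),
                                 true_frequency = NULL) {
  decode_pooled(psds, occipital_channels, candidates, true_frequency,
                mode = "collaborative")
}

decode_pooled <- function(psds, occipital_channels, candidates,
                          true_frequency, mode) {
  if (length(psds) < 1L) abort("need at least one participant PSD")
  if (length(candidates) < 1L) abort("candidate list must be non-empty")
  ref <- psds[[1]]
  for (p in psds) {
    if (!identical(p$channel_labels, ref$channel_labels))
      abort("participants have mismatched channel labels")
    if (!isTRUE(all.equal(p$frequencies, ref$frequencies)))
      abort("participants have mismatched frequency grids")
  }
  missing <- setdiff(occipital_channels, ref$channel_labels)
  if (length(missing))
    abort("channel(s) not present in PSD: %s", paste(missing, collapse = ", "))
  ord <- order(candidates)
  cand <- candidates[ord]
  pooled <- vapply(cand, function(f) {
    mean(unlist(lapply(psds, function(p) band_power(p, f)[occipital_channels])))
  }, numeric(1))
  pred <- cand[which.max(pooled)]          # first max = lowest frequency
  tf <- true_frequency %||% ref$epoch_info$true_frequency
  structure(list(epoch_info = ref$epoch_info,
                 candidate_frequencies = cand,
                 pooled_power = stats::setNames(pooled, cand),
                 predicted_frequency = pred,
                 true_frequency = tf,
                 correct = if (is.null(tf)) NA else pred == tf,
                 mode = mode,
                 n_participants = length(psds)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s: predicted %g Hz%s\n", x$mode,
              x$predicted_frequency,
              if (is.null(x$true_frequency)) ""
              else sprintf(" (true %g Hz, %s)", x$true_frequency,
                           if (isTRUE(x$correct)) "correct" else "wrong")))
  invisible(x)
}

#' Recognition accuracy over a set of decoding results
#'
#' @param results non-empty list of `decoding_result` with known truth.
#' @return fraction correct, in `[0, 1]`.
#' @export
recognition_accuracy <- function(results) {
  if (length(results) == 0L) abort("empty result list")
  ok <- vapply(results, function(r) {
    if (is.na(r$correct)) abort("result without ground truth")
    r$correct
  }, logical(1))
  mean(ok)
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean_a - mean_b) / s_pooled`, with the pooled standard deviation
#' weighted by `(n_a - 1, n_b - 1)`. The magnitude label follows the
#' conventional thresholds: |d| > 0.2 small, > 0.5 medium, > 0.8 large.
#'
#' @param group_a,group_b numeric vectors of at least 2 values each.
#' @return an `effect_size` with elements `d` and `magnitude_label`.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) abort("each group needs at least 2 values")
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  dm <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (dm != 0)
      abort("degenerate variance: groups differ but pooled SD is zero")
    d <- 0
  } else d <- dm / sqrt(sp2)
  label <- if (abs(d) > 0.8) "large" else if (abs(d) > 0.5) "medium"
           else if (abs(d) > 0.2) "small" else "none"
  structure(list(d = d, magnitude_label = label), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.4f (%s)\n", x$d, x$magnitude_label))
  invisible(x)
}

#' Decode every epoch of one or more preprocessed participants
#'
#' Convenience wrapper: computes per-epoch PSDs (if given epochs) and runs
#' individual or collaborative decoding per epoch position.
#'
#' @param psds_per_participant list (per participant) of lists of
#'   `psd_matrix` in matching epoch order.
#' @param mode `"individual"` decodes participant 1's epochs alone is not
#'   meaningful for multiple participants, so individual mode returns a list
#'   of result lists (one per participant); `"collaborative"` returns a
#'   single result list pooling all participants.
#' @inheritParams decode_individual
#' @return list of `decoding_result` (collaborative) or list of such lists
#'   (individual).
#' @export
decode_session <- function(psds_per_participant,
                           mode = c("collaborative", "individual"),
                           occipital_channels = c("O1", "O2", "Oz"),
                           candidates = c(8, 10, 13)) {
  mode <- match.arg(mode)
  n_ep <- unique(vapply(psds_per_participant, length, integer(1)))
  if (length(n_ep) != 1L)
    abort("participants have differing epoch counts")
  if (mode == "individual") {
    lapply(psds_per_participant, function(pp)
      lapply(pp, decode_individual, occipital_channels = occipital_channels,
             candidates = candidates))
  } else {
    lapply(seq_len(n_ep), function(i)
      decode_collaborative(lapply(psds_per_participant, `[[`, i),
                           occipital_channels, candidates))
  }
}
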