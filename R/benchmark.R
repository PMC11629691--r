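#' Benchmark decoding regimes: II, CI and CC
#'
#' Simulates seeded sessions and compares recognition accuracy across the
#' three regimes of the offline analysis: individual paradigms with
#' individual decoding (II), collaborative paradigms with individual
#' decoding (CI), and collaborative paradigms with collaborative decoding
#' (CC). Per replicate, CI/CC share one collaborative session (one group
#' recording per participant, common trial schedule) while II uses fresh
#' single-participant sessions. CI accuracy is the mean of the participants'
#' individual accuracies; CC is the accuracy of grand-mean collaborative
#' decoding over the same epochs.
#'
#' @param config an `ssvep_config`; `n_participants >= 2` is required for
#'   CI/CC.
#' @param regimes subset of `c("II", "CI", "CC")`.
#' @param replicates number of seeded replicates (replicate r uses a
#'   sub-seed derived from `config$seed`).
#' @param rate,band,epoch_duration preprocessing parameters.
#' @return an `ssvep_benchmark`: accuracy table (one row per replicate and
#'   regime) plus pairwise effect sizes CC vs CI and CI vs II.
#' @export
run_benchmark <- function(config, regimes = c("II", "CI", "CC"),
                          replicates = 1L, rate = 512, band = c(4, 45),
                          epoch_duration = 1) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  if (any(c("CI", "CC") %in% regimes) && config$n_participants < 2L)
    abort("CI/CC regimes need n_participants >= 2")
  candidates <- config$target_frequencies

  session_psds <- function(rec) {
    lapply(preprocess_pipeline(rec, rate, band, epoch_duration), welch_psd)
  }
  indiv_acc <- function(psds) {
    recognition_accuracy(lapply(psds, decode_individual,
                                candidates = candidates))
  }

  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- mix_seed(config$seed, 97L, r)
    if (any(c("CI", "CC") %in% regimes)) {
      cfg <- config; cfg$seed <- rep_seed
      group <- lapply(generate_group_session(cfg), session_psds)
      if ("CI" %in% regimes)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, regime = "CI",
          accuracy = mean(vapply(group, indiv_acc, numeric(1))))
      if ("CC" %in% regimes) {
        n_ep <- length(group[[1]])
        coll <- lapply(seq_len(n_ep), function(i)
          decode_collaborative(lapply(group, `[[`, i),
                               candidates = candidates))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, regime = "CC",
          accuracy = recognition_accuracy(coll))
      }
    }
    if ("II" %in% regimes) {
      accs <- vapply(seq_len(config$n_participants), function(p) {
        cfg <- config
        cfg$n_participants <- 1L
        cfg$coupling_gain <- 0
        cfg$seed <- mix_seed(rep_seed, 13L, p)
        indiv_acc(session_psds(generate_recording(cfg, 1L)))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, regime = "II", accuracy = mean(accs))
    }
  }
  tab <- do.call(rbind, rows)

  effect <- function(a, b) {
    ga <- tab$accuracy[tab$regime == a]
    gb <- tab$accuracy[tab$regime == b]
    if (!length(ga) || !length(gb) || length(ga) < 2L || length(gb) < 2L)
      return(NULL)
    sp2 <- ((length(ga) - 1) * var(ga) + (length(gb) - 1) * var(gb)) /
      (length(ga) + length(gb) - 2)
    if (sp2 == 0)
      return(structure(list(d = NA_real_, magnitude_label = "degenerate"),
                       class = "effect_size"))
    cohens_d(ga, gb)
  }
  structure(list(table = tab,
                 effect_sizes = list(CC_vs_CI = effect("CC", "CI"),
                                     CI_vs_II = effect("CI", "II")),
                 config = config, replicates = replicates),
            class = "ssvep_benchmark")
}

#' @export
print.ssvep_benchmark <- function(x, ...) {
  cat("<ssvep_benchmark>\n")
  agg <- stats::aggregate(accuracy ~ regime, data = x$table,
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: accuracy %.3f +/- %.3f (n = %d)\n",
                agg$regime[i], agg$accuracy[i, "mean"],
                agg$accuracy[i, "sd"],
                sum(x$table$regime == agg$regime[i])))
  for (nm in names(x$effect_sizes)) {
    es <- x$effect_sizes[[nm]]
    if (!is.null(es))
      cat(sprintf("  Cohen's d %s: %s (%s)\n", sub("_vs_", " vs ", nm),
                  ifelse(is.na(es$d), "NA", sprintf("%.3f", es$d)),
                  es$magnitude_label))
  }
  invisible(x)
}
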