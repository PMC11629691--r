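# Shared fixtures: everything is generated in code at test time.

# Small, fast session config; override any field via ...
quick_cfg <- function(...) {
  defaults <- list(sampling_rate = 512, target_frequencies = c(8, 10, 13),
                   trial_duration = 2, trials_per_target = 1,
                   ssvep_amplitude = 5, noise_amplitude = 0,
                   coupling_gain = 0, n_participants = 1, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# A bare single-tone epoch: `nch` channels all carrying a unit sinusoid.
tone_epoch <- function(freq, fs = 512, n = 512, nch = 4, amplitude = 1,
                       labels = NULL) {
  labels <- labels %||% c("O1", "O2", "Oz", "Pz")[seq_len(nch)]
  t <- (seq_len(n) - 1) / fs
  x <- matrix(rep(amplitude * sin(2 * pi * freq * t), each = nch), nrow = nch)
  new_epoch("test", 1L, 1L, freq, labels, fs, x)
}

# Independent single-periodogram PSD oracle (raw fft arithmetic, no reuse
# of package internals beyond the container constructor).
oracle_psd <- function(x, fs) {
  n <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  nf <- n %/% 2 + 1
  p <- t(apply(x, 1, function(v) {
    v <- v - mean(v)
    sp <- abs(fft(v * w)[1:nf])^2 / (fs * sum(w^2))
    sp[2:(nf - 1)] <- 2 * sp[2:(nf - 1)]
    if (n %% 2 == 1) sp[nf] <- 2 * sp[nf]
    sp
  }))
  list(freq = (0:(nf - 1)) * fs / n, power = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
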