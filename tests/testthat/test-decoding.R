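make_psd <- function(values, labels = c("O1", "O2", "Oz"),
                     freqs = 0:20) {
  # values: channels x freqs matrix of fake PSD entries
  new_psd_matrix(labels, freqs, values)
}

test_that("individual decoding pools occipital power and takes argmax", {
  for (f in c(8, 10, 13)) {
    res <- decode_individual(welch_psd(tone_epoch(f)))
    expect_equal(res$predicted_frequency, f)
    expect_true(res$correct)
    expect_equal(res$mode, "individual")
  }
})

test_that("ties break toward the lowest candidate frequency", {
  flat <- make_psd(matrix(1, 3, 21))
  expect_equal(decode_individual(flat, candidates = c(13, 8, 10),
                                 true_frequency = 8)$predicted_frequency, 8)
  # candidate order must not matter
  expect_equal(decode_individual(flat,
                                 candidates = c(10, 13, 8))$predicted_frequency,
               8)
})

test_that("decoding contracts: missing channels and empty candidates", {
  psd <- make_psd(matrix(1, 3, 21))
  expect_error(decode_individual(psd, occipital_channels = c("O1", "POz")),
               "POz")
  expect_error(decode_individual(psd, candidates = numeric(0)), "non-empty")
})

test_that("collaborative decoding reduces, permutes, and grand-means", {
  set.seed(20)
  psd_a <- welch_psd(matrix(rnorm(3 * 512), 3,
                            dimnames = list(c("O1", "O2", "Oz"), NULL)),
                     sampling_rate = 512)
  psd_b <- welch_psd(matrix(rnorm(3 * 512), 3,
                            dimnames = list(c("O1", "O2", "Oz"), NULL)),
                     sampling_rate = 512)
  solo <- decode_individual(psd_a, true_frequency = 8)
  red <- decode_collaborative(list(psd_a), true_frequency = 8)
  expect_equal(red$pooled_power, solo$pooled_power)
  expect_equal(red$predicted_frequency, solo$predicted_frequency)
  ab <- decode_collaborative(list(psd_a, psd_b))
  ba <- decode_collaborative(list(psd_b, psd_a))
  expect_equal(ab$pooled_power, ba$pooled_power)
  expect_equal(decode_collaborative(list(psd_a, psd_a))$predicted_frequency,
               solo$predicted_frequency)
})

test_that("grand-mean pooling matches a hand-computed arithmetic oracle", {
  # A's noise favors 10 Hz, B's favors 13 Hz, shared 8 Hz signal dominates
  base <- matrix(0.1, 3, 21)
  a <- base; a[, 8 + 1] <- 5; a[, 10 + 1] <- 4
  b <- base; b[, 8 + 1] <- 5; b[, 13 + 1] <- 4
  res <- decode_collaborative(list(make_psd(a), make_psd(b)),
                              candidates = c(8, 10, 13))
  pooled_oracle <- vapply(c(8, 10, 13), function(f)
    mean(c(a[, f + 1], b[, f + 1])), numeric(1))
  expect_equal(unname(res$pooled_power), pooled_oracle)
  expect_equal(res$predicted_frequency, 8)
})

test_that("decoding argmax agrees with a brute-force FFT oracle", {
  set.seed(21)
  for (i in 1:25) {
    f_true <- sample(c(8, 10, 13), 1)
    x <- matrix(rnorm(4 * 512, sd = 4), 4,
                dimnames = list(c("O1", "O2", "Oz", "Pz"), NULL))
    x[1:3, ] <- x[1:3, ] +
      rep(sin(2 * pi * f_true * (0:511) / 512), each = 3)
    ep <- new_epoch("t", 1L, 1L, f_true, rownames(x), 512, x)
    got <- decode_individual(welch_psd(ep))$predicted_frequency
    ref <- oracle_psd(x[1:3, , drop = FALSE], 512)
    cands <- c(8, 10, 13)
    pooled <- vapply(cands, function(f)
      mean(ref$power[, which(ref$freq == f)]), numeric(1))
    expect_equal(got, cands[which.max(pooled)])
  }
})

test_that("recognition_accuracy counts correct predictions", {
  res <- lapply(c(8, 10, 13, 13), function(f)
    decode_individual(welch_psd(tone_epoch(10)), true_frequency = f))
  expect_equal(recognition_accuracy(res), 0.25)
  expect_equal(recognition_accuracy(res[2]), 1.0)
  expect_equal(recognition_accuracy(res[c(1, 3)]), 0.0)
  expect_error(recognition_accuracy(list()), "empty")
})

test_that("cohens_d matches the pooled-SD formula and labels magnitudes", {
  # independent arithmetic oracle
  d_oracle <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  set.seed(22)
  for (i in 1:20) {
    a <- runif(sample(2:10, 1)); b <- runif(sample(2:10, 1))
    expect_equal(cohens_d(a, b)$d, d_oracle(a, b), tolerance = 1e-12)
  }
  es <- cohens_d(c(0.8, 0.9), c(0.6, 0.7))
  expect_equal(es$d, 0.2 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(es$magnitude_label, "large")
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$magnitude_label, "none")
  expect_error(cohens_d(c(1, 1, 1), c(0, 0, 0)), "degenerate")
  expect_error(cohens_d(1, c(0, 0)), "at least 2")
})

test_that("benchmark is reproducible and degenerate on noiseless input", {
  cfg <- quick_cfg(trial_duration = 2, trials_per_target = 1,
                   noise_amplitude = 0, n_participants = 2, seed = 9)
  b1 <- run_benchmark(cfg, replicates = 2)
  b2 <- run_benchmark(cfg, replicates = 2)
  expect_identical(b1$table, b2$table)
  expect_true(all(b1$table$accuracy == 1))
  expect_equal(b1$effect_sizes$CC_vs_CI$magnitude_label, "degenerate")
  expect_error(run_benchmark(quick_cfg(), replicates = 1),
               "n_participants")
})
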