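test_that("pearson_r matches the definitional formula and its contracts", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  # hand-derived: cov = 0.75*4/3, sd products -> r = 3/5
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(30)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), r_oracle, tolerance = 1e-12)
  }
  expect_error(pearson_r(1:4, 1:5), "length mismatch")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "degenerate")
})

test_that("fisher transform round-trips, clamps, and matches atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(inverse_fisher_z(fisher_z(0.5)), 0.5, tolerance = 1e-9)
  for (r in c(-0.999, -0.5, 0.2, 0.77, 0.999))
    expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-6)
  expect_equal(fisher_z(0.77), 0.5 * log(1.77 / 0.23), tolerance = 1e-12)
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "exceed")
})

test_that("trial band-power vectors average epochs per channel", {
  set.seed(31)
  mk <- function() welch_psd(new_epoch("a", 1L, 1L, 8,
                                       c("O1", "O2", "Oz", "Pz"), 512,
                                       matrix(rnorm(4 * 512), 4)))
  p1 <- mk()
  expect_equal(trial_band_power_vector(list(p1), 8), band_power(p1, 8))
  expect_equal(trial_band_power_vector(list(p1, p1), 8), band_power(p1, 8))
  ps <- replicate(10, mk(), simplify = FALSE)
  oracle <- rowMeans(vapply(ps, band_power, numeric(4), frequency = 8))
  expect_equal(trial_band_power_vector(ps, 8), oracle)
  short <- welch_psd(matrix(rnorm(4 * 256), 4,
                            dimnames = list(c("O1", "O2", "Oz", "Pz"), NULL)),
                     sampling_rate = 512)
  expect_error(trial_band_power_vector(list(p1, short), 8), "mismatched")
})

make_trials <- function(m = 3, nch = 6, seed = 1) {
  set.seed(seed)
  labels <- c("O1", "O2", "Oz", "Pz", "Cz", "Fz")[1:nch]
  lapply(seq_len(m), function(i)
    list(welch_psd(new_epoch("x", i, 1L, 8, labels, 512,
                             matrix(rnorm(nch * 512), nch)))))
}

test_that("coupling_analysis handles the perfect-coupling limit", {
  a <- make_trials(m = 3)
  res <- coupling_analysis(a, a, 8)
  expect_true(all(res$per_trial_r > 1 - 1e-6))
  expect_true(all(is.finite(res$per_trial_z)))
  expect_lt(res$p_value, 1e-10)
  expect_gt(res$p_value, 0)
})

test_that("coupling_analysis is symmetric and self-consistent", {
  a <- make_trials(m = 4, seed = 2)
  b <- make_trials(m = 4, seed = 3)
  ab <- coupling_analysis(a, b, 8)
  ba <- coupling_analysis(b, a, 8)
  expect_identical(ab$mean_z, ba$mean_z)
  expect_identical(ab$p_value, ba$p_value)
  expect_equal(ab$per_trial_z, fisher_z(ab$per_trial_r))
  expect_equal(ab$mean_r, tanh(ab$mean_z))
  expect_equal(ab$n_channels, 6)
  # p-value from the documented normal-theory construction
  se <- 1 / sqrt(4 * (6 - 3))
  expect_equal(ab$p_value, pnorm(ab$mean_z / se, lower.tail = FALSE))
})

test_that("coupling_analysis validates trials, channels and subsets", {
  a <- make_trials(m = 4, seed = 4)
  expect_error(coupling_analysis(a, a[1:3], 8), "trial-count")
  expect_error(coupling_analysis(a[1], a[1], 8), "at least 2 trials")
  expect_error(coupling_analysis(a, a, 8,
                                 channel_subset = c("O1", "O2", "Oz")),
               "at least 4 channels")
  expect_error(coupling_analysis(a, a, 8, channel_subset = c("O1", "XX")),
               "XX")
  b <- make_trials(m = 4, nch = 4, seed = 5)
  expect_error(coupling_analysis(a, b, 8), "mismatched channel sets")
})

test_that("coupling rises with the generator's coupling gain", {
  mean_z_at <- function(gain, seed) {
    cfg <- quick_cfg(target_frequencies = 8, trial_duration = 1,
                     trials_per_target = 5, ssvep_amplitude = 0,
                     noise_amplitude = 1, coupling_gain = gain,
                     n_participants = 2, seed = seed)
    grp <- generate_group_session(cfg)
    coupling_from_recordings(grp[[1]], grp[[2]], 8, rate = 512)$mean_z
  }
  z0 <- mean(vapply(1:5, function(s) mean_z_at(0, s), numeric(1)))
  z2 <- mean(vapply(1:5, function(s) mean_z_at(2, s), numeric(1)))
  expect_lt(abs(z0), 0.2)
  expect_gt(z2, 1)
})
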