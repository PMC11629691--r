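test_that("resampling follows the floor rule and preserves tones", {
  cfg <- quick_cfg(sampling_rate = 1000, trial_duration = 2,
                   ssvep_amplitude = 1)
  rec <- generate_recording(cfg)
  out <- resample_recording(rec, 512)
  expect_equal(out$sampling_rate, 512)
  expect_equal(ncol(out$samples), floor(ncol(rec$samples) * 512 / 1000))
  expect_identical(out$annotations, rec$annotations)
  expect_identical(out$channel_labels, rec$channel_labels)
  # a pure on-grid tone survives with amplitude within 1 %
  t10 <- sin(2 * pi * 10 * (0:1999) / 1000)
  r <- new_recording("t", "Oz", 1000, matrix(t10, 1))
  y <- resample_recording(r, 512)$samples[1, ]
  amp_in <- 2 * max(abs(fft(t10))) / length(t10)
  amp_out <- 2 * max(abs(fft(y))) / length(y)
  expect_lt(abs(amp_out - amp_in) / amp_in, 0.01)
  k <- which.max(abs(fft(y))[1:(length(y) / 2)]) - 1
  expect_equal(k * 512 / length(y), 10)   # peak still at 10 Hz
})

test_that("resampling is an identity at equal rates and rejects upsampling", {
  rec <- generate_recording(quick_cfg(noise_amplitude = 1))
  expect_identical(resample_recording(rec, 512), rec)
  expect_error(resample_recording(rec, 1024), "upsampling")
  expect_error(resample_recording(rec, 0), "positive")
})

test_that("band-pass response meets the stated pass/stop attenuations", {
  filt <- butter_bandpass(4, 45, 512, 4)
  # forward-backward application squares the magnitude response
  att_db <- function(f) 20 * log10(abs(freq_response(filt, f, 512))^2)
  for (f in c(8, 10, 13)) expect_gt(att_db(f), -1)
  expect_lt(att_db(0.5), -20)
  expect_lt(att_db(1), -20)
  expect_lt(att_db(60), -20)
  expect_error(butter_bandpass(45, 4, 512), "band edges")
  expect_error(bandpass_recording(generate_recording(quick_cfg()), 4, 300),
               "band edges")
})

test_that("zero-phase filtering preserves in-band tones in the time domain", {
  t <- (0:4095) / 512
  x <- sin(2 * pi * 10 * t)
  rec <- new_recording("t", "Oz", 512, matrix(x, 1))
  y <- bandpass_recording(rec)$samples[1, ]
  mid <- 1000:3000
  expect_lt(max(abs(y[mid] - x[mid])), 0.02)      # no phase shift, < 1 dB
  zero <- bandpass_recording(new_recording("t", "Oz", 512,
                                           matrix(0, 1, 4096)))
  expect_equal(max(abs(zero$samples)), 0)
})

test_that("epoching is exact, inherits truth, and drops remainders", {
  cfg <- quick_cfg(trial_duration = 10, trials_per_target = 1,
                   noise_amplitude = 1, seed = 2)
  rec <- generate_recording(cfg)
  eps <- epoch_segments(rec, 1)
  expect_length(eps, 30)                          # 3 trials x 10 epochs
  expect_equal(ncol(eps[[1]]$samples), 512)
  expect_equal(eps[[1]]$true_frequency, 8)
  expect_equal(eps[[11]]$true_frequency, 10)      # second trial
  # concatenating a trial's epochs reproduces the trial bit-for-bit
  tr1 <- do.call(cbind, lapply(eps[1:10], `[[`, "samples"))
  expect_identical(tr1, rec$samples[, 1:5120])
  # remainder rule: a 1.5-s trial yields one 1-s epoch
  r <- new_recording("t", c("O1", "O2", "Oz"), 512,
                     matrix(rnorm(3 * 768), 3),
                     data.frame(onset = 0, duration = 1.5,
                                label = "target:8"))
  expect_length(epoch_segments(r, 1), 1)
  expect_error(epoch_segments(new_recording("t", "Oz", 512,
                                            matrix(0, 1, 512))),
               "no annotations")
  expect_error(epoch_segments(r, 2), "at least epoch_duration")
})

test_that("epoch counts follow trial arithmetic through the full chain", {
  cfg <- quick_cfg(sampling_rate = 1000, trial_duration = 3,
                   trials_per_target = 2, noise_amplitude = 1, seed = 4)
  eps <- preprocess_pipeline(generate_recording(cfg))
  expect_length(eps, 6 * 3)                       # 6 trials x 3 epochs
  expect_identical(eps[[1]]$channel_labels, cfg$channel_labels)
})
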