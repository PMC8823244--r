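test_that("an up-sweep's instantaneous frequency is monotone within its band", {
  syl <- synth_syllable(0.05, 40000, 80000, "up", amplitude = 1, rate = 250000)
  # phase-derivative oracle on the raw chunk (ignore the amplitude ramps)
  ph <- unwrap_phase(syl$samples)
  inst <- diff(ph) * 250000 / (2 * pi)
  # smooth over 1 ms: per-sample phase estimates are noisy
  sm <- stats::filter(inst, rep(1 / 250, 250), sides = 2)
  core <- sm[2000:10000]
  expect_true(all(core > 39000 & core < 81000))
  expect_true(all(diff(core) > -50))  # monotone rise up to estimator noise
  expect_equal(syl$f_low, 40000)
  expect_equal(syl$f_high, 80000)
})

test_that("degenerate syllable requests are rejected", {
  expect_error(synth_syllable(0, 4e4, 8e4), "duration")
  expect_error(synth_syllable(0.05, 4e4, 1.5e5, rate = 250000), "Nyquist")
})

test_that("a recording with zero calls is pure noise with an empty table", {
  rec <- synth_recording(synth_config(n_calls = 0L, seed = 3))
  expect_equal(nrow(rec$labels), 0L)
  expect_equal(length(rec$wave$samples), 250000L)
})

test_that("the truth table lists exactly the placed syllables, inside bounds", {
  cfg <- synth_config(duration = 2, n_calls = 2,
                      syllables_per_call = c(3L, 3L), seed = 21)
  rec <- synth_recording(cfg)
  expect_equal(nrow(rec$labels), 6L)
  expect_true(all(rec$labels$onset >= 0))
  expect_true(all(rec$labels$offset <= 2))
  expect_true(all(rec$labels$offset > rec$labels$onset))
  # syllables never overlap
  expect_true(all(rec$labels$onset[-1] >= rec$labels$offset[-6]))
  expect_true(all(rec$labels$freq_low_hz >= 30000 - 1))
  expect_true(all(rec$labels$freq_high_hz <= 110000 + 1))
})

test_that("overfull requests error out", {
  cfg <- synth_config(duration = 0.2, n_calls = 3L,
                      syllables_per_call = c(4L, 4L), seed = 1)
  expect_error(synth_recording(cfg), "cannot fit")
})

test_that("the SNR calibration loop hits its target", {
  med <- sapply(1:6, function(i) {
    rec <- synth_recording(synth_config(duration = 1, n_calls = 1,
                                        target_snr = 2, seed = 100 + i))
    stats::median(local_snr(rec$wave, rec$labels)$snr)
  })
  expect_true(all(med >= 1.6 & med <= 2.4))
})

test_that("the same seed reproduces the recording bit for bit", {
  cfg <- synth_config(seed = 77)
  a <- synth_recording(cfg)
  b <- synth_recording(cfg)
  expect_identical(a$wave$samples, b$wave$samples)
  expect_identical(as.data.frame(a$labels), as.data.frame(b$labels))
})

test_that("raising the noise floor lowers the measured local SNR", {
  meds <- sapply(c(0.005, 0.02, 0.08), function(fl) {
    rec <- synth_recording(synth_config(duration = 1, n_calls = 1,
                                        target_snr = NULL, amplitude = 0.1,
                                        noise_floor = fl, seed = 5))
    stats::median(local_snr(rec$wave, rec$labels)$snr)
  })
  expect_true(all(diff(meds) < 0))
})

test_that("labels coincide with band-limited energy in the audio", {
  rec <- synth_recording(synth_config(duration = 1, n_calls = 1,
                                      target_snr = 15, seed = 33))
  # independent oracle: 30-110 kHz Butterworth bandpass + moving RMS
  bf <- signal::butter(4, c(30000, 110000) / 125000, type = "pass")
  y <- signal::filtfilt(bf, rec$wave$samples)
  win <- 1250  # 5 ms
  e <- sqrt(stats::filter(y^2, rep(1 / win, win), sides = 2))
  thr <- 2.5 * stats::median(e, na.rm = TRUE)
  t_axis <- seq_along(e) / 250000
  in_label <- rep(FALSE, length(e))
  for (i in seq_len(nrow(rec$labels)))
    in_label[t_axis > rec$labels$onset[i] & t_axis <= rec$labels$offset[i]] <- TRUE
  hot <- !is.na(e) & e > thr
  # energy is found inside every labeled syllable, and hot samples stay close
  # to labeled spans
  for (i in seq_len(nrow(rec$labels))) {
    span <- t_axis > rec$labels$onset[i] & t_axis <= rec$labels$offset[i]
    expect_gt(mean(hot[span]), 0.5)
  }
  expect_lt(mean(hot[!in_label]), 0.02)
})

test_that("recording-budget arithmetic multiplies out", {
  expect_equal(schedule_hours(list(S = 3, G = 4, P = 3, D = 3, H = 12, M = 10)),
               216)
  expect_equal(schedule_hours(list(S = 3, P = 10, M = 5)), 2.5)
  expect_equal(schedule_hours(rep(1, 6)), 1 / 60)
  expect_error(schedule_hours(list(S = 0, P = 1)), "positive")
})

test_that("USV fraction and noise-pool arithmetic match the printed values", {
  expect_equal(usv_fraction(57, 216), 0.44)
  expect_equal(usv_fraction(0, 5), 0)
  expect_equal(usv_fraction(30, 1), 50)
  expect_error(usv_fraction(10, 0), "total_hours")
  expect_equal(noise_pool_minutes(2600, 1), 2600 / 60)
})
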