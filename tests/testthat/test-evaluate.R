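test_that("magnitude is the mean of squares", {
  expect_equal(magnitude(c(1, -1, 1, -1)), 1)
  expect_equal(magnitude(rep(0, 100)), 0)
  set.seed(61)
  x <- rnorm(500)
  expect_equal(magnitude(x), sum(x^2) / length(x), tolerance = 1e-14)
  expect_error(magnitude(numeric()), "empty")
})

test_that("local SNR follows (M_sig - M_bg) / M_bg", {
  rate <- 10000
  # flat unit-amplitude square wave everywhere: signal equals surroundings
  w <- waveform(rep(c(1, -1), rate / 2), rate)
  tab <- label_table(0.4, 0.6, "USV")
  s <- local_snr(w, tab)
  expect_equal(s$snr, 0, tolerance = 1e-9)
  # signal span has 3x the background power
  x <- rep(c(1, -1), rate / 2)
  span <- (0.4 * rate + 1):(0.6 * rate)
  x[span] <- x[span] * sqrt(3)
  s3 <- local_snr(waveform(x, rate), tab)
  expect_equal(s3$snr, 2, tolerance = 1e-9)
})

test_that("local SNR is invariant to global amplitude scaling", {
  set.seed(62)
  rec <- synth_recording(synth_config(duration = 1, n_calls = 1, seed = 8))
  s1 <- local_snr(rec$wave, rec$labels)$snr
  s2 <- local_snr(waveform(rec$wave$samples * 7.3, rec$wave$rate),
                  rec$labels)$snr
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("zero-power background flags the ratio as undefined", {
  w <- waveform(c(rep(0, 400), rep(1, 200), rep(0, 400)), 1000)
  tab <- label_table(0.4, 0.6, "USV")
  s <- local_snr(w, tab)
  expect_true(s$flagged)
  expect_true(is.na(s$snr))
})

test_that("global SNR pools samples and degenerates sensibly", {
  rate <- 10000
  w <- waveform(rep(c(1, -1), rate / 2), rate)
  expect_true(is.na(global_snr(w, label_table())))
  expect_equal(global_snr(w, label_table(0.2, 0.5, "USV")), 0,
               tolerance = 1e-9)
  # with a single USV and pure flanks, global equals local
  set.seed(63)
  rec <- synth_recording(synth_config(duration = 1, n_calls = 1,
                                      syllables_per_call = c(1L, 1L),
                                      seed = 12))
  g <- global_snr(rec$wave, rec$labels)
  l <- local_snr(rec$wave, rec$labels)$snr
  expect_equal(g, l, tolerance = 0.05)
})

test_that("matching implements the USV/Partial/Multi taxonomy", {
  truth <- label_table(c(1, 2, 3), c(1.1, 2.1, 3.1), "USV")
  # exact one-to-one
  m <- match_detections(data.frame(onset = c(1, 2, 3),
                                   offset = c(1.1, 2.1, 3.1)), truth)
  expect_true(all(m$category == "USV"))
  # two detections on one truth: USV then Partial, tp = 1
  m2 <- match_detections(data.frame(onset = c(1.0, 1.05),
                                    offset = c(1.04, 1.1)),
                         label_table(1, 1.1, "USV"))
  expect_equal(sort(m2$category), c("Partial", "USV"))
  expect_equal(metrics(m2)$tp, 1L)
  # one detection spanning two truths: Multi, counted once, no misses
  m3 <- match_detections(data.frame(onset = 0.9, offset = 3.2), truth)
  expect_equal(m3$category, "Multi")
  rep3 <- metrics(m3)
  expect_equal(rep3$tp, 1L)
  expect_equal(rep3$fn, 0L)
  # false positive and miss
  m4 <- match_detections(data.frame(onset = 5, offset = 5.1), truth)
  expect_equal(sort(unique(m4$category)), c("FalsePositive", "Missed"))
  expect_equal(metrics(m4)$fn, 3L)
})

test_that("detections overlapping only alarm calls are set aside", {
  truth <- label_table(c(1, 2), c(1.1, 2.1), c("USV", "AC"))
  m <- match_detections(data.frame(onset = c(1, 2), offset = c(1.1, 2.1)),
                        truth)
  expect_equal(sort(m$category), c("AC", "USV"))
  rep_ <- metrics(m)
  expect_equal(rep_$tp, 1L)
  expect_equal(rep_$fp, 0L)
})

test_that("metric formulas and conventions hold", {
  fake <- function(tp, fp, fn) {
    data.frame(category = c(rep("USV", tp), rep("FalsePositive", fp),
                            rep("Missed", fn)))
  }
  r <- metrics(fake(8, 2, 2))
  expect_equal(r$recall, 0.8)
  expect_equal(r$precision, 0.8)
  expect_equal(r$f1, 0.8)
  r2 <- metrics(fake(5, 0, 0))
  expect_equal(c(r2$recall, r2$precision, r2$f1), c(1, 1, 1))
  r3 <- metrics(fake(0, 3, 4))
  expect_equal(c(r3$recall, r3$precision, r3$f1), c(0, 0, 0))
  r4 <- metrics(fake(0, 0, 0))
  expect_true(r4$flagged)
})

test_that("partial detections can optionally be penalized", {
  m <- match_detections(data.frame(onset = c(1.0, 1.05), offset = c(1.04, 1.1)),
                        label_table(1, 1.1, "USV"))
  expect_equal(metrics(m)$fp, 0L)
  expect_equal(metrics(m, partial_as_fp = TRUE)$fp, 1L)
})

test_that("F1 lies between precision and recall and equals them when equal", {
  set.seed(64)
  for (i in 1:25) {
    tp <- sample(0:6, 1); fp <- sample(0:4, 1); fn <- sample(0:4, 1)
    if (tp + fn == 0 || tp + fp == 0) next
    m <- data.frame(category = c(rep("USV", tp), rep("FalsePositive", fp),
                                 rep("Missed", fn)))
    r <- metrics(m)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    if (r$precision == r$recall) expect_equal(r$f1, r$precision)
  }
})

test_that("SNR-stratified recall bins truths by their local SNR", {
  set.seed(65)
  rec <- synth_recording(synth_config(duration = 2, n_calls = 3,
                                      target_snr = 2, seed = 19))
  det <- as.data.frame(rec$labels)[, c("onset", "offset")]
  rep_ <- metrics_by_snr(det, rec$labels, rec$wave,
                         breaks = c(0, 1, 5, Inf))
  expect_equal(sum(rep_$n_truth), nrow(rec$labels))
  expect_true(all(rep_$tp[rep_$n_truth > 0] == rep_$n_truth[rep_$n_truth > 0]))
})
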