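test_that("threshold runs become intervals with exact frame spans", {
  fr <- 332
  expect_equal(nrow(track_to_detections(rep(0, 50), frame_rate = fr)), 0L)
  det <- track_to_detections(c(0, 1, 1, 1, 0), threshold = 0.5,
                             min_dur = 0, merge_gap = 0, frame_rate = fr)
  expect_equal(nrow(det), 1L)
  expect_equal(det$onset, 1 / fr)
  expect_equal(det$offset - det$onset, 3 / fr)
  expect_equal(det$score, 1)
  expect_error(track_to_detections(rep(0.6, 5), threshold = 1.2,
                                   frame_rate = fr), "threshold")
})

test_that("detection extraction matches a brute-force run/merge/drop oracle", {
  # independent oracle: explicit frame walk, then interval merge and filter
  oracle <- function(p, thr, min_dur, gap, fr) {
    iv <- NULL; start <- NA
    for (t in seq_along(p)) {
      if (p[t] >= thr && is.na(start)) start <- t
      if ((p[t] < thr || t == length(p)) && !is.na(start)) {
        end <- if (p[t] < thr) t - 1 else t
        iv <- rbind(iv, c(start, end)); start <- NA
      }
    }
    if (is.null(iv)) return(data.frame(onset = numeric(), offset = numeric()))
    out <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      if ((iv[i, 1] - 1 - out[nrow(out), 2]) / fr < gap)
        out[nrow(out), 2] <- iv[i, 2]
      else out <- rbind(out, iv[i, ])
    }
    res <- data.frame(onset = (out[, 1] - 1) / fr, offset = out[, 2] / fr)
    res[res$offset - res$onset >= min_dur, , drop = FALSE]
  }
  set.seed(51)
  fr <- 331.565
  for (rep in 1:20) {
    p <- runif(60)
    got <- track_to_detections(p, 0.5, min_dur = 0.006, merge_gap = 0.008,
                               frame_rate = fr)
    want <- oracle(p, 0.5, 0.006, 0.008, fr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset, want$onset, tolerance = 1e-12)
      expect_equal(got$offset, want$offset, tolerance = 1e-12)
    }
  }
})

test_that("raising the threshold never increases total detected duration", {
  set.seed(52)
  fr <- 331.565
  for (rep in 1:10) {
    p <- runif(100)
    total <- sapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
      d <- track_to_detections(p, thr, min_dur = 0.005, merge_gap = 0.01,
                               frame_rate = fr)
      if (nrow(d)) sum(d$offset - d$onset) else 0
    })
    expect_true(all(diff(total) <= 1e-12))
  }
})

test_that("detections are disjoint and sorted", {
  set.seed(53)
  p <- runif(200)
  d <- track_to_detections(p, 0.5, min_dur = 0, merge_gap = 0.01,
                           frame_rate = 331.565)
  if (nrow(d) > 1) {
    expect_true(all(diff(d$onset) > 0))
    expect_true(all(d$onset[-1] >= d$offset[-nrow(d)]))
  }
})

test_that("frequency bounds come from band edges of active mask rows", {
  fr <- 331.565
  set.seed(54)
  ms <- melspec(waveform(rnorm(25000, 0, 0.01), 250000))
  nb <- 124L; nf <- ncol(ms$values)
  iv <- c(0.01, 0.05)
  full <- matrix(1, nb, nf)
  b <- freq_bounds(full, iv, fr, ms$band_lo, ms$band_hi)
  expect_equal(unname(b), c(ms$band_lo[1], ms$band_hi[nb]))
  one <- matrix(0, nb, nf); one[37, ] <- 1
  b1 <- freq_bounds(one, iv, fr, ms$band_lo, ms$band_hi)
  expect_equal(unname(b1), c(ms$band_lo[37], ms$band_hi[37]))
  none <- matrix(0, nb, nf)
  b0 <- freq_bounds(none, iv, fr, ms$band_lo, ms$band_hi)
  expect_true(all(is.na(b0)))
})

test_that("denoising is exactly the triple elementwise product", {
  set.seed(55)
  s <- matrix(abs(rnorm(30 * 12)), 30, 12)
  m <- matrix(runif(30 * 12), 30, 12)
  p <- runif(12)
  out <- denoise(s, m, p)
  expect_equal(out, s * m * matrix(rep(p, each = 30), 30, 12),
               tolerance = 1e-15)
  expect_equal(denoise(s, matrix(1, 30, 12), rep(1, 12)), s)
  expect_true(all(denoise(s, m, rep(0, 12)) == 0))
  expect_true(all(out <= s + 1e-15))
  expect_error(denoise(s, m[1:10, ], p), "shapes")
  expect_error(denoise(s, m, p[1:5]), "track length")
})

test_that("label round trip through frames recovers intervals within one frame", {
  fr <- 331.565
  set.seed(56)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    on <- sort(runif(n, 0, 2.5))
    off <- on + runif(n, 0.01, 0.08)
    # greedily keep intervals separated by > 2.5 frame periods so runs of
    # 1-frames stay distinct
    keep_on <- on[1]; keep_off <- off[1]
    for (i in seq_len(n)[-1]) {
      if (on[i] > keep_off[length(keep_off)] + 2.5 / fr) {
        keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i])
      }
    }
    tab <- label_table(keep_on, keep_off, "USV")
    nf <- 1000L
    y <- labels_to_frames(tab, fr, nf)
    det <- track_to_detections(as.numeric(y), 0.5, min_dur = 0,
                               merge_gap = 0, frame_rate = fr)
    expect_equal(nrow(det), nrow(tab))
    expect_true(all(abs(det$onset - tab$onset) <= 1 / fr + 1e-12))
    expect_true(all(abs(det$offset - tab$offset) <= 1 / fr + 1e-12))
  }
})
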