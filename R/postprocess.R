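#' Convert a probability track to detected intervals
#'
#' Maximal runs of frames with `P(USV) >= threshold` become candidate
#' intervals (frame `t`, 0-based, spans `[t, t+1) / frame_rate`); intervals
#' separated by less than `merge_gap` seconds are merged; merged intervals
#' shorter than `min_dur` are dropped. Each detection's score is the mean
#' track probability over its frames.
#'
#' @param track A `usv_track` (or numeric vector with `frame_rate` given).
#' @param threshold Detection threshold in (0, 1), default 0.5.
#' @param min_dur Minimum duration in seconds (default 0.005; well below the
#'   ~50 ms median mouse call).
#' @param merge_gap Gaps shorter than this (seconds) are bridged (default
#'   0.010).
#' @param frame_rate Frames per second; taken from the track when absent.
#' @return Data frame with columns `onset`, `offset`, `label` (`"USV"`) and
#'   `score`; zero rows when nothing crosses the threshold.
#' @export
track_to_detections <- function(track, threshold = 0.5, min_dur = 0.005,
                                merge_gap = 0.010, frame_rate = NULL) {
  p <- if (inherits(track, "usv_track")) track$values else track
  if (is.null(frame_rate) && inherits(track, "usv_track"))
    frame_rate <- track$frame_rate
  if (is.null(frame_rate)) stop("frame_rate is required", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  hit <- p >= threshold
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      label = character(), score = numeric())
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])  # 1-based frame indices
  # merge runs separated by < merge_gap
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs[i, 1] - 1L - merged[nrow(merged), 2]) / frame_rate
      if (gap < merge_gap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  onset <- (runs[, 1] - 1L) / frame_rate
  offset <- runs[, 2] / frame_rate
  keep <- (offset - onset) >= min_dur
  if (!any(keep)) return(empty)
  runs <- runs[keep, , drop = FALSE]
  onset <- onset[keep]; offset <- offset[keep]
  score <- vapply(seq_len(nrow(runs)),
                  function(i) mean(p[runs[i, 1]:runs[i, 2]]), 1)
  data.frame(onset = onset, offset = offset, label = "USV", score = score)
}

#' Frequency boundaries of a detection from the mask
#'
#' Within the detection's frames, a band is active when its mean mask value
#' reaches `mask_threshold`. The bounds are the lower edge of the lowest
#' active band and the upper edge of the highest, in Hz. When no band is
#' active both bounds are `NA` (the detection itself is kept).
#'
#' @param mask Bands x frames mask matrix in \[0, 1].
#' @param interval `c(onset, offset)` in seconds (or a one-row detection
#'   data frame).
#' @param frame_rate Frames per second of the mask columns.
#' @param band_lo,band_hi Per-band lower/upper edge frequencies in Hz (from
#'   a `usv_melspec`).
#' @param mask_threshold Activity threshold, default 0.5.
#' @return Named numeric `c(freq_low_hz, freq_high_hz)`.
#' @export
freq_bounds <- function(mask, interval, frame_rate, band_lo, band_hi,
                        mask_threshold = 0.5) {
  if (is.data.frame(interval)) interval <- c(interval$onset[1], interval$offset[1])
  t0 <- max(0L, floor(interval[1] * frame_rate))
  t1 <- min(ncol(mask) - 1L, ceiling(interval[2] * frame_rate) - 1L)
  if (t1 < t0) return(c(freq_low_hz = NA_real_, freq_high_hz = NA_real_))
  m <- rowMeans(mask[, (t0 + 1L):(t1 + 1L), drop = FALSE])
  act <- which(m >= mask_threshold)
  if (!length(act)) return(c(freq_low_hz = NA_real_, freq_high_hz = NA_real_))
  c(freq_low_hz = band_lo[min(act)], freq_high_hz = band_hi[max(act)])
}

#' Mask-and-track denoising of a spectrogram
#'
#' The cleaned spectrogram is the elementwise product of the spectrogram,
#' the frequency mask, and the per-frame probability track broadcast across
#' frequency — nothing else. Because mask and track are in \[0, 1], no
#' magnitude ever increases. Apply it to a linear-power view (see
#' [mel_power()]) to extract clean syllables.
#'
#' @param spectrogram Bands x frames numeric matrix.
#' @param mask Matrix of the same shape, values in \[0, 1].
#' @param track A `usv_track` or numeric vector of length `ncol(spectrogram)`.
#' @return The denoised matrix.
#' @export
denoise <- function(spectrogram, mask, track) {
  p <- if (inherits(track, "usv_track")) track$values else track
  if (!all(dim(spectrogram) == dim(mask)))
    stop("spectrogram and mask shapes differ", call. = FALSE)
  if (length(p) != ncol(spectrogram))
    stop("track length must equal the number of frames", call. = FALSE)
  spectrogram * mask * rep(p, each = nrow(spectrogram))
}

#' Detect USVs in a waveform
#'
#' End-to-end convenience: feature extraction, model prediction, interval
#' extraction and per-detection frequency bounds.
#'
#' @param wave A [waveform()].
#' @param model A `usv_model`.
#' @param feature_cfg A [feature_config()].
#' @param threshold,min_dur,merge_gap See [track_to_detections()].
#' @param mask_threshold See [freq_bounds()].
#' @param segment_frames Segment length for the recurrent stage.
#' @return List with `detections` (data frame: onset, offset, label, score,
#'   freq_low_hz, freq_high_hz), `track`, `mask` and `melspec`.
#' @export
detect_usv <- function(wave, model, feature_cfg = feature_config(),
                       threshold = 0.5, min_dur = 0.005, merge_gap = 0.010,
                       mask_threshold = 0.5, segment_frames = 332L) {
  ms <- melspec(wave, feature_cfg)
  pred <- predict(model, ms, segment_frames = segment_frames)
  det <- track_to_detections(pred$track, threshold, min_dur, merge_gap)
  if (nrow(det)) {
    fb <- t(vapply(seq_len(nrow(det)), function(i)
      freq_bounds(pred$mask, c(det$onset[i], det$offset[i]), ms$frame_rate,
                  ms$band_lo, ms$band_hi, mask_threshold), numeric(2)))
    det$freq_low_hz <- fb[, 1]
    det$freq_high_hz <- fb[, 2]
  } else {
    det$freq_low_hz <- numeric()
    det$freq_high_hz <- numeric()
  }
  list(detections = det, track = pred$track, mask = pred$mask, melspec = ms)
}
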