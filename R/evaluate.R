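#' Magnitude of an audio segment
#'
#' The mean of the squared raw sample values. This is the quantity both SNR
#' definitions are built from.
#'
#' @param segment Numeric vector of samples (non-empty).
#' @return Mean of squares.
#' @export
magnitude <- function(segment) {
  if (length(segment) == 0L) stop("segment is empty", call. = FALSE)
  mean(segment^2)
}

seconds_to_span <- function(t0, t1, rate, n) {
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(n, ceiling(t1 * rate))
  if (i1 < i0) integer() else i0:i1
}

#' Local signal-to-noise ratio of each USV
#'
#' For USV `i`, `R_i = (M_sig+bg,i - M_bg,i) / M_bg,i`, where `M_sig+bg,i`
#' is the magnitude of the audio spanning the USV and `M_bg,i` the mean of
#' the magnitudes of the background stretches immediately before and after
#' it (stretches belonging to other annotated events are excluded). `R_i`
#' is 0 exactly when the call segment has the same magnitude as its
#' surroundings. Undefined values (`M_bg = 0`, or no flanking background)
#' are returned as `NA` and flagged.
#'
#' @param wave A [waveform()].
#' @param table A `usv_labels` truth table.
#' @return Data frame with one row per USV: `onset`, `offset`, `m_sig_bg`,
#'   `m_bg`, `snr`, `flagged`.
#' @export
local_snr <- function(wave, table) {
  usv <- merge_label_intervals(table, "USV")
  out <- data.frame(onset = numeric(), offset = numeric(),
                    m_sig_bg = numeric(), m_bg = numeric(), snr = numeric(),
                    flagged = logical())
  if (nrow(usv) == 0L) return(out)
  # background must exclude every annotated event, whatever the label
  occupied <- as.data.frame(table)
  occ <- occupied[order(occupied$onset), c("onset", "offset"), drop = FALSE]
  n <- length(wave$samples)
  dur <- n / wave$rate
  for (i in seq_len(nrow(usv))) {
    a <- usv[i, 1]; b <- usv[i, 2]
    prev_end <- c(0, occ$offset[occ$offset <= a])
    prev_end <- max(prev_end)
    next_start <- c(dur, occ$onset[occ$onset >= b])
    next_start <- min(next_start)
    sig <- seconds_to_span(a, b, wave$rate, n)
    pre <- seconds_to_span(prev_end, a, wave$rate, n)
    post <- seconds_to_span(b, next_start, wave$rate, n)
    pre <- setdiff(pre, sig); post <- setdiff(post, sig)
    m_sig <- if (length(sig)) magnitude(wave$samples[sig]) else NA_real_
    mags <- c(if (length(pre)) magnitude(wave$samples[pre]),
              if (length(post)) magnitude(wave$samples[post]))
    m_bg <- if (length(mags)) mean(mags) else NA_real_
    flagged <- is.na(m_sig) || is.na(m_bg) || m_bg == 0
    snr <- if (flagged) NA_real_ else (m_sig - m_bg) / m_bg
    out <- rbind(out, data.frame(onset = a, offset = b, m_sig_bg = m_sig,
                                 m_bg = m_bg, snr = snr, flagged = flagged))
  }
  out
}

#' Global signal-to-noise ratio of a recording
#'
#' Pools all USV-containing samples against all remaining samples (samples
#' under other annotated events are excluded from the background pool) and
#' applies the same ratio as [local_snr()]. `NA` when there are no USVs or
#' the background magnitude is zero.
#'
#' @param wave A [waveform()].
#' @param table A `usv_labels` truth table.
#' @return A single number (possibly `NA`).
#' @export
global_snr <- function(wave, table) {
  usv <- merge_label_intervals(table, "USV")
  if (nrow(usv) == 0L) return(NA_real_)
  n <- length(wave$samples)
  in_usv <- logical(n)
  for (i in seq_len(nrow(usv)))
    in_usv[seconds_to_span(usv[i, 1], usv[i, 2], wave$rate, n)] <- TRUE
  excluded <- logical(n)
  other <- as.data.frame(table)
  other <- other[other$label != "USV", , drop = FALSE]
  for (i in seq_len(nrow(other)))
    excluded[seconds_to_span(other$onset[i], other$offset[i], wave$rate, n)] <- TRUE
  bg <- !in_usv & !excluded
  if (!any(in_usv) || !any(bg)) return(NA_real_)
  m_sig <- magnitude(wave$samples[in_usv])
  m_bg <- magnitude(wave$samples[bg])
  if (m_bg == 0) return(NA_real_)
  (m_sig - m_bg) / m_bg
}

overlap_len <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Match detections against a truth table
#'
#' Greedy chronological matching with the four-way taxonomy: the first
#' detection overlapping a truth USV is a true positive (`USV`); later
#' detections overlapping only already-found truths are `Partial`
#' (re-taggings, counted once); one detection overlapping two or more
#' not-yet-found truths is `Multi` (one true positive, the extra covered
#' truths are consumed but not double-counted); detections overlapping no
#' truth are `FalsePositive`; truths never overlapped are `Missed`.
#' Alarm-call (`AC`) truths are excluded before matching, and detections
#' that overlap only AC events are set aside (category `AC`, ignored by
#' [metrics()]).
#'
#' @param detections Data frame with `onset`/`offset` columns (seconds).
#' @param truth A `usv_labels` truth table.
#' @param min_overlap Minimum temporal intersection-over-union required to
#'   count an overlap; 0 (default) means any nonzero intersection.
#' @return Data frame of class `usv_matches`: one row per detection and per
#'   missed truth, with columns `category`, `det_onset`, `det_offset`,
#'   `truth_onset`, `truth_offset`.
#' @export
match_detections <- function(detections, truth, min_overlap = 0) {
  usv <- merge_label_intervals(truth, "USV")
  ac <- as.data.frame(truth)
  ac <- ac[ac$label == "AC", , drop = FALSE]
  det <- as.data.frame(detections)
  det <- det[order(det$onset), , drop = FALSE]
  found <- rep(FALSE, nrow(usv))
  rows <- list()
  overlaps_enough <- function(d0, d1, t0, t1) {
    inter <- overlap_len(d0, d1, t0, t1)
    if (inter <= 0) return(FALSE)
    if (min_overlap <= 0) return(TRUE)
    iou <- inter / (max(d1, t1) - min(d0, t0))
    iou >= min_overlap
  }
  for (i in seq_len(nrow(det))) {
    d0 <- det$onset[i]; d1 <- det$offset[i]
    hit <- if (nrow(usv)) which(vapply(seq_len(nrow(usv)), function(j)
      overlaps_enough(d0, d1, usv[j, 1], usv[j, 2]), TRUE)) else integer()
    if (!length(hit)) {
      on_ac <- nrow(ac) > 0 &&
        any(overlap_len(d0, d1, ac$onset, ac$offset) > 0)
      cat_i <- if (on_ac) "AC" else "FalsePositive"
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_i, det_onset = d0, det_offset = d1,
        truth_onset = NA_real_, truth_offset = NA_real_)
      next
    }
    new_hits <- hit[!found[hit]]
    cat_i <- if (!length(new_hits)) "Partial"
             else if (length(new_hits) >= 2L) "Multi" else "USV"
    found[new_hits] <- TRUE
    anchor <- if (length(new_hits)) new_hits[1] else hit[1]
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat_i, det_onset = d0, det_offset = d1,
      truth_onset = usv[anchor, 1], truth_offset = usv[anchor, 2])
  }
  for (j in which(!found)) {
    rows[[length(rows) + 1L]] <- data.frame(
      category = "Missed", det_onset = NA_real_, det_offset = NA_real_,
      truth_onset = usv[j, 1], truth_offset = usv[j, 2])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), det_onset = numeric(),
               det_offset = numeric(), truth_onset = numeric(),
               truth_offset = numeric())
  class(out) <- c("usv_matches", "data.frame")
  out
}

#' Recall, precision and F1 from a match table
#'
#' `TP` = correctly identified USVs (`USV` and `Multi` rows, each counted
#' once), `FP` = detections of noise (`FalsePositive` rows, plus `Partial`
#' rows when `partial_as_fp`), `FN` = `Missed` rows. Then
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)` and F1 is their
#' harmonic mean. Undefined ratios are `NA` and flagged; F1 is reported as 0
#' when precision + recall is 0.
#'
#' @param matches A `usv_matches` data frame.
#' @param partial_as_fp Count `Partial` re-taggings as false positives
#'   (default `FALSE`: they re-tag an already-found truth and earn neither
#'   credit nor penalty).
#' @return A list of class `usv_metrics`: `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `f1`, `flagged`.
#' @export
metrics <- function(matches, partial_as_fp = FALSE) {
  cat_ <- matches$category
  tp <- sum(cat_ %in% c("USV", "Multi"))
  fp <- sum(cat_ == "FalsePositive") +
    if (partial_as_fp) sum(cat_ == "Partial") else 0L
  fn <- sum(cat_ == "Missed")
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  pr <- c(precision, recall)
  f1 <- if (any(is.na(pr))) {
    if (isTRUE(tp == 0)) 0 else NA_real_
  } else if (sum(pr) == 0) 0 else 2 * prod(pr) / sum(pr)
  structure(list(tp = tp, fp = fp, fn = fn, recall = recall,
                 precision = precision, f1 = f1,
                 flagged = is.na(recall) || is.na(precision)),
            class = "usv_metrics")
}

#' @export
print.usv_metrics <- function(x, ...) {
  cat(sprintf("<usv_metrics> TP %d FP %d FN %d | recall %.3f precision %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$recall, x$precision, x$f1))
  invisible(x)
}

#' Detection metrics stratified by local SNR
#'
#' Computes each truth USV's local SNR, bins the truths, and reports
#' recall/precision/F1 within each bin (detections are assigned to the bin
#' of the truth they match; false positives are pooled over all bins, so
#' per-bin precision is conservative at low SNR).
#'
#' @param detections Detection data frame.
#' @param truth A `usv_labels` truth table.
#' @param wave The recording [waveform()].
#' @param breaks SNR bin edges passed to [cut()].
#' @return Data frame with one row per bin: `bin`, `n_truth`, `tp`, `fn`,
#'   `recall`.
#' @export
metrics_by_snr <- function(detections, truth, wave,
                           breaks = c(0, 0.5, 1, 2, 5, Inf)) {
  snr <- local_snr(wave, truth)
  det <- as.data.frame(detections)
  bins <- cut(snr$snr, breaks = breaks, include.lowest = TRUE)
  res <- NULL
  for (b in levels(bins)) {
    rows <- snr[which(bins == b), , drop = FALSE]
    if (!nrow(rows)) {
      res <- rbind(res, data.frame(bin = b, n_truth = 0L, tp = 0L, fn = 0L,
                                   recall = NA_real_))
      next
    }
    tp <- fn <- 0L
    for (i in seq_len(nrow(rows))) {
      hit <- nrow(det) > 0 &&
        any(overlap_len(det$onset, det$offset, rows$onset[i], rows$offset[i]) > 0)
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    }
    res <- rbind(res, data.frame(bin = b, n_truth = nrow(rows), tp = tp,
                                 fn = fn,
                                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_))
  }
  res
}
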