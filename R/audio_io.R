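#' Construct a waveform object
#'
#' A waveform is the package's basic audio container: a numeric vector of
#' amplitude samples plus a sampling rate in Hz. Recordings aimed at the
#' detector are expected at 250 kHz so that the 1-125 kHz analysis band
#' is below the Nyquist frequency.
#'
#' @param samples Numeric vector of amplitudes. Must be finite and non-empty.
#' @param rate Sampling rate in Hz (positive).
#' @return An object of class `usv_waveform` with elements `samples` and
#'   `rate`.
#' @export
waveform <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples must all be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "usv_waveform")
}

#' @export
print.usv_waveform <- function(x, ...) {
  cat(sprintf("<usv_waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave A `usv_waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$rate

# ---------------------------------------------------------------------------
# WAV container. Minimal RIFF/WAVE reader/writer: PCM 8/16/24/32-bit integer
# and IEEE float 32/64, any channel count (reduced to mono by averaging).
# ---------------------------------------------------------------------------

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (integer PCM or IEEE float), averages channels to
#' mono, and resamples to `target_rate` when the file rate differs
#' (polyphase resampling via [signal::resample()]). Integer PCM samples are
#' scaled to \[-1, 1].
#'
#' @param path Path to a WAV file.
#' @param target_rate Desired sampling rate in Hz; default 250000. Use `NULL`
#'   to keep the file's native rate.
#' @return A [waveform()].
#' @export
read_wav <- function(path, target_rate = 250000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        tag = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      if (fmt$tag == 65534L && size >= 40L) {
        # WAVE_FORMAT_EXTENSIBLE: actual format in first 2 bytes of the GUID
        fmt$tag <- readBin(body[25:26], "integer", 1, 2, signed = FALSE,
                           endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path, call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("WAV file has no audio data: ", path, call. = FALSE)

  x <- decode_wav_samples(data_raw, fmt)
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  if (length(x) == 0L) stop("WAV file contains zero samples: ", path, call. = FALSE)
  w <- waveform(x, fmt$rate)
  if (!is.null(target_rate) && fmt$rate != target_rate)
    w <- resample_wave(w, target_rate)
  w
}

decode_wav_samples <- function(raw, fmt) {
  bits <- fmt$bits
  if (fmt$tag == 1L) {  # integer PCM
    if (bits == 8L) {
      as.numeric(readBin(raw, "integer", length(raw), 1, signed = FALSE)) / 127.5 - 1
    } else if (bits == 16L) {
      readBin(raw, "integer", length(raw) %/% 2L, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (bits == 24L) {
      n <- length(raw) %/% 3L
      b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (bits == 32L) {
      readBin(raw, "integer", length(raw) %/% 4L, 4, signed = TRUE,
              endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", bits, call. = FALSE)
  } else if (fmt$tag == 3L) {  # IEEE float
    if (bits == 32L) {
      readBin(raw, "double", length(raw) %/% 4L, 4, endian = "little")
    } else if (bits == 64L) {
      readBin(raw, "double", length(raw) %/% 8L, 8, endian = "little")
    } else stop("unsupported float bit depth: ", bits, call. = FALSE)
  } else stop("unsupported WAV format tag: ", fmt$tag, call. = FALSE)
}

#' Write a waveform to a WAV file
#'
#' @param wave A [waveform()].
#' @param path Output path.
#' @param bits Either 32 (IEEE float, default; lossless for this package's
#'   pipelines) or 16 (integer PCM, samples clipped to \[-1, 1]).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 32) {
  stopifnot(inherits(wave, "usv_waveform"))
  x <- wave$samples
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  tag <- if (bits == 32) 3L else 1L
  writeBin(tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                     # mono
  writeBin(as.integer(wave$rate), con, 4, endian = "little")
  writeBin(as.integer(wave$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, 4, endian = "little")
  } else if (bits == 16) {
    v <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    writeBin(v, con, 2, endian = "little")
  } else stop("bits must be 16 or 32", call. = FALSE)
  invisible(path)
}

#' Resample a waveform
#'
#' Rational-factor polyphase resampling via [signal::resample()]. The output
#' length is chosen so the duration is preserved to within one sample period.
#'
#' @param wave A [waveform()].
#' @param target_rate New sampling rate in Hz.
#' @return A [waveform()] at `target_rate`.
#' @export
resample_wave <- function(wave, target_rate) {
  stopifnot(inherits(wave, "usv_waveform"))
  if (target_rate == wave$rate) return(wave)
  frac <- rational_approx(target_rate / wave$rate)
  y <- signal::resample(wave$samples, frac[1], frac[2])
  n_out <- ceiling(length(wave$samples) * target_rate / wave$rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  waveform(y, target_rate)
}

# Continued-fraction rational approximation p/q of x (q bounded).
rational_approx <- function(x, max_den = 10000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

# ---------------------------------------------------------------------------
# Label tables
# ---------------------------------------------------------------------------

usv_label_levels <- c("USV", "AC", "noise")

#' Construct/validate a label table
#'
#' A label table is a data frame of annotated events with columns `onset`
#' and `offset` (seconds) and `label` (one of `"USV"`, `"AC"`, `"noise"`).
#' Rows are sorted by onset. `AC` (alarm call) rows are excluded from metric
#' computation downstream; `noise` rows mark annotated noise events.
#'
#' @param onset,offset Numeric vectors of event boundaries in seconds.
#' @param label Character vector of labels (recycled if length 1).
#' @param source Optional source identifier stored as an attribute.
#' @return A `data.frame` of class `usv_labels`.
#' @export
label_table <- function(onset = numeric(), offset = numeric(),
                        label = character(), source = NA_character_) {
  if (length(label) == 1L && length(onset) > 1L)
    label <- rep(label, length(onset))
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   label = as.character(label), stringsAsFactors = FALSE)
  validate_label_table(df)
  df <- df[order(df$onset, df$offset), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("usv_labels", "data.frame")
  df
}

validate_label_table <- function(df) {
  if (!all(c("onset", "offset", "label") %in% names(df)))
    stop("label table needs columns onset, offset, label", call. = FALSE)
  bad <- which(!(df$onset < df$offset))
  if (length(bad))
    stop("onset must be < offset; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(df$label), usv_label_levels)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(usv_label_levels, collapse = ", "), ")",
         call. = FALSE)
  invisible(df)
}

#' Read a label table from CSV
#'
#' Expects a header with at least `onset,offset,label` (seconds with decimal
#' point). Rows are validated (onset < offset, labels from the closed
#' vocabulary) and re-sorted by onset. Extra columns (e.g. `score`,
#' `freq_low_hz`, `freq_high_hz` written by the detector) are preserved.
#'
#' @param path CSV path.
#' @return A `usv_labels` data frame.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    out <- label_table(source = path)
    for (cn in setdiff(names(df), names(out))) out[[cn]] <- df[[cn]]
    return(out)
  }
  validate_label_table(df)
  ord <- order(df$onset, df$offset)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source") <- path
  class(df) <- c("usv_labels", "data.frame")
  df
}

#' Write a label table to CSV
#'
#' Comma-separated, header `onset,offset,label` (plus any extra columns),
#' UTF-8, seconds printed with 6 decimals so that a write/read round trip is
#' the identity to 1e-6 s.
#'
#' @param table A `usv_labels` data frame (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(table, path) {
  df <- as.data.frame(table)
  if (nrow(df)) {
    validate_label_table(df)
    df <- df[order(df$onset, df$offset), , drop = FALSE]
    df$onset <- sprintf("%.6f", df$onset)
    df$offset <- sprintf("%.6f", df$offset)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge overlapping or abutting intervals of one label class
#'
#' Manual annotations may overlap; before conversion to frame labels the
#' union of the annotated spans is taken per label.
#'
#' @param table A `usv_labels` data frame.
#' @param label Label class to merge (default `"USV"`).
#' @return Two-column matrix of merged `(onset, offset)` rows, possibly with
#'   zero rows.
#' @export
merge_label_intervals <- function(table, label = "USV") {
  df <- table[table$label == label, , drop = FALSE]
  if (nrow(df) == 0L) return(matrix(numeric(), ncol = 2,
                                    dimnames = list(NULL, c("onset", "offset"))))
  df <- df[order(df$onset), , drop = FALSE]
  on <- df$onset; off <- df$offset
  keep_on <- on[1]; keep_off <- off[1]
  res <- NULL
  for (i in seq_len(nrow(df))[-1]) {
    if (on[i] <= keep_off) {
      keep_off <- max(keep_off, off[i])
    } else {
      res <- rbind(res, c(keep_on, keep_off))
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  res <- rbind(res, c(keep_on, keep_off))
  dimnames(res) <- list(NULL, c("onset", "offset"))
  res
}
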