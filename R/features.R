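#' Feature-extraction configuration
#'
#' Controls the log-Mel spectrogram the detector works on. The defaults are
#' the representation the model was designed around: 124 Mel-spaced bands
#' covering 1-125 kHz and approximately 332 analysis frames per second
#' (about 3 ms per time step) for 250 kHz audio.
#'
#' The hop is `ceiling(rate / frames_per_s)` samples (754 at 250 kHz) and a
#' recording of `n` samples yields `ceiling(n / hop)` frames, so one second
#' at 250 kHz gives exactly 332 frames. The analysis window is 1024 samples
#' (Hann), zero-padded at the recording tail. Log compression is
#' `10 * log10(power + floor)` with floor 1e-10 of full-scale energy, so
#' silence maps to exactly -100 dB.
#'
#' @param n_bands Number of Mel bands (124).
#' @param fmin,fmax Band range in Hz (1000, 125000).
#' @param frames_per_s Target frame rate (332).
#' @param window_samples STFT window length in samples (1024, Hann).
#' @param n_fft FFT length (1024).
#' @param floor_power Power floor epsilon relative to full scale (1e-10).
#' @return A list of class `usv_feature_config`.
#' @export
feature_config <- function(n_bands = 124L, fmin = 1000, fmax = 125000,
                           frames_per_s = 332, window_samples = 1024L,
                           n_fft = 1024L, floor_power = 1e-10) {
  stopifnot(n_bands >= 1, fmin > 0, fmax > fmin, frames_per_s > 0,
            window_samples >= 2, n_fft >= window_samples, floor_power > 0)
  structure(list(n_bands = as.integer(n_bands), fmin = fmin, fmax = fmax,
                 frames_per_s = frames_per_s,
                 window_samples = as.integer(window_samples),
                 n_fft = as.integer(n_fft), floor_power = floor_power),
            class = "usv_feature_config")
}

#' Value representing silence on the log scale
#' @param config A [feature_config()].
#' @return The dB value assigned to zero-power cells.
#' @export
floor_db <- function(config) 10 * log10(config$floor_power)

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters on `n_bands` Mel-spaced bands between `fmin` and
#' `fmax`, sampled at the FFT bin centers. Narrow bands at the low end of
#' the range can fall between FFT bins; such a filter is given unit weight
#' at the bin nearest its center so every band responds to energy near it.
#'
#' @param config A [feature_config()].
#' @param rate Sampling rate in Hz of the audio to be analyzed.
#' @return A list with `weights` (`n_bands` x `n_fft/2+1` matrix),
#'   `band_edges` (length `n_bands + 2` Hz vector of triangle nodes) and
#'   `band_lo`/`band_hi`/`band_center` per-band Hz vectors.
#' @export
mel_filterbank <- function(config, rate) {
  if (rate < 2 * config$fmax)
    stop("sampling rate ", rate, " Hz is too low for a ", config$fmax,
         " Hz band edge (need >= ", 2 * config$fmax, ")", call. = FALSE)
  nb <- config$n_bands
  edges_mel <- seq(hz_to_mel(config$fmin), hz_to_mel(config$fmax),
                   length.out = nb + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  n_bins <- config$n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1) * rate / config$n_fft
  W <- matrix(0, nb, n_bins)
  for (b in seq_len(nb)) {
    lo <- edges_hz[b]; mid <- edges_hz[b + 1L]; hi <- edges_hz[b + 2L]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    w <- pmax(0, pmin(up, down))
    if (all(w == 0)) w[which.min(abs(bin_hz - mid))] <- 1
    W[b, ] <- w
  }
  list(weights = W, band_edges = edges_hz,
       band_lo = edges_hz[seq_len(nb)],
       band_center = edges_hz[seq_len(nb) + 1L],
       band_hi = edges_hz[seq_len(nb) + 2L])
}

#' Log-Mel spectrogram
#'
#' Converts a waveform to the model's working image: a matrix of log-Mel
#' energies with `config$n_bands` rows (bands, low to high frequency) and
#' one column per analysis frame. Frame `t` (0-based) starts at sample
#' `t * hop`; the tail is zero-padded so the frame count is
#' `ceiling(n_samples / hop)`.
#'
#' @param wave A [waveform()].
#' @param config A [feature_config()].
#' @return An object of class `usv_melspec`: list with `values`
#'   (bands x frames dB matrix), `frame_rate` (frames/s = rate/hop), `hop`,
#'   `rate`, `band_edges`, `band_lo`, `band_hi`, `band_center`, `floor_db`,
#'   `origin_time` (seconds of frame 0 start, always 0 here) and `config`.
#' @export
melspec <- function(wave, config = feature_config()) {
  stopifnot(inherits(wave, "usv_waveform"))
  fb <- mel_filterbank(config, wave$rate)
  hop <- as.integer(ceiling(wave$rate / config$frames_per_s))
  win <- config$window_samples
  x <- wave$samples
  n <- length(x)
  if (n < 1L) stop("waveform is empty", call. = FALSE)
  n_frames <- as.integer(ceiling(n / hop))
  starts <- (seq_len(n_frames) - 1L) * hop
  # frame matrix win x n_frames, zero-padded beyond the signal tail
  idx <- outer(seq_len(win), starts, "+")
  frames <- matrix(0, win, n_frames)
  inside <- idx <= n
  frames[inside] <- x[idx[inside]]
  hw <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))  # Hann
  frames <- frames * hw
  if (config$n_fft > win)
    frames <- rbind(frames, matrix(0, config$n_fft - win, n_frames))
  spec <- stats::mvfft(frames)
  n_bins <- config$n_fft %/% 2L + 1L
  # power normalized so a full-scale DC-free tone is O(1)
  power <- (Mod(spec[seq_len(n_bins), , drop = FALSE])^2) / (sum(hw) / 2)^2
  mel_power <- fb$weights %*% power
  values <- 10 * log10(mel_power + config$floor_power)
  structure(list(values = values, frame_rate = wave$rate / hop, hop = hop,
                 rate = wave$rate, band_edges = fb$band_edges,
                 band_lo = fb$band_lo, band_hi = fb$band_hi,
                 band_center = fb$band_center, floor_db = floor_db(config),
                 origin_time = 0, config = config),
            class = "usv_melspec")
}

#' @export
print.usv_melspec <- function(x, ...) {
  cat(sprintf("<usv_melspec> %d bands x %d frames @ %.2f frames/s (%.1f-%.1f kHz)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              x$band_edges[1] / 1000, x$band_edges[length(x$band_edges)] / 1000))
  invisible(x)
}

#' Number of frames in a Mel spectrogram
#' @param ms A `usv_melspec`.
#' @return Integer frame count.
#' @export
n_frames <- function(ms) ncol(ms$values)

#' Linear-power view of a log-Mel spectrogram
#'
#' Undoes the dB compression (`10^(v/10) - floor`), clamped at zero. Used
#' when denoised syllables are wanted on a linear energy scale.
#'
#' @param ms A `usv_melspec`.
#' @return Bands x frames matrix of Mel-band powers.
#' @export
mel_power <- function(ms) {
  pmax(10^(ms$values / 10) - ms$config$floor_power, 0)
}

#' Context windows around each frame
#'
#' Returns the 124 x (2k+1) patch centered on each frame, the unit the CNN
#' stage consumes. The spectrogram is padded in time with the silence floor
#' value so every window is full width; column `k+1` of window `t` equals
#' frame `t` of the spectrogram.
#'
#' @param ms A `usv_melspec`.
#' @param k Context radius in frames (default 25, giving 51-frame windows).
#' @return A 3-d array `bands x (2k+1) x n_frames`.
#' @export
context_windows <- function(ms, k = 25L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  v <- pad_time(ms$values, k, ms$floor_db)
  nf <- ncol(ms$values)
  w <- 2L * k + 1L
  out <- array(0, dim = c(nrow(ms$values), w, nf))
  for (t in seq_len(nf)) out[, , t] <- v[, t:(t + w - 1L), drop = FALSE]
  out
}

# pad a bands x frames matrix with `k` constant columns on each side
pad_time <- function(values, k, pad_value) {
  nb <- nrow(values)
  pad <- matrix(pad_value, nb, k)
  cbind(pad, values, pad)
}

#' Convert a label table to per-frame binary labels
#'
#' Frame `t` (0-based) covers the half-open time span
#' `[t, t+1) / frame_rate`; it is labeled 1 when that span intersects any
#' USV row (after merging overlapping rows). `AC` and `noise` rows are
#' ignored. The hop-tiling span makes frame labels and interval
#' reconstruction mutually consistent to within one frame period per edge.
#'
#' @param table A `usv_labels` data frame.
#' @param frame_rate Frames per second.
#' @param n_frames Number of frames to label.
#' @return Integer vector of 0/1 of length `n_frames`.
#' @export
labels_to_frames <- function(table, frame_rate, n_frames) {
  y <- integer(n_frames)
  iv <- merge_label_intervals(table, "USV")
  if (nrow(iv) == 0L) return(y)
  for (i in seq_len(nrow(iv))) {
    t0 <- max(0L, floor(iv[i, 1] * frame_rate))
    t1 <- min(n_frames - 1L, ceiling(iv[i, 2] * frame_rate) - 1L)
    if (t1 >= t0) y[(t0 + 1L):(t1 + 1L)] <- 1L
  }
  y
}
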