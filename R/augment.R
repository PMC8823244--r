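#' Augmentation configuration
#'
#' Training-time map augmentations that make the classifier tolerant to
#' recording-chain differences: a shift along the frequency axis (new call
#' frequencies), an affine jitter of the log-energy values (input scale and
#' center), and injection of horizontal/vertical lines (continuous humming
#' and impulse noise). Gaussian and salt-and-pepper pixel noise are
#' implemented but disabled by default; they did not help this kind of
#' detector and are kept only for experimentation.
#'
#' Value ranges are in the log-energy units of the feature maps (dB-like
#' "a.u."): `value_offset_range` is an additive re-centering, and
#' `value_scale_range` is a gain expressed additively in the log domain and
#' converted to a multiplicative factor `10^(scale/20)`.
#'
#' @param freq_shift_range Integer band shift range, default `c(-15, 15)`.
#' @param value_offset_range Additive offset range in a.u., default
#'   `c(-50, 10)`.
#' @param value_scale_range Scale range in a.u., default `c(-3, 3)`.
#' @param line_count_range Lines injected per axis, default `c(1, 3)`.
#' @param line_intensity_range Added line intensity in a.u., default
#'   `c(10, 40)`.
#' @param p_shift,p_jitter,p_lines,p_gauss,p_saltpepper Per-augmentation
#'   application probabilities.
#' @param gauss_sd Standard deviation of optional Gaussian pixel noise (a.u.).
#' @param saltpepper_frac Fraction of pixels hit by optional salt-and-pepper
#'   noise.
#' @return A list of class `usv_augment_config`.
#' @export
augment_config <- function(freq_shift_range = c(-15L, 15L),
                           value_offset_range = c(-50, 10),
                           value_scale_range = c(-3, 3),
                           line_count_range = c(1L, 3L),
                           line_intensity_range = c(10, 40),
                           p_shift = 0.5, p_jitter = 0.5, p_lines = 0.5,
                           p_gauss = 0, p_saltpepper = 0,
                           gauss_sd = 2, saltpepper_frac = 0.01) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      stop(nm, " must be an ordered pair", call. = FALSE)
  }
  chk_range(freq_shift_range, "freq_shift_range")
  chk_range(value_offset_range, "value_offset_range")
  chk_range(value_scale_range, "value_scale_range")
  chk_range(line_count_range, "line_count_range")
  chk_range(line_intensity_range, "line_intensity_range")
  for (p in c(p_shift, p_jitter, p_lines, p_gauss, p_saltpepper))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  structure(list(freq_shift_range = as.integer(freq_shift_range),
                 value_offset_range = value_offset_range,
                 value_scale_range = value_scale_range,
                 line_count_range = as.integer(line_count_range),
                 line_intensity_range = line_intensity_range,
                 p_shift = p_shift, p_jitter = p_jitter, p_lines = p_lines,
                 p_gauss = p_gauss, p_saltpepper = p_saltpepper,
                 gauss_sd = gauss_sd, saltpepper_frac = saltpepper_frac),
            class = "usv_augment_config")
}

#' Shift a feature map along the frequency axis
#'
#' Band `b` of the input appears at band `b + shift_bands` of the output;
#' bands shifted outside the map are dropped and vacated bands are filled
#' with `pad_value` (the silence floor). Shape is preserved.
#'
#' @param map Bands x frames numeric matrix.
#' @param shift_bands Integer shift; positive moves energy to higher bands.
#' @param pad_value Fill value for vacated bands (default -100, the silence
#'   floor of the default feature config).
#' @return Shifted matrix of the same dimensions.
#' @export
shift_frequency <- function(map, shift_bands, pad_value = -100) {
  nb <- nrow(map)
  if (abs(shift_bands) >= nb)
    stop("|shift_bands| must be < ", nb, call. = FALSE)
  s <- as.integer(shift_bands)
  if (s == 0L) return(map)
  out <- matrix(pad_value, nb, ncol(map))
  if (s > 0) {
    out[(1L + s):nb, ] <- map[1:(nb - s), , drop = FALSE]
  } else {
    out[1:(nb + s), ] <- map[(1L - s):nb, , drop = FALSE]
  }
  out
}

#' Affine value jitter of a feature map
#'
#' Applies `map * scale_factor + offset` with
#' `scale_factor = 10^(scale / 20)`, i.e. the scale argument is a gain in
#' the same additive log units as the map and `scale = 0` is neutral.
#'
#' @param map Numeric matrix.
#' @param offset Additive offset in a.u.
#' @param scale Gain in a.u.; 0 leaves the scale unchanged.
#' @return Jittered matrix.
#' @export
jitter_values <- function(map, offset = 0, scale = 0) {
  map * jitter_scale_factor(scale) + offset
}

#' @rdname jitter_values
#' @export
jitter_scale_factor <- function(scale) 10^(scale / 20)

#' Inject humming and impulse lines into a feature map
#'
#' Adds full-width horizontal lines (continuous humming at a fixed band) and
#' full-height vertical lines (broadband impulses at a single frame), with
#' counts, positions and intensities drawn from the current RNG stream.
#'
#' @param map Bands x frames numeric matrix.
#' @param config An [augment_config()].
#' @param seed Optional integer; when given, `set.seed(seed)` makes the call
#'   reproducible on its own.
#' @return List with `map` (augmented matrix), `rows` (injected band
#'   indices) and `cols` (injected frame indices).
#' @export
inject_lines <- function(map, config = augment_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cr <- config$line_count_range
  n_h <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1L)
  n_v <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1L)
  rows <- if (n_h > 0) sample.int(nrow(map), n_h) else integer()
  cols <- if (n_v > 0) sample.int(ncol(map), n_v) else integer()
  ir <- config$line_intensity_range
  for (r in rows) map[r, ] <- map[r, ] + stats::runif(1, ir[1], ir[2])
  for (cc in cols) map[, cc] <- map[, cc] + stats::runif(1, ir[1], ir[2])
  list(map = map, rows = rows, cols = cols)
}

#' Apply the augmentation pipeline to one feature map
#'
#' Each augmentation fires independently with its configured probability,
#' drawing parameters from the current RNG stream. With all probabilities
#' zero this is the identity.
#'
#' @param map Bands x frames numeric matrix.
#' @param config An [augment_config()].
#' @param pad_value Fill value for frequency shifts.
#' @return List with `map` and `applied`, a named logical vector recording
#'   which augmentations fired.
#' @export
augment_map <- function(map, config = augment_config(), pad_value = -100) {
  applied <- c(shift = FALSE, jitter = FALSE, lines = FALSE,
               gauss = FALSE, saltpepper = FALSE)
  if (config$p_shift > 0 && stats::runif(1) < config$p_shift) {
    sr <- config$freq_shift_range
    s <- if (sr[1] == sr[2]) sr[1] else sample(sr[1]:sr[2], 1L)
    map <- shift_frequency(map, s, pad_value)
    applied["shift"] <- TRUE
  }
  if (config$p_jitter > 0 && stats::runif(1) < config$p_jitter) {
    off <- stats::runif(1, config$value_offset_range[1], config$value_offset_range[2])
    sc <- stats::runif(1, config$value_scale_range[1], config$value_scale_range[2])
    map <- jitter_values(map, off, sc)
    applied["jitter"] <- TRUE
  }
  if (config$p_lines > 0 && stats::runif(1) < config$p_lines) {
    map <- inject_lines(map, config)$map
    applied["lines"] <- TRUE
  }
  if (config$p_gauss > 0 && stats::runif(1) < config$p_gauss) {
    map <- map + matrix(stats::rnorm(length(map), 0, config$gauss_sd),
                        nrow(map), ncol(map))
    applied["gauss"] <- TRUE
  }
  if (config$p_saltpepper > 0 && stats::runif(1) < config$p_saltpepper) {
    n_hit <- max(1L, round(config$saltpepper_frac * length(map)))
    hit <- sample.int(length(map), n_hit)
    lo <- min(map); hi <- max(map)
    map[hit] <- ifelse(stats::runif(n_hit) < 0.5, lo, hi)
    applied["saltpepper"] <- TRUE
  }
  list(map = map, applied = applied)
}
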