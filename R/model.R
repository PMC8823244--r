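#' Model configuration
#'
#' Architecture of the hybrid detector. Each analysis frame is classified
#' from its 124 x 51 context window in two stages. (1) A convolutional
#' stage with two branches: a 1-D (frequency-axis) convolution over the
#' window's mid column that accentuates candidate call energy, and a 2-D
#' convolution over the whole window, pooled over time, that captures the
#' surrounding noise context. The branch outputs are multiplied and passed
#' through a sigmoid, giving a 124-value frequency mask in \[0, 1] per frame
#' ("which bands belong to a call here"). (2) A bidirectional LSTM reads
#' the mask columns across a segment (~332 frames) and a fully connected
#' softmax layer classifies every frame as call / background, trained with
#' class-weighted cross entropy.
#'
#' Convolutions are zero-padded along frequency and valid (unpadded) along
#' time, which makes the mask exactly frame-local: a frame's mask column
#' depends only on its own 51-frame context, and per-window and
#' full-spectrogram evaluation agree to machine precision.
#'
#' The default layer sizes are deliberately small so the model trains in
#' minutes on a single CPU core; every size is exposed here.
#'
#' @param bands Frequency bands (124).
#' @param context Context radius k in frames (25, i.e. 51-frame windows).
#' @param conv1d_kernel,conv1d_channels Mid-column branch: frequency kernel
#'   length and hidden channel count (two layers, `1 -> channels -> 1`).
#' @param conv2d_kernel Full-map branch kernel as `c(freq, time)`; the time
#'   extent must be odd and small enough that two valid layers fit in the
#'   window.
#' @param conv2d_channels Hidden channels of the full-map branch (two
#'   layers, `1 -> channels -> 1`).
#' @param hidden BiLSTM hidden units per direction.
#' @param class_weights Numeric `(background, USV)` loss weights; normalized
#'   to sum to 1. Default `c(0.5, 0.5)`; training usually overrides with
#'   inverse class prevalence.
#' @param in_center,in_scale Fixed affine input normalization applied to the
#'   dB feature maps before the network (`(x - in_center) / in_scale`).
#' @param floor_db Silence value used to pad window edges, matching the
#'   feature extractor's log floor.
#' @param seed Seed for weight initialization.
#' @return A list of class `usv_model_config`.
#' @export
model_config <- function(bands = 124L, context = 25L,
                         conv1d_kernel = 7L, conv1d_channels = 4L,
                         conv2d_kernel = c(5L, 3L), conv2d_channels = 4L,
                         hidden = 48L, class_weights = c(0.5, 0.5),
                         in_center = -60, in_scale = 20,
                         floor_db = -100, seed = 1L) {
  stopifnot(bands >= 4, context >= 1, conv1d_kernel %% 2 == 1,
            conv2d_kernel[2] %% 2 == 1, hidden >= 1,
            length(class_weights) == 2, all(class_weights > 0))
  if (2L * (conv2d_kernel[2] - 1L) >= 2L * context + 1L)
    stop("conv2d time kernel too large for the context window", call. = FALSE)
  structure(list(bands = as.integer(bands), context = as.integer(context),
                 conv1d_kernel = as.integer(conv1d_kernel),
                 conv1d_channels = as.integer(conv1d_channels),
                 conv2d_kernel = as.integer(conv2d_kernel),
                 conv2d_channels = as.integer(conv2d_channels),
                 hidden = as.integer(hidden),
                 class_weights = class_weights / sum(class_weights),
                 in_center = in_center, in_scale = in_scale,
                 floor_db = floor_db, seed = as.integer(seed)),
            class = "usv_model_config")
}

glorot <- function(dims) {
  n <- length(dims)
  fan_in <- prod(dims[-n])
  fan_out <- prod(dims[seq_len(n - 2L)]) * dims[n]
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Initialize a model
#'
#' Draws all weights from a seeded Glorot-uniform distribution (LSTM forget
#' gates biased open). Two calls with the same config are identical.
#'
#' @param config A [model_config()].
#' @return An object of class `usv_model`: the config plus a flat named
#'   parameter list.
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "usv_model_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  k1 <- config$conv1d_kernel
  c1 <- config$conv1d_channels
  kf <- config$conv2d_kernel[1]; kt <- config$conv2d_kernel[2]
  c2 <- config$conv2d_channels
  hid <- config$hidden
  params <- list(
    # the 1-D branch output bias starts at 1 and the 2-D branch at 0: the
    # product a1 * b2 then starts near 0 (mask 0.5, i.e. centered) while
    # still passing gradient through the 2-D branch from the first step
    # (both branches near zero would stall the product gate)
    c1_W1 = glorot(c(k1, 1L, 1L, c1)), c1_b1 = numeric(c1),
    c1_W2 = glorot(c(k1, 1L, c1, 1L)), c1_b2 = 1,
    c2_W1 = glorot(c(kf, kt, 1L, c2)), c2_b1 = numeric(c2),
    c2_W2 = glorot(c(kf, kt, c2, 1L)), c2_b2 = 0
  )
  lf <- lstm_init(config$bands, hid)
  lb <- lstm_init(config$bands, hid)
  params$lf_Wx <- lf$Wx; params$lf_Wh <- lf$Wh; params$lf_b <- lf$b
  params$lb_Wx <- lb$Wx; params$lb_Wh <- lb$Wh; params$lb_b <- lb$b
  params$fc_W <- matrix(stats::runif(2L * hid * 2L, -sqrt(6 / (2 * hid + 2)),
                                     sqrt(6 / (2 * hid + 2))), 2L * hid, 2L)
  params$fc_b <- numeric(2L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  structure(list(config = config, params = params), class = "usv_model")
}

#' @export
print.usv_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<usv_model> %d bands, context %d, conv %d/%d ch, BiLSTM %d/dir, %d parameters\n",
              x$config$bands, x$config$context, x$config$conv1d_channels,
              x$config$conv2d_channels, x$config$hidden, np))
  invisible(x)
}

# normalized pad value used for time padding of the 2-D branch input
norm_pad_value <- function(model) {
  (model$config$floor_db - model$config$in_center) / model$config$in_scale
}

# CNN stage over a full dB feature map (bands x L). Returns mask (bands x L)
# plus caches when keep_cache.
cnn_forward <- function(model, values, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (nrow(values) != cfg$bands)
    stop("feature map has ", nrow(values), " bands; model expects ",
         cfg$bands, call. = FALSE)
  L <- ncol(values)
  xn <- (values - cfg$in_center) / cfg$in_scale
  # 1-D branch: frequency conv on each frame column (the window mid column)
  X1 <- array(xn, c(cfg$bands, L, 1L))
  h1 <- conv2d_fwd(X1, p$c1_W1, p$c1_b1)
  r1 <- pmax(h1, 0)
  a1 <- conv2d_fwd(r1, p$c1_W2, p$c1_b2)
  a1 <- matrix(a1, cfg$bands, L)
  # 2-D branch: valid-in-time convs over the context-padded map, then a
  # sliding time mean covering each 51-frame window
  k <- cfg$context; kt <- cfg$conv2d_kernel[2]
  Xp <- array(pad_time(xn, k, norm_pad_value(model)), c(cfg$bands, L + 2L * k, 1L))
  h2 <- conv2d_fwd(Xp, p$c2_W1, p$c2_b1)
  r2 <- pmax(h2, 0)
  g2 <- conv2d_fwd(r2, p$c2_W2, p$c2_b2)
  g2m <- matrix(g2, cfg$bands, dim(g2)[2])
  P <- 2L * k + 1L - 2L * (kt - 1L)
  b2 <- meanpool_fwd(g2m, P)
  pre <- a1 * b2
  mask <- sigmoid(pre)
  if (!keep_cache) return(list(mask = mask))
  list(mask = mask, xn = xn, X1 = X1, h1 = h1, r1 = r1, a1 = a1, Xp = Xp,
       h2 = h2, r2 = r2, g2m = g2m, b2 = b2, P = P)
}

# Backward through the CNN stage. dM: gradient at the mask (bands x L).
# Returns flat named gradient list (conv parameters only).
cnn_backward <- function(model, cache, dM) {
  p <- model$params
  mask <- cache$mask
  dpre <- dM * mask * (1 - mask)
  da1 <- dpre * cache$b2
  db2 <- dpre * cache$a1
  # 1-D branch
  da1a <- array(da1, c(dim(da1), 1L))
  g2 <- conv2d_bwd(cache$r1, p$c1_W2, da1a, need_dx = TRUE)
  dr1 <- g2$dX * (cache$h1 > 0)
  g1 <- conv2d_bwd(cache$X1, p$c1_W1, dr1, need_dx = FALSE)
  # 2-D branch
  dg2m <- meanpool_bwd(db2, cache$P, ncol(cache$g2m))
  dg2 <- array(dg2m, c(dim(dg2m), 1L))
  h2b <- conv2d_bwd(cache$r2, p$c2_W2, dg2, need_dx = TRUE)
  dr2 <- h2b$dX * (cache$h2 > 0)
  h1b <- conv2d_bwd(cache$Xp, p$c2_W1, dr2, need_dx = FALSE)
  list(c1_W1 = g1$dW, c1_b1 = g1$db, c1_W2 = g2$dW, c1_b2 = g2$db,
       c2_W1 = h1b$dW, c2_b1 = h1b$db, c2_W2 = h2b$dW, c2_b2 = h2b$db)
}

#' Frequency mask and filtered window for one context window
#'
#' Runs the convolutional stage on a single 124 x 51 context window (see
#' [context_windows()]): the 1-D branch reads the mid column, the 2-D branch
#' reads the whole window, and the sigmoid of their product is the per-band
#' call probability. The filtered window is the input multiplied by the
#' mask (broadcast across time), i.e. the mask acting as a filter.
#'
#' @param model A `usv_model`.
#' @param window Bands x (2k+1) dB matrix.
#' @return List with `mask_column` (length-bands vector in \[0, 1]) and
#'   `filtered_window` (same shape as `window`).
#' @export
cnn_mask <- function(model, window) {
  cfg <- model$config
  w <- 2L * cfg$context + 1L
  if (!is.matrix(window) || nrow(window) != cfg$bands || ncol(window) != w)
    stop("window must be a ", cfg$bands, " x ", w, " matrix", call. = FALSE)
  # the window *is* the context-padded map of its center frame
  mid <- window[, cfg$context + 1L, drop = FALSE]
  p <- model$params
  xn_mid <- (mid - cfg$in_center) / cfg$in_scale
  a1 <- conv2d_fwd(pmax(conv2d_fwd(array(xn_mid, c(cfg$bands, 1L, 1L)),
                                   p$c1_W1, p$c1_b1), 0), p$c1_W2, p$c1_b2)
  xn_win <- (window - cfg$in_center) / cfg$in_scale
  r2 <- pmax(conv2d_fwd(array(xn_win, c(cfg$bands, w, 1L)), p$c2_W1, p$c2_b1), 0)
  g2 <- conv2d_fwd(r2, p$c2_W2, p$c2_b2)
  b2 <- rowMeans(matrix(g2, cfg$bands, dim(g2)[2]))
  mask_column <- as.numeric(sigmoid(as.numeric(a1) * b2))
  list(mask_column = mask_column,
       filtered_window = window * mask_column)
}

# LSTM + FC over a stack of mask sequences.
# masks: (B, bands, T). Returns probs (B, T) of the USV class and caches.
sequence_forward <- function(model, masks, keep_cache = FALSE) {
  p <- model$params
  B <- dim(masks)[1]; nt <- dim(masks)[3]
  hid <- model$config$hidden
  # mask values live in [0, 1]; center them so the LSTM sees zero-mean
  # inputs (all-positive inputs slow gate learning down badly)
  xin <- masks - 0.5
  fw <- lstm_fwd(xin, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b), FALSE)
  bw <- lstm_fwd(xin, list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b), TRUE)
  Y <- matrix(0, B * nt, 2L * hid)
  Y[, seq_len(hid)] <- matrix(aperm(fw$H, c(1, 3, 2)), B * nt, hid)
  Y[, hid + seq_len(hid)] <- matrix(aperm(bw$H, c(1, 3, 2)), B * nt, hid)
  logits <- sweep(Y %*% p$fc_W, 2, p$fc_b, "+")
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  p_usv <- e2 / (e1 + e2)
  probs <- matrix(p_usv, B, nt)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, Y = Y, fw = fw, bw = bw, B = B, nt = nt)
}

# Backward from per-frame class probabilities. labels: (B, T) in {0,1};
# weights: normalized c(w_bg, w_usv). Returns loss, grads (flat list), and
# the gradient wrt the mask input (B, bands, T).
sequence_backward <- function(model, cache, labels, weights) {
  p <- model$params
  B <- cache$B; nt <- cache$nt
  hid <- model$config$hidden
  y <- as.integer(labels)               # column-major matches probs layout
  pu <- as.numeric(cache$probs)
  n <- length(y)
  w <- ifelse(y == 1L, weights[2], weights[1])
  p_true <- ifelse(y == 1L, pu, 1 - pu)
  loss <- -mean(w * log(pmax(p_true, 1e-12)))
  # d loss / d logits for softmax-CE, per frame
  dlog <- matrix(0, n, 2L)
  dlog[, 2] <- w * (pu - y) / n
  dlog[, 1] <- -dlog[, 2]
  # probs (B, nt) column-major == Y row order (b + (t-1)B) -- aligned
  dY <- dlog %*% t(p$fc_W)
  dfc_W <- crossprod(cache$Y, dlog)
  dfc_b <- colSums(dlog)
  dHf <- aperm(array(dY[, seq_len(hid)], c(B, nt, hid)), c(1, 3, 2))
  dHb <- aperm(array(dY[, hid + seq_len(hid)], c(B, nt, hid)), c(1, 3, 2))
  gf <- lstm_bwd(cache$fw, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b), dHf)
  gb <- lstm_bwd(cache$bw, list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b), dHb)
  grads <- list(lf_Wx = gf$dWx, lf_Wh = gf$dWh, lf_b = gf$db,
                lb_Wx = gb$dWx, lb_Wh = gb$dWh, lb_b = gb$db,
                fc_W = dfc_W, fc_b = dfc_b)
  list(loss = loss, grads = grads, dmask = gf$dX + gb$dX)
}

#' Classify a sequence of mask columns
#'
#' Runs the BiLSTM and fully connected stage over a bands x frames stack of
#' mask columns and returns the per-frame probability of the USV class.
#'
#' @param model A `usv_model`.
#' @param mask_columns Bands x frames matrix (values in \[0, 1]).
#' @param frame_rate Optional frames/s carried on the result.
#' @return A `usv_track`: list with `values` (per-frame P(USV)) and
#'   `frame_rate`.
#' @export
classify_sequence <- function(model, mask_columns, frame_rate = NULL) {
  if (!is.matrix(mask_columns) || ncol(mask_columns) < 1L)
    stop("mask_columns must be a non-empty bands x frames matrix", call. = FALSE)
  masks <- array(0, c(1L, nrow(mask_columns), ncol(mask_columns)))
  masks[1, , ] <- mask_columns
  out <- sequence_forward(model, masks)
  prob_track(as.numeric(out$probs[1, ]), frame_rate)
}

#' Per-frame probability track
#'
#' @param values Numeric vector of P(USV) per frame, in \[0, 1].
#' @param frame_rate Frames per second (may be `NULL` when unknown).
#' @return A list of class `usv_track`.
#' @export
prob_track <- function(values, frame_rate = NULL) {
  stopifnot(all(values >= -1e-9 & values <= 1 + 1e-9))
  structure(list(values = pmin(pmax(values, 0), 1), frame_rate = frame_rate),
            class = "usv_track")
}

#' Class-weighted cross entropy of a probability track
#'
#' `loss = -mean(w[label] * log P(label))` with `w = class_weights` taken as
#' `(background, USV)`, so the loss is linear in the weights. This is the
#' training criterion of the frame classifier (which uses the weights
#' normalized to sum to 1); weighting the rare USV class up compensates for
#' class imbalance.
#'
#' @param track A `usv_track` or numeric vector of P(USV).
#' @param labels Integer 0/1 vector, same length.
#' @param class_weights Positive pair `(w_background, w_usv)`.
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(track, labels, class_weights = c(0.5, 0.5)) {
  p <- if (inherits(track, "usv_track")) track$values else track
  if (length(p) != length(labels))
    stop("track and labels must have the same length", call. = FALSE)
  stopifnot(all(class_weights > 0))
  wv <- ifelse(labels == 1L, class_weights[2], class_weights[1])
  p_true <- ifelse(labels == 1L, p, 1 - p)
  -mean(wv * log(pmax(p_true, 1e-300)))
}

#' Run the detector over a spectrogram
#'
#' Computes the frequency mask for every frame (exactly equal to running
#' [cnn_mask()] window by window) and classifies mask columns with the
#' BiLSTM in segments of `segment_frames` (default 332, the 1-s training
#' regime; the trailing partial segment is processed as-is).
#'
#' @param object A `usv_model`.
#' @param ms A `usv_melspec` (or bare bands x frames dB matrix).
#' @param segment_frames Segment length for the recurrent stage.
#' @param ... Unused.
#' @return List with `track` (a `usv_track`) and `mask` (bands x frames
#'   matrix in \[0, 1]).
#' @export
predict.usv_model <- function(object, ms, segment_frames = 332L, ...) {
  values <- if (inherits(ms, "usv_melspec")) ms$values else ms
  frame_rate <- if (inherits(ms, "usv_melspec")) ms$frame_rate else NULL
  if (!is.matrix(values) || ncol(values) < 1L)
    stop("need a non-empty feature map", call. = FALSE)
  mask <- cnn_forward(object, values)$mask
  L <- ncol(mask)
  starts <- seq(1L, L, by = segment_frames)
  probs <- numeric(L)
  for (s in starts) {
    e <- min(L, s + segment_frames - 1L)
    seg <- array(0, c(1L, nrow(mask), e - s + 1L))
    seg[1, , ] <- mask[, s:e]
    probs[s:e] <- sequence_forward(object, seg)$probs[1, ]
  }
  list(track = prob_track(probs, frame_rate), mask = mask)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single files containing the configuration and all
#' parameters (R serialization).
#'
#' @param model A `usv_model`.
#' @param path Checkpoint path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "usv_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "usv_model"))
    stop("not a usv_model checkpoint: ", path, call. = FALSE)
  model
}
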