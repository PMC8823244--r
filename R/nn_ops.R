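# Neural-network primitives for the hybrid detector.
#
# Shapes: feature maps are 3-d arrays (bands F, time T, channels C), conv
# kernels 4-d arrays (kf, kt, c_in, c_out), LSTM sequences 3-d arrays
# (batch B, input I, time T). Convolutions are zero-padded ("same") along
# frequency and valid (no padding) along time; valid-in-time is what makes
# the per-window CNN and the full-sequence CNN produce identical mask
# columns. The inner loops live in src/usv_nn.cpp; gradients are checked
# against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

conv2d_fwd <- function(X, W, b) {
  dw <- dim(W)
  stopifnot(dim(X)[3] == dw[3])
  Y <- cpp_conv2d_fwd(X, as.numeric(W), as.integer(dw), as.numeric(b))
  Y
}

conv2d_bwd <- function(X, W, dY, need_dx = TRUE) {
  dw <- dim(W)
  out <- cpp_conv2d_bwd(X, as.numeric(W), as.integer(dw), dY, need_dx)
  res <- list(dW = array(out$dW, dw), db = as.numeric(out$db), dX = NULL)
  if (need_dx) res$dX <- out$dX
  res
}

# sliding mean over time, window P: (F, Tin) -> (F, Tin - P + 1)
row_cumsum <- function(X) {
  for (t in seq_len(ncol(X))[-1]) X[, t] <- X[, t - 1L] + X[, t]
  X
}

meanpool_fwd <- function(X, P) {
  tin <- ncol(X)
  tout <- tin - P + 1L
  stopifnot(tout >= 1L)
  CS <- row_cumsum(X)
  lead <- CS[, P:tin, drop = FALSE]
  lag <- cbind(0, CS[, seq_len(tout - 1L), drop = FALSE])
  (lead - lag) / P
}

meanpool_bwd <- function(dY, P, tin) {
  tout <- ncol(dY)
  DS <- row_cumsum(dY)
  hi <- DS[, pmin(seq_len(tin), tout), drop = FALSE]
  lo <- matrix(0, nrow(dY), tin)
  s <- seq_len(tin)
  has_lo <- s - P >= 1L
  lo[, has_lo] <- DS[, (s - P)[has_lo], drop = FALSE]
  (hi - lo) / P
}

# ---------------------------------------------------------------------------
# LSTM (single layer, batched). Gate column layout: [i | f | g | o].
# ---------------------------------------------------------------------------

lstm_init <- function(input_size, hidden) {
  h4 <- 4L * hidden
  lim_x <- sqrt(6 / (input_size + h4))
  lim_h <- sqrt(6 / (hidden + h4))
  b <- numeric(h4)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(Wx = matrix(stats::runif(input_size * h4, -lim_x, lim_x), input_size, h4),
       Wh = matrix(stats::runif(hidden * h4, -lim_h, lim_h), hidden, h4),
       b = b)
}

# X: (B, I, T). Returns H: (B, hid, T) plus caches for BPTT.
lstm_fwd <- function(X, p, reverse = FALSE) {
  out <- cpp_lstm_fwd(X, p$Wx, p$Wh, p$b, reverse)
  list(H = out$H, gates = out$gates, C = out$C, X = X, reverse = reverse)
}

lstm_bwd <- function(fw, p, dH) {
  cpp_lstm_bwd(fw$X, fw$H, fw$gates, fw$C, p$Wx, p$Wh, dH, fw$reverse)
}

# ---------------------------------------------------------------------------
# Adam optimizer over a flat named list of arrays
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
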