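# The analytic gradients are the core of the training implementation; they
# are validated against central finite differences on a small network.
test_that("backpropagation matches numerical gradients", {
  ns <- asNamespace("usvdetect")
  set.seed(42)
  model <- init_model(tiny_model_config())
  B <- 2L; nt <- 9L; bands <- 12L
  vals <- lapply(1:B, function(i) random_map(bands, nt))
  labels <- matrix(rbinom(B * nt, 1, 0.4), B, nt)
  weights <- c(0.3, 0.7)
  loss_fn <- function(model) {
    masks <- array(0, c(B, bands, nt))
    caches <- vector("list", B)
    for (b in 1:B) {
      cc <- ns$cnn_forward(model, vals[[b]], keep_cache = TRUE)
      caches[[b]] <- cc
      masks[b, , ] <- cc$mask
    }
    sc <- ns$sequence_forward(model, masks, keep_cache = TRUE)
    back <- ns$sequence_backward(model, sc, labels, weights)
    grads <- back$grads
    for (b in 1:B) {
      g <- ns$cnn_backward(model, caches[[b]], matrix(back$dmask[b, , ], bands, nt))
      for (nm in names(g))
        grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
    }
    list(loss = back$loss, grads = grads)
  }
  res <- loss_fn(model)
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (ii in sample(length(p), min(4, length(p)))) {
      m2 <- model; m2$params[[nm]][ii] <- p[ii] + eps
      lp <- loss_fn(m2)$loss
      m2$params[[nm]][ii] <- p[ii] - eps
      lm <- loss_fn(m2)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-7, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("cnn_mask returns a valid mask column and the filtered product", {
  model <- init_model(tiny_model_config())
  win <- random_map(12, 7, seed = 31)
  out <- cnn_mask(model, win)
  expect_length(out$mask_column, 12L)
  expect_true(all(out$mask_column >= 0 & out$mask_column <= 1))
  expect_equal(out$filtered_window, win * out$mask_column)
  expect_error(cnn_mask(model, win[, 1:5]), "matrix")
})

test_that("an all-zero-weight network outputs a constant 0.5 mask", {
  model <- init_model(tiny_model_config())
  model$params <- lapply(model$params, function(p) p * 0)
  out <- cnn_mask(model, random_map(12, 7, seed = 32))
  expect_true(all(out$mask_column == 0.5))
})

test_that("per-window and full-spectrogram masks agree exactly", {
  set.seed(33)
  w <- waveform(rnorm(50000, 0, 0.02), 250000)
  ms <- melspec(w)
  model <- init_model(model_config(seed = 5))
  pred <- predict(model, ms)
  cw <- context_windows(ms, 25)
  for (t in c(1L, 17L, ncol(ms$values))) {
    expect_equal(cnn_mask(model, cw[, , t])$mask_column, pred$mask[, t],
                 tolerance = 1e-12)
  }
})

test_that("the mask is frame-local: perturbations outside the context do nothing", {
  set.seed(34)
  w <- waveform(rnorm(50000, 0, 0.02), 250000)
  ms <- melspec(w)
  model <- init_model(model_config(seed = 5))
  m1 <- predict(model, ms)$mask
  t0 <- 40L
  ms2 <- ms
  ms2$values[, -((t0 - 25):(t0 + 25))] <-
    ms2$values[, -((t0 - 25):(t0 + 25))] + 17
  m2 <- predict(model, ms2)$mask
  expect_equal(m2[, t0], m1[, t0], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m2[, t0 + 26], m1[, t0 + 26])))
})

test_that("classify_sequence returns per-frame probabilities of matching length", {
  model <- init_model(tiny_model_config())
  one <- classify_sequence(model, matrix(runif(12), 12, 1))
  expect_length(one$values, 1L)
  expect_true(one$values >= 0 && one$values <= 1)
  tr <- classify_sequence(model, matrix(runif(12 * 332), 12, 332))
  expect_length(tr$values, 332L)
  expect_true(all(tr$values >= 0 & tr$values <= 1))
  expect_error(classify_sequence(model, matrix(numeric(), 12, 0)), "non-empty")
})

test_that("weighted cross entropy follows its closed form", {
  expect_equal(weighted_cross_entropy(rep(1, 10), rep(1L, 10), c(0.25, 0.75)), 0)
  # uniform 0.5 on half/half labels, weights (bg 0.75, usv 0.25)
  p <- rep(0.5, 10); y <- rep(c(0L, 1L), 5)
  expect_equal(weighted_cross_entropy(p, y, c(0.75, 0.25)),
               0.5 * log(2), tolerance = 1e-12)
  expect_error(weighted_cross_entropy(rep(0.5, 3), rep(1L, 4)), "same length")
})

test_that("doubling both class weights doubles the loss", {
  set.seed(35)
  p <- runif(20); y <- rbinom(20, 1, 0.5)
  expect_equal(weighted_cross_entropy(p, y, c(0.6, 1.4)),
               2 * weighted_cross_entropy(p, y, c(0.3, 0.7)),
               tolerance = 1e-12)
})

test_that("predict returns track and mask matching the frame count", {
  set.seed(36)
  w <- waveform(rnorm(100000, 0, 0.02), 250000)
  ms <- melspec(w)
  model <- init_model(model_config(seed = 5))
  pred <- predict(model, ms, segment_frames = 100L)
  expect_length(pred$track$values, ncol(ms$values))
  expect_equal(dim(pred$mask), dim(ms$values))
  expect_true(all(pred$track$values >= 0 & pred$track$values <= 1))
  expect_true(all(pred$mask >= 0 & pred$mask <= 1))
})

test_that("model initialization is seed-deterministic and checkpoints round-trip", {
  m1 <- init_model(tiny_model_config(seed = 9))
  m2 <- init_model(tiny_model_config(seed = 9))
  expect_identical(m1$params, m2$params)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m1, path)
  m3 <- load_model(path)
  expect_identical(m3$params, m1$params)
  expect_identical(m3$config$bands, m1$config$bands)
})
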