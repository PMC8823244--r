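#' Training configuration
#'
#' Controls dataset engineering and optimization. USV recordings are
#' extremely imbalanced (calls occupy well under a percent of a session), so
#' training uses short clips of consecutive calls (condensation), adds
#' call-free noise clips, and weights the loss by inverse class prevalence.
#'
#' @param segment_len_range Allowed condensed-clip length in seconds,
#'   default `c(1, 20)`.
#' @param max_gap Calls closer than this (seconds) are chained into one
#'   clip, default 1.
#' @param noise_clip_len Length of sampled noise clips in seconds (1).
#' @param clip_pad Seconds of context kept on each side of a chained call
#'   group; defaults to 0.1 s (at least the CNN context duration).
#' @param epochs,batch_size,learning_rate Optimizer settings (Adam).
#' @param val_fraction Fraction of examples held out for validation (split
#'   at the clip level to avoid frame leakage between neighboring windows).
#' @param segment_frames Frames per training segment (332 = 1 s).
#' @param augment An [augment_config()] applied to training feature maps, or
#'   `NULL` (default) for none. Augmentation exists to generalize across
#'   recording chains and noise regimes unseen in training; switch it on
#'   when training for deployment on heterogeneous recordings. On a
#'   within-regime corpus it mostly slows convergence.
#' @param seed RNG seed for the split, shuffling and augmentation draws.
#' @param init_checkpoint Optional checkpoint path to fine-tune from.
#' @param checkpoint_path Optional path where the best-validation model is
#'   saved.
#' @return A list of class `usv_train_config`.
#' @export
train_config <- function(segment_len_range = c(1, 20), max_gap = 1.0,
                         noise_clip_len = 1.0, clip_pad = 0.1,
                         epochs = 10L, batch_size = 8L,
                         learning_rate = 3e-3, val_fraction = 0.2,
                         segment_frames = 332L,
                         augment = NULL,
                         seed = 1L, init_checkpoint = NULL,
                         checkpoint_path = NULL) {
  stopifnot(length(segment_len_range) == 2L,
            segment_len_range[1] <= segment_len_range[2],
            max_gap > 0, epochs >= 1, batch_size >= 1, learning_rate >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(segment_len_range = segment_len_range, max_gap = max_gap,
                 noise_clip_len = noise_clip_len, clip_pad = clip_pad,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 segment_frames = as.integer(segment_frames),
                 augment = augment, seed = as.integer(seed),
                 init_checkpoint = init_checkpoint,
                 checkpoint_path = checkpoint_path),
            class = "usv_train_config")
}

#' Condense a label table into training clip intervals
#'
#' Chains USVs separated by gaps shorter than `max_gap` and emits each chain
#' as one or more clips within `segment_len_range`, padded by `clip_pad` on
#' each side. Chains longer than the upper length bound are split
#' recursively at their largest internal gap. Emitted clips never overlap
#' and every USV lies inside exactly one clip.
#'
#' @param table A `usv_labels` data frame.
#' @param config A [train_config()].
#' @param duration Optional recording duration in seconds used to clamp clip
#'   ends.
#' @return Data frame with columns `start`, `end` (seconds), possibly empty.
#' @export
condense_segments <- function(table, config = train_config(), duration = Inf) {
  iv <- merge_label_intervals(table, "USV")
  out <- data.frame(start = numeric(), end = numeric())
  if (nrow(iv) == 0L) return(out)
  pad <- config$clip_pad
  max_len <- config$segment_len_range[2]
  min_len <- config$segment_len_range[1]
  # chain by gap
  chain_id <- cumsum(c(1, as.numeric(iv[-1, 1] - iv[-nrow(iv), 2] >= config$max_gap)))
  spans <- list()
  for (cid in unique(chain_id)) {
    rows <- iv[chain_id == cid, , drop = FALSE]
    spans <- c(spans, split_chain(rows, max_len - 2 * pad))
  }
  starts <- vapply(spans, function(s) s[1], 1) - pad
  ends <- vapply(spans, function(s) s[2], 1) + pad
  # grow short clips toward min length, then clamp to bounds and neighbors
  need <- pmax(0, min_len - (ends - starts))
  starts <- starts - need / 2
  ends <- ends + need / 2
  starts <- pmax(starts, 0)
  ends <- pmin(ends, duration)
  if (length(starts) > 1L) {
    for (i in seq_len(length(starts) - 1L)) {
      if (ends[i] > starts[i + 1L]) {
        lim_lo <- spans[[i]][2]        # never cut into a call
        lim_hi <- spans[[i + 1L]][1]
        mid <- min(max((ends[i] + starts[i + 1L]) / 2, lim_lo), lim_hi)
        ends[i] <- mid
        starts[i + 1L] <- mid
      }
    }
  }
  data.frame(start = starts, end = ends)
}

# split a chain (matrix of merged USV rows) into spans of length <= max_span,
# cutting at the largest internal gap
split_chain <- function(rows, max_span) {
  span <- c(rows[1, 1], rows[nrow(rows), 2])
  if (span[2] - span[1] <= max_span || nrow(rows) == 1L)
    return(list(span))
  gaps <- rows[-1, 1] - rows[-nrow(rows), 2]
  cut <- which.max(gaps)
  c(split_chain(rows[seq_len(cut), , drop = FALSE], max_span),
    split_chain(rows[(cut + 1):nrow(rows), , drop = FALSE], max_span))
}

#' Extract a clip from a recording
#'
#' Cuts `[start, end)` out of a waveform and shifts the label table into
#' clip-local time, keeping rows that intersect the clip (trimmed to it).
#'
#' @param wave A [waveform()].
#' @param table A `usv_labels` data frame.
#' @param start,end Clip boundaries in seconds.
#' @return List with `wave` and `labels` (a training clip).
#' @export
extract_clip <- function(wave, table, start, end) {
  i0 <- max(1L, floor(start * wave$rate) + 1L)
  i1 <- min(length(wave$samples), ceiling(end * wave$rate))
  w <- waveform(wave$samples[i0:i1], wave$rate)
  keep <- table$onset < end & table$offset > start
  df <- as.data.frame(table)[keep, , drop = FALSE]
  if (nrow(df)) {
    df$onset <- pmax(df$onset - start, 0)
    df$offset <- pmin(df$offset - start, end - start)
    lab <- label_table(df$onset, df$offset, df$label)
  } else lab <- label_table()
  list(wave = w, labels = lab)
}

#' Assemble a training dataset from clips
#'
#' Converts call clips and noise clips (lists with elements `wave` and
#' `labels`) to log-Mel feature maps, chops them into fixed-length frame
#' segments, attaches per-frame 0/1 labels, and measures the USV frame
#' prevalence used for class weighting (inverse-prevalence weights, so a
#' 25% USV / 75% background mix yields weights 0.75 USV / 0.25 background).
#' Noise clips must not contain labeled USVs.
#'
#' @param clips List of call clips.
#' @param noise_clips List of call-free clips.
#' @param feature_cfg A [feature_config()].
#' @param segment_frames Frames per training segment (default 332); shorter
#'   tails are padded with the silence floor and background labels.
#' @return A list of class `usv_dataset` with `examples` (each a list with
#'   `values` and `labels`), `prevalence`, `class_weights` (background,
#'   USV), `frame_rate` and `floor_db`.
#' @export
assemble_dataset <- function(clips, noise_clips = list(),
                             feature_cfg = feature_config(),
                             segment_frames = 332L) {
  for (nc in noise_clips) {
    if (!is.null(nc$labels) && nrow(nc$labels) && any(nc$labels$label == "USV"))
      stop("a noise clip contains labeled USVs", call. = FALSE)
  }
  all_clips <- c(clips, noise_clips)
  if (!length(all_clips)) stop("no clips supplied", call. = FALSE)
  fl <- floor_db(feature_cfg)
  examples <- list()
  n_usv_frames <- 0; n_frames_total <- 0
  frame_rate <- NULL
  for (cl in all_clips) {
    ms <- melspec(cl$wave, feature_cfg)
    frame_rate <- ms$frame_rate
    lab <- if (is.null(cl$labels)) label_table() else cl$labels
    y <- labels_to_frames(lab, ms$frame_rate, n_frames(ms))
    n_usv_frames <- n_usv_frames + sum(y)
    n_frames_total <- n_frames_total + length(y)
    for (s in seq(1L, ncol(ms$values), by = segment_frames)) {
      e <- min(ncol(ms$values), s + segment_frames - 1L)
      v <- ms$values[, s:e, drop = FALSE]
      yy <- y[s:e]
      if (ncol(v) < segment_frames) {
        padn <- segment_frames - ncol(v)
        v <- cbind(v, matrix(fl, nrow(v), padn))
        yy <- c(yy, integer(padn))
      }
      examples[[length(examples) + 1L]] <- list(values = v, labels = yy)
    }
  }
  prevalence <- n_usv_frames / n_frames_total
  w <- if (prevalence > 0 && prevalence < 1)
    c(prevalence, 1 - prevalence) else c(0.5, 0.5)
  structure(list(examples = examples, prevalence = prevalence,
                 class_weights = w, frame_rate = frame_rate, floor_db = fl,
                 segment_frames = as.integer(segment_frames)),
            class = "usv_dataset")
}

# one optimization step over a batch of examples; returns loss and updates
# params/state in the calling environment via returned list
train_batch <- function(model, batch, weights, opt_state, lr, aug_cfg, floor_db) {
  B <- length(batch)
  nt <- length(batch[[1]]$labels)
  caches <- vector("list", B)
  masks <- array(0, c(B, model$config$bands, nt))
  labels <- matrix(0L, B, nt)
  for (b in seq_len(B)) {
    v <- batch[[b]]$values
    if (!is.null(aug_cfg)) v <- augment_map(v, aug_cfg, pad_value = floor_db)$map
    cc <- cnn_forward(model, v, keep_cache = TRUE)
    caches[[b]] <- cc
    masks[b, , ] <- cc$mask
    labels[b, ] <- batch[[b]]$labels
  }
  seq_cache <- sequence_forward(model, masks, keep_cache = TRUE)
  back <- sequence_backward(model, seq_cache, labels, weights)
  grads <- back$grads
  for (b in seq_len(B)) {
    dM <- matrix(back$dmask[b, , ], model$config$bands, nt)
    g <- cnn_backward(model, caches[[b]], dM)
    for (nm in names(g))
      grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
  }
  upd <- adam_step(model$params, grads, opt_state, lr = lr)
  model$params <- upd$params
  list(model = model, state = upd$state, loss = back$loss)
}

# frame-level recall/precision/F1 of a model on a list of examples
frame_metrics <- function(model, examples, threshold = 0.5) {
  tp <- fp <- fn <- 0
  for (ex in examples) {
    masks <- array(0, c(1L, model$config$bands, ncol(ex$values)))
    masks[1, , ] <- cnn_forward(model, ex$values)$mask
    p <- sequence_forward(model, masks)$probs[1, ]
    pred <- as.integer(p >= threshold)
    tp <- tp + sum(pred == 1L & ex$labels == 1L)
    fp <- fp + sum(pred == 1L & ex$labels == 0L)
    fn <- fn + sum(pred == 0L & ex$labels == 1L)
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Train (or fine-tune) the detector
#'
#' Splits the dataset into training and validation examples, optimizes the
#' class-weighted cross entropy with Adam, logs per-epoch training loss and
#' validation frame-level recall/precision/F1, and keeps the parameters of
#' the best-validation epoch. With `init_checkpoint` set in the training
#' config, training resumes from a saved model whose architecture must
#' match `model_cfg`.
#'
#' @param dataset A `usv_dataset` from [assemble_dataset()].
#' @param model_cfg A [model_config()]; its `class_weights` are replaced by
#'   the dataset's inverse-prevalence weights unless `use_dataset_weights`
#'   is `FALSE`.
#' @param cfg A [train_config()].
#' @param use_dataset_weights Take loss weights from the dataset prevalence
#'   (default) or keep the ones in `model_cfg`.
#' @return A list of class `usv_fit`: `model` (best-validation `usv_model`),
#'   `history` (data frame: epoch, loss, val_recall, val_precision, val_f1)
#'   and `class_weights`.
#' @export
train_model <- function(dataset, model_cfg = model_config(),
                        cfg = train_config(), use_dataset_weights = TRUE) {
  stopifnot(inherits(dataset, "usv_dataset"))
  if (!length(dataset$examples)) stop("dataset is empty", call. = FALSE)
  set.seed(cfg$seed)
  if (!is.null(cfg$init_checkpoint)) {
    model <- load_model(cfg$init_checkpoint)
    same <- function(f) identical(model$config[[f]], model_cfg[[f]])
    if (!all(vapply(c("bands", "context", "conv1d_kernel", "conv1d_channels",
                      "conv2d_kernel", "conv2d_channels", "hidden"), same, TRUE)))
      stop("checkpoint architecture does not match model_cfg", call. = FALSE)
  } else {
    model <- init_model(model_cfg)
  }
  weights <- if (use_dataset_weights) dataset$class_weights
             else model_cfg$class_weights
  weights <- weights / sum(weights)
  model$config$class_weights <- weights

  n <- length(dataset$examples)
  idx <- sample.int(n)
  n_val <- max(if (cfg$val_fraction > 0) 1L else 0L, floor(cfg$val_fraction * n))
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer()
  tr_idx <- setdiff(idx, val_idx)
  if (!length(tr_idx)) stop("no training examples after validation split", call. = FALSE)
  val <- dataset$examples[val_idx]
  train <- dataset$examples[tr_idx]

  opt_state <- adam_init(model$params)
  history <- NULL
  best <- list(f1 = -Inf, params = model$params)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train))
    losses <- numeric()
    for (s in seq(1L, length(train), by = cfg$batch_size)) {
      e <- min(length(train), s + cfg$batch_size - 1L)
      step <- train_batch(model, train[ord[s:e]], weights, opt_state,
                          cfg$learning_rate, cfg$augment, dataset$floor_db)
      model <- step$model
      opt_state <- step$state
      losses <- c(losses, step$loss)
    }
    vm <- if (length(val)) frame_metrics(model, val) else
      c(recall = NA_real_, precision = NA_real_, f1 = NA_real_)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses),
                                val_recall = vm["recall"],
                                val_precision = vm["precision"],
                                val_f1 = vm["f1"], row.names = NULL))
    track_f1 <- if (is.na(vm["f1"])) -mean(losses) else vm["f1"]
    if (track_f1 >= best$f1) {
      best$f1 <- track_f1
      best$params <- model$params
    }
  }
  model$params <- best$params
  if (!is.null(cfg$checkpoint_path)) save_model(model, cfg$checkpoint_path)
  structure(list(model = model, history = history, class_weights = weights),
            class = "usv_fit")
}

#' @export
print.usv_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<usv_fit> %d epochs; final loss %.4f; best val F1 %.3f\n",
              nrow(x$history), last$loss, max(x$history$val_f1, na.rm = TRUE)))
  invisible(x)
}
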