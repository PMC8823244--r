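test_that("condensation chains calls by gap and pads with context", {
  tab <- label_table(c(0.5, 1.2, 5.0), c(0.6, 1.3, 5.1), "USV")
  clips <- condense_segments(tab, train_config(max_gap = 1))
  expect_equal(nrow(clips), 2L)
  # first clip spans the first pair, second the lone call
  expect_lte(clips$start[1], 0.5); expect_gte(clips$end[1], 1.3)
  expect_lte(clips$start[2], 5.0); expect_gte(clips$end[2], 5.1)
  expect_lt(clips$end[1], clips$start[2])
  expect_equal(nrow(condense_segments(label_table())), 0L)
})

test_that("long chains split into clips within the length bound", {
  set.seed(41)
  on <- cumsum(runif(60, 0.3, 0.8))  # unbroken ~30 s chain (gaps < 1 s)
  tab <- label_table(on, on + 0.2, "USV")
  cfg <- train_config(max_gap = 1)
  clips <- condense_segments(tab, cfg)
  expect_true(all(clips$end - clips$start <= 20 + 1e-9))
  expect_true(all(clips$end - clips$start >= 1 - 1e-9))
})

test_that("every call lies inside exactly one emitted clip", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    on <- sort(runif(n, 0, 60))
    off <- on + runif(n, 0.02, 0.3)
    tab <- label_table(on, off, "USV")
    iv <- merge_label_intervals(tab)
    clips <- condense_segments(tab, train_config())
    covered <- vapply(seq_len(nrow(iv)), function(i)
      sum(clips$start <= iv[i, 1] & clips$end >= iv[i, 2]), 1L)
    expect_true(all(covered == 1L))
    if (nrow(clips) > 1L)
      expect_true(all(clips$start[-1] >= clips$end[-nrow(clips)] - 1e-9))
  }
})

test_that("dataset prevalence equals the frame-label mean and sets weights", {
  clips <- tiny_corpus()
  ds <- assemble_dataset(clips[1:10], clips[11:13])
  direct <- sapply(clips, function(cl) {
    ms <- melspec(cl$wave)
    y <- labels_to_frames(cl$labels, ms$frame_rate, ncol(ms$values))
    c(sum(y), length(y))
  })
  expect_equal(ds$prevalence, sum(direct[1, ]) / sum(direct[2, ]))
  expect_equal(ds$class_weights, c(ds$prevalence, 1 - ds$prevalence))
})

test_that("a 25% USV / 75% background mix yields 0.75/0.25 class weights", {
  # one clip whose call occupies exactly 83 of 332 frames (25%)
  w <- waveform(rep(0, 250000), 250000)
  fr <- 250000 / 754
  lab <- label_table(0, 83 / fr, "USV")
  ds <- assemble_dataset(list(list(wave = w, labels = lab)))
  expect_equal(ds$prevalence, 0.25)
  expect_equal(ds$class_weights, c(0.25, 0.75))  # (background, USV)
})

test_that("adding noise clips strictly decreases USV prevalence", {
  clips <- tiny_corpus()
  ds_no <- assemble_dataset(clips[1:10])
  ds_yes <- assemble_dataset(clips[1:10], clips[11:13])
  expect_lt(ds_yes$prevalence, ds_no$prevalence)
})

test_that("noise clips containing labeled calls are rejected", {
  clips <- tiny_corpus()
  expect_error(assemble_dataset(clips[2:3], clips[1]), "noise clip contains")
})

test_that("training runs, logs history, checkpoints, and is reproducible", {
  clips <- tiny_corpus()
  ds <- assemble_dataset(clips[1:10], clips[11:13])
  ckpt <- withr::local_tempfile(fileext = ".ckpt")
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 3,
                      checkpoint_path = ckpt)
  fit <- train_model(ds, tiny_big_config(), cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_true(file.exists(ckpt))
  expect_true(all(is.finite(fit$history$loss)))
  fit2 <- train_model(ds, tiny_big_config(), cfg)
  expect_equal(fit2$history$loss, fit$history$loss, tolerance = 1e-5)
})

test_that("fine-tuning with learning rate zero leaves the model unchanged", {
  clips <- tiny_corpus()
  ds <- assemble_dataset(clips[1:6], clips[11:12])
  ckpt <- withr::local_tempfile(fileext = ".ckpt")
  fit <- train_model(ds, tiny_big_config(),
                     train_config(epochs = 1, batch_size = 4, seed = 3,
                                  checkpoint_path = ckpt))
  fit0 <- train_model(ds, tiny_big_config(),
                      train_config(epochs = 2, batch_size = 4, seed = 4,
                                   learning_rate = 0, init_checkpoint = ckpt))
  expect_equal(fit0$model$params, fit$model$params, tolerance = 1e-12)
  expect_equal(fit0$history$val_f1[1], fit0$history$val_f1[2])
})

test_that("fine-tuning rejects a mismatched architecture", {
  clips <- tiny_corpus()
  ds <- assemble_dataset(clips[1:6])
  ckpt <- withr::local_tempfile(fileext = ".ckpt")
  save_model(init_model(tiny_model_config()), ckpt)
  expect_error(
    train_model(ds, model_config(), train_config(init_checkpoint = ckpt)),
    "architecture")
})
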