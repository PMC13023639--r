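make_tiny_dataset <- function(dir, n = 8, seed = 5) {
  make_dataset(n, default_params_ranges(64), dir, split = 0.75, seed = seed)
}

test_that("a tiny training run completes and writes a loadable checkpoint", {
  td <- withr::local_tempdir()
  make_tiny_dataset(file.path(td, "ds"))
  cfg <- train_config(lr = 3e-4, weight_decay = 0, epochs = 2, batch_size = 4,
                      seed = 1, augment = FALSE, model_cfg = tiny_model_config())
  r <- octseg_train(file.path(td, "ds"), cfg, out_dir = file.path(td, "run"))
  expect_equal(nrow(r$history), 2)
  expect_true(file.exists(r$checkpoint))
  expect_true(file.exists(file.path(td, "run", "config.yaml")))
  expect_true(file.exists(file.path(td, "run", "train_log.jsonl")))
  lk <- load_checkpoint(r$checkpoint)
  expect_s3_class(lk$config, "model_config")
  # ablation flag recorded in the checkpoint
  cfg2 <- train_config(lr = 3e-4, epochs = 1, batch_size = 4, seed = 1,
                       augment = FALSE,
                       model_cfg = tiny_model_config(rim = FALSE))
  r2 <- octseg_train(file.path(td, "ds"), cfg2, out_dir = file.path(td, "run2"))
  expect_false(load_checkpoint(r2$checkpoint)$config$rim)
})

test_that("training is reproducible under one global seed", {
  td <- withr::local_tempdir()
  make_tiny_dataset(file.path(td, "ds"))
  cfg <- train_config(lr = 3e-4, epochs = 1, batch_size = 4, seed = 7,
                      augment = TRUE, model_cfg = tiny_model_config())
  r1 <- octseg_train(file.path(td, "ds"), cfg)
  r2 <- octseg_train(file.path(td, "ds"), cfg)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
  expect_identical(get_state(r1$model), get_state(r2$model))
})

test_that("empty training split raises an error", {
  td <- withr::local_tempdir()
  make_dataset(2, default_params_ranges(64), file.path(td, "ds"), split = 0,
               seed = 1)
  expect_error(octseg_train(file.path(td, "ds"), train_config(epochs = 1)),
               "empty training split")
})

test_that("evaluating ground truth against itself gives perfect metrics", {
  td <- withr::local_tempdir()
  make_tiny_dataset(file.path(td, "ds"))
  ds <- load_dataset(file.path(td, "ds"))
  oracle <- list(config = NULL)
  # oracle input mode: a "model" that returns the stored mask
  rows <- lapply(Filter(function(it) it$split == "val", ds$items), function(it) {
    d <- it$load()
    evaluate_masks(d$mask, d$mask)
  })
  df <- do.call(rbind, rows)
  expect_true(all(df$dice == 1))
  expect_true(all(df$hd95_px == 0))
  agg <- aggregate_metrics(df)
  expect_equal(agg$dice$mean, 1)
  expect_equal(agg$dice$mean, mean(df$dice))   # aggregate equals column mean
})

test_that("octseg_eval writes per-image CSV and aggregate JSON", {
  td <- withr::local_tempdir()
  make_tiny_dataset(file.path(td, "ds"))
  m <- build_model(tiny_model_config(), seed = 1)
  ev <- octseg_eval(m, file.path(td, "ds"), out_dir = file.path(td, "ev"),
                    split = "val")
  expect_true(file.exists(file.path(td, "ev", "metrics_per_image.csv")))
  expect_true(file.exists(file.path(td, "ev", "metrics_aggregate.json")))
  csv <- utils::read.csv(file.path(td, "ev", "metrics_per_image.csv"))
  expect_equal(ev$aggregate$dice$mean, mean(csv$dice))
  expect_equal(ev$aggregate$n, nrow(csv))
})

test_that("prediction writes filename-matched binary masks idempotently", {
  td <- withr::local_tempdir()
  make_tiny_dataset(file.path(td, "ds"), n = 3)
  ds <- load_dataset(file.path(td, "ds"))
  imgs <- file.path(td, "ds", sapply(ds$manifest$items, function(i) i$image))[1:2]
  m <- build_model(tiny_model_config(), seed = 1)
  r1 <- octseg_predict(m, imgs, file.path(td, "out"))
  expect_true(all(r1$ok))
  expect_true(all(file.exists(r1$output)))
  msk <- octseg:::read_gray_png(r1$output[1])
  expect_equal(dim(msk), c(64, 64))
  expect_true(all(msk %in% c(0, 1)))
  # threshold 0 gives an all-foreground mask
  r0 <- octseg_predict(m, imgs[1], file.path(td, "out0"), threshold = 0)
  expect_true(all(octseg:::read_gray_png(r0$output[1]) == 1))
  # idempotent re-run: byte-identical outputs
  h1 <- tools::md5sum(r1$output[1])
  octseg_predict(m, imgs, file.path(td, "out"))
  expect_identical(tools::md5sum(r1$output[1]), h1)
  # unreadable input: warning and failed status; all-fail is an error
  expect_warning(expect_error(
    octseg_predict(m, file.path(td, "nope.png"), file.path(td, "outx")),
    "all inputs failed"))
})
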