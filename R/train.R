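# Training loop (AdamW, composite loss, early stopping on validation Dice),
# evaluation and prediction entry points.

#' Training configuration
#'
#' @param lr initial AdamW learning rate (default 1e-4)
#' @param weight_decay AdamW decoupled weight decay
#' @param batch_size images per optimisation step
#' @param epochs maximum epochs
#' @param patience early-stopping patience (epochs without validation Dice
#'   improvement)
#' @param seed global seed: controls weight init, data order and augmentation
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay over `epochs`
#' @param mixed_precision accepted for config compatibility; computation is
#'   double precision on CPU, so this flag is recorded but has no effect
#' @param augment apply the augmentation pipeline to training pairs
#' @param augment_cfg an [augment_config()]
#' @param loss_w a [loss_weights()]
#' @param model_cfg a [model_config()]
#' @return named list of class `train_config`
#' @export
train_config <- function(lr = 1e-4, weight_decay = 0.01, batch_size = 2L,
                         epochs = 15L, patience = 10L, seed = 0L,
                         lr_schedule = c("constant", "cosine"),
                         mixed_precision = FALSE, augment = TRUE,
                         augment_cfg = augment_config(),
                         loss_w = loss_weights(),
                         model_cfg = model_config()) {
  lr_schedule <- match.arg(lr_schedule)
  if (lr <= 0) stop("train_config: lr must be > 0")
  if (patience < 1) stop("train_config: patience must be >= 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 lr_schedule = lr_schedule,
                 mixed_precision = mixed_precision, augment = augment,
                 augment_cfg = augment_cfg, loss_w = loss_w,
                 model_cfg = model_cfg),
            class = "train_config")
}

log_line <- function(con, ...) {
  rec <- list(...)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Train a segmentation model on a phantom dataset
#'
#' Optimises the composite loss with AdamW at constant learning rate, logs
#' per-epoch training loss and validation Dice, applies early stopping on
#' validation Dice and keeps the best-by-validation-Dice weights. One seed
#' controls weight initialisation, data order and augmentation draws.
#'
#' @param data_dir dataset directory with `manifest.json` (see [make_dataset()])
#' @param config a [train_config()]
#' @param out_dir output directory for checkpoint, log and resolved config
#'   (`NULL` to skip writing)
#' @return list with `model`, `history` (per-epoch data.frame), `best_epoch`,
#'   `best_val_dice` and `checkpoint` path (or NA)
#' @export
octseg_train <- function(data_dir, config = train_config(), out_dir = NULL) {
  ds <- load_dataset(data_dir)
  train_items <- Filter(function(it) it$split == "train", ds$items)
  val_items <- Filter(function(it) it$split == "val", ds$items)
  if (length(train_items) == 0L) stop("octseg_train: empty training split")
  train_data <- lapply(train_items, function(it) it$load())
  val_data <- lapply(val_items, function(it) it$load())

  model <- build_model(config$model_cfg, seed = config$seed)
  opt <- opt_adamw(collect_params(model), lr = config$lr,
                   weight_decay = config$weight_decay)
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(serialize_config(config), file.path(out_dir, "config.yaml"))
    con <- file(file.path(out_dir, "train_log.jsonl"), open = "w")
    on.exit(close(con), add = TRUE)
  }
  rng_seed <- config$seed + 77L
  history <- data.frame()
  best <- list(dice = -Inf, epoch = NA_integer_, state = NULL)
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    if (identical(config$lr_schedule, "cosine"))
      opt$lr <- config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    ord <- with_seed(rng_seed + epoch, sample.int(length(train_data)))
    ep_loss <- 0; nb <- 0L
    for (bs in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, length(ord))]
      opt_zero_grad(opt)
      bloss <- 0
      ad_with_tape({
        total <- NULL
        for (i in idx) {
          d <- train_data[[i]]
          if (config$augment) {
            a <- augment_pair(d$image, d$mask, config$augment_cfg,
                              seed = rng_seed + 1000L * epoch + i)
            d <- list(image = a$image, mask = a$mask)
          }
          p <- model_forward_node(model, d$image)
          garr <- ad_const(array(d$mask, c(dim(d$mask), 1L)))
          l <- oct_loss(p, garr, config$loss_w)$total
          aux <- attr(p, "aux")
          if (!is.null(aux))   # deep supervision on both heads
            l <- ad_add(l, oct_loss(aux, garr, config$loss_w)$total)
          total <- if (is.null(total)) l else ad_add(total, l)
        }
        total <- ad_cmul(total, 1 / length(idx))
        bloss <- as.numeric(val(total))
        ad_backward(total)
      })
      opt_step(opt)
      ep_loss <- ep_loss + bloss; nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    val_dice <- if (length(val_data)) {
      mean(vapply(val_data, function(d) {
        dice_score((model_forward(model, d$image) > 0.5) * 1, d$mask)
      }, numeric(1)))
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_dice = val_dice))
    log_line(con, event = "epoch", epoch = epoch, train_loss = ep_loss,
             val_dice = val_dice)
    improved <- !is.na(val_dice) && val_dice > best$dice
    if (is.na(val_dice)) improved <- TRUE  # no validation split: keep latest
    if (improved) {
      best <- list(dice = if (is.na(val_dice)) NA_real_ else val_dice,
                   epoch = epoch, state = get_state(model))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (!is.null(best$state)) set_state(model, best$state)
  ck <- NA_character_
  if (!is.null(out_dir)) {
    ck <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(model, ck, extra = list(train_config = serialize_config(config),
                                            best_epoch = best$epoch,
                                            best_val_dice = best$dice))
    utils::write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_dice = best$dice, checkpoint = ck)
}

serialize_config <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

#' Evaluate a model (or checkpoint) on a dataset split
#'
#' Writes a per-image CSV and an aggregate JSON (mean and sd of Dice, IoU and
#' HD95 in pixels and millimetres); images with undefined HD95 (empty
#' prediction or mask) are counted as missing, never scored as zero.
#'
#' @param model_or_ckpt model object or path to a checkpoint file
#' @param data_dir dataset directory
#' @param out_dir output directory (`NULL` to skip writing)
#' @param split which split to evaluate (`"val"`, `"train"` or `"all"`)
#' @param spacing_mm pixel spacing for HD95
#' @param threshold probability threshold
#' @return list with `per_image` data.frame and `aggregate` list
#' @export
octseg_eval <- function(model_or_ckpt, data_dir, out_dir = NULL, split = "val",
                        spacing_mm = 0.005, threshold = 0.5) {
  model <- if (is.character(model_or_ckpt)) load_checkpoint(model_or_ckpt)$model
           else model_or_ckpt
  ds <- load_dataset(data_dir)
  items <- if (split == "all") ds$items
           else Filter(function(it) it$split == split, ds$items)
  if (length(items) == 0L) stop("octseg_eval: no items in split ", split)
  rows <- lapply(items, function(it) {
    d <- it$load()
    pred <- (model_forward(model, d$image) > threshold) * 1
    cbind(id = it$id, evaluate_masks(pred, d$mask, spacing_mm))
  })
  per_image <- do.call(rbind, rows)
  agg <- aggregate_metrics(per_image)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_image, file.path(out_dir, "metrics_per_image.csv"),
                     row.names = FALSE)
    jsonlite::write_json(agg, file.path(out_dir, "metrics_aggregate.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(per_image = per_image, aggregate = agg)
}

#' Predict lumen masks for image files
#'
#' @param model_or_ckpt model object or checkpoint path
#' @param images character vector of grayscale PNG paths
#' @param out_dir output directory for `{0, 255}` mask PNGs (filename-matched,
#'   `<name>_mask.png`)
#' @param threshold probability threshold (0 gives an all-foreground mask)
#' @return data.frame of input/output paths and status
#' @export
octseg_predict <- function(model_or_ckpt, images, out_dir, threshold = 0.5) {
  model <- if (is.character(model_or_ckpt)) load_checkpoint(model_or_ckpt)$model
           else model_or_ckpt
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- lapply(images, function(pth) {
    out <- file.path(out_dir, paste0(sub("\\.[^.]+$", "", basename(pth)), "_mask.png"))
    ok <- tryCatch({
      img <- read_gray_png(pth)
      pm <- model_forward(model, img)
      write_gray_png((pm >= threshold) * 1, out)
      TRUE
    }, error = function(e) { warning("predict failed for ", pth, ": ",
                                     conditionMessage(e)); FALSE })
    data.frame(input = pth, output = out, ok = ok)
  })
  out <- do.call(rbind, res)
  if (nrow(out) > 0 && !any(out$ok)) stop("octseg_predict: all inputs failed")
  out
}

#' Generate a phantom dataset (CLI-facing wrapper over [make_dataset()])
#'
#' @param n number of phantoms
#' @param size image side in pixels
#' @param out output directory
#' @param seed integer seed
#' @param split training fraction
#' @return the manifest, invisibly
#' @export
octseg_simulate <- function(n, size = 512L, out, seed = 0L, split = 0.8) {
  make_dataset(n, default_params_ranges(size), out, split = split, seed = seed)
}
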