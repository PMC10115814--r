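# End-to-end training with Adam, evaluation over a dataset split, mask
# prediction with overlay rendering, and checkpoint I/O.

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$value * 0) # zeros, same shape/dim attrs
  st$v <- st$m
  st$t <- 0L
  st
}

adam_step <- function(params, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  invisible(st)
}

#' Save a model checkpoint
#'
#' Weights go to an RDS file; a JSON sidecar records the variant, seed and a
#' hash of the configuration for provenance.
#'
#' @param model a `dbhnet_model`
#' @param path RDS output path (`<path>.json` sidecar is written next to it)
#' @param extra named list merged into the sidecar (e.g. epoch, val dice)
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(variant = model$variant, config = model$config,
               state = state_dict(model)), path)
  side <- c(list(variant = model$variant,
                 config_hash = digest_cfg(model$config),
                 n_params = as.integer(count_parameters(model))), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

digest_cfg <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  # small rolling hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Load a checkpoint into a freshly built model
#' @param path RDS path from [save_checkpoint()]
#' @return a `dbhnet_model` with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$variant, ck$config)
  rep <- load_state_dict(model, ck$state)
  if (length(rep$missing) || length(rep$shape_mismatch))
    stop("load_checkpoint: incompatible checkpoint (",
         length(rep$missing), " missing, ",
         length(rep$shape_mismatch), " mismatched keys)")
  model
}

batch_dice <- function(pred_mask, gt) {
  cts <- confusion(pred_mask, gt)
  metrics_from_counts(cts)$dice
}

#' Train a model variant on an on-disk dataset
#'
#' Fully seeded end-to-end training: parameter initialization, batch order and
#' everything downstream derive from `config$train$seed`. Per-epoch training
#' loss and validation Dice are logged; the checkpoint with the best
#' validation Dice is kept. A non-finite loss aborts with a diagnostic.
#'
#' @param config configuration from [dbh_config()]
#' @param data_dir dataset directory with a manifest (see [build_dataset()])
#' @param variant model variant name
#' @param out_dir output directory for checkpoints and the log
#' @param epochs optional override of `config$train$epochs`
#' @param verbose print per-epoch lines
#' @return invisibly, a list with the trained `model`, `log` data frame and
#'   `checkpoint` path
#' @export
train <- function(config = dbh_config(), data_dir, variant = "ours",
                  out_dir = tempfile("dbhnet_run_"), epochs = NULL,
                  verbose = TRUE) {
  tc <- config$train
  epochs <- epochs %||% tc$epochs
  if (!file.exists(file.path(data_dir, "manifest.json")))
    stop("train: no manifest.json under ", data_dir,
         " - build the dataset first")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(tc$seed)
  model <- build_model(variant, config)
  params <- collect_params(model)
  opt <- adam_state(params)
  w <- do.call(loss_weights, as.list(tc$loss_weights))
  train_pairs <- load_dataset(data_dir, "train")
  val_pairs <- tryCatch(load_dataset(data_dir, "val"), error = function(e) list())
  n <- length(train_pairs)
  bs <- min(tc$batch_size, n)
  log <- data.frame()
  best <- -Inf
  ck_path <- file.path(out_dir, paste0(variant, "_best.rds"))
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L
    cts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (b in seq_len(ceiling(n / bs))) {
      sel <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      batch <- to_batch(train_pairs[sel])
      zero_grads(params)
      outs <- model_forward(model, batch$x, training = TRUE)
      loss <- model_loss(outs, batch$y, w)
      lv <- as.numeric(tval(loss))
      if (!is.finite(lv))
        stop("train: non-finite loss at epoch ", ep, ", batch ", b,
             " (diverged; lower the learning rate or check the data)")
      dbh_backward(loss)
      adam_step(params, opt, lr = tc$learning_rate,
                weight_decay = tc$weight_decay)
      ep_loss <- ep_loss + lv; nb <- nb + 1L
      bc <- confusion(logits_to_mask(outs[[1]]), batch$y)
      cts <- cts + unlist(bc)
    }
    # training Dice accumulated over the epoch's batches (main head)
    tr_dice <- metrics_from_counts(as.list(cts))$dice
    val_dice <- NA_real_
    if (length(val_pairs)) {
      vb <- to_batch(val_pairs)
      vouts <- with_no_grad(model_forward(model, vb$x, training = FALSE))
      val_dice <- batch_dice(logits_to_mask(vouts[[1]]), vb$y)
    }
    sel_dice <- if (is.na(val_dice)) tr_dice else val_dice
    if (sel_dice > best) {
      best <- sel_dice
      best_state <- state_dict(model)
      best_meta <- list(epoch = ep, val_dice = sel_dice, seed = tc$seed)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                 train_dice = tr_dice, val_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train dice %.3f  val dice %s",
                      ep, ep_loss / nb, tr_dice,
                      if (is.na(val_dice)) "-" else sprintf("%.3f", val_dice)))
  }
  utils::write.csv(log, file.path(out_dir, "train_log.csv"), row.names = FALSE)
  # persist the best-scoring weights once, at the end
  saveRDS(list(variant = variant, config = config, state = best_state), ck_path)
  jsonlite::write_json(
    c(list(variant = variant, config_hash = digest_cfg(config),
           n_params = as.integer(count_parameters(model))), best_meta),
    paste0(ck_path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, log = log, checkpoint = ck_path))
}

#' Evaluate a model or checkpoint over a dataset split
#'
#' Computes the seven metrics per image, writes a CSV (one row per image plus
#' a "mean +/- sd" summary row) and returns the aggregate. Images whose mask
#' size disagrees are reported and skipped; the run continues.
#'
#' @param model a `dbhnet_model` or a checkpoint path
#' @param data_dir dataset directory
#' @param split split name (default `"test"`)
#' @param out_csv optional CSV output path
#' @return list with `rows` (per-image), `aggregate` and `skipped`
#' @export
evaluate <- function(model, data_dir, split = "test", out_csv = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  pairs <- load_dataset(data_dir, split)
  rows <- list(); skipped <- character()
  for (p in pairs) {
    if (!identical(dim(p$image)[1:2], dim(p$mask))) {
      warning("evaluate: size mismatch for ", p$id, "; skipped")
      skipped <- c(skipped, p$id)
      next
    }
    b <- to_batch(list(p))
    outs <- with_no_grad(model_forward(model, b$x, training = FALSE))
    pm <- logits_to_mask(outs[[1]])
    cts <- confusion(pm, b$y)
    rows[[length(rows) + 1L]] <- list(id = p$id, counts = cts,
                                      metrics = metrics_from_counts(cts))
  }
  if (!length(rows)) stop("evaluate: no evaluable pairs in split '", split, "'")
  agg <- aggregate_reports(lapply(rows, `[[`, "metrics"))
  if (!is.null(out_csv)) write_metrics_csv(rows, out_csv)
  list(rows = rows, aggregate = agg, skipped = skipped)
}

#' Overlay a prediction on the ground truth
#'
#' Red marks ground-truth-only pixels, yellow prediction-only pixels, and
#' green their intersection.
#'
#' @param pred,gt binary masks
#' @return H x W x 3 array in 0..255
#' @export
overlay_masks <- function(pred, gt) {
  H <- dim(gt)[1]; W <- dim(gt)[2]
  out <- array(0, c(H, W, 3))
  both <- pred == 1 & gt == 1
  only_gt <- pred == 0 & gt == 1
  only_pred <- pred == 1 & gt == 0
  out[, , 1][only_gt] <- 255                     # red
  out[, , 1][only_pred] <- 255; out[, , 2][only_pred] <- 255 # yellow
  out[, , 2][both] <- 255                        # green
  out
}

#' Predict a lesion mask for one image
#'
#' @param model a `dbhnet_model` or checkpoint path
#' @param image_path input image PNG
#' @param out_path output mask PNG
#' @param gt_path optional ground-truth mask; when given, a red/yellow/green
#'   overlay is written next to `out_path`
#' @return invisibly, the predicted binary mask
#' @export
predict_mask <- function(model, image_path, out_path, gt_path = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!file.exists(image_path)) stop("predict_mask: cannot read ", image_path)
  img <- read_image_png(image_path)
  b <- to_batch(list(list(image = img, mask = matrix(0, dim(img)[1], dim(img)[2]))))
  outs <- with_no_grad(model_forward(model, b$x, training = FALSE))
  pm <- logits_to_mask(outs[[1]])
  mask <- matrix(pm[1, , ], dim(img)[1], dim(img)[2])
  write_mask_png(mask, out_path)
  if (!is.null(gt_path)) {
    gt <- read_mask_png(gt_path)
    ov <- overlay_masks(mask, gt)
    write_image_png(ov, sub("\\.png$", "_overlay.png", out_path))
  }
  invisible(mask)
}
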