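# Pixel-overlap evaluation: confusion counts between binary masks and the
# seven derived metrics (IOU, Dice, accuracy, recall, precision, specificity,
# F1), with per-image and dataset-level aggregation.

#' Pixel-level confusion counts between a predicted and a reference mask
#'
#' @param pred binary predicted mask
#' @param gt binary ground-truth mask of the same shape
#' @return list with integer `tp`, `fp`, `fn`, `tn` (summing to the pixel count)
#' @export
confusion <- function(pred, gt) {
  p <- as.numeric(pred); g <- as.numeric(gt)
  if (length(p) != length(g) ||
      !identical(as.integer(dim(pred) %||% length(p)),
                 as.integer(dim(gt) %||% length(g))))
    stop("confusion: masks differ in shape")
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("confusion: masks must be binary {0,1}")
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  tn <- sum(p == 0 & g == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den) {
  if (den == 0) {
    # degenerate denominator: vacuously perfect when nothing was there to
    # find or reject, otherwise a miss
    return(if (num == 0) 1 else 0)
  }
  num / den
}

#' The seven segmentation metrics from confusion counts
#'
#' IOU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), accuracy, recall, precision,
#' specificity and F1 (harmonic mean of precision and recall). Zero
#' denominators return 1 when the condition is vacuously satisfied (empty
#' truth and empty prediction), else 0.
#'
#' @param c confusion counts from [confusion()]
#' @return named list of the seven metrics, each in `[0, 1]`
#' @export
metrics_from_counts <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  pr <- safe_ratio(tp, tp + fp)
  re <- safe_ratio(tp, tp + fn)
  f1 <- if (pr + re == 0) {
    if (tp + fp + fn == 0) 1 else 0
  } else 2 * pr * re / (pr + re)
  list(
    iou = safe_ratio(tp, tp + fp + fn),
    dice = safe_ratio(2 * tp, 2 * tp + fp + fn),
    acc = safe_ratio(tp + tn, tp + fp + fn + tn),
    recall = re,
    precision = pr,
    specificity = safe_ratio(tn, tn + fp),
    f1 = f1
  )
}

metric_names <- c("iou", "dice", "acc", "recall", "precision",
                  "specificity", "f1")

#' Aggregate per-image metric reports
#'
#' Per-metric mean and population standard deviation (divisor n). The
#' dataset-level F1 is additionally reported as the harmonic mean of the mean
#' precision and mean recall, which is how ablation tables are conventionally
#' assembled and generally differs from the mean per-image Dice.
#'
#' @param reports nonempty list of outputs of [metrics_from_counts()]
#' @return list with `mean`, `sd` (named vectors over the seven metrics),
#'   `dataset_f1`, and `summary` (a "mean +/- sd" character vector)
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stop("aggregate_reports: empty report list")
  m <- vapply(metric_names, function(nm)
    mean(vapply(reports, function(r) r[[nm]], 0)), 0)
  s <- vapply(metric_names, function(nm) {
    v <- vapply(reports, function(r) r[[nm]], 0)
    sqrt(mean((v - mean(v))^2))
  }, 0)
  ds_f1 <- if (m[["precision"]] + m[["recall"]] == 0) 0 else
    2 * m[["precision"]] * m[["recall"]] / (m[["precision"]] + m[["recall"]])
  list(mean = m, sd = s, dataset_f1 = ds_f1,
       summary = sprintf("%.3f ± %.3f", m, s))
}

#' Convert logits to a binary mask
#'
#' Two-channel logits are decided by argmax over channels; single-channel
#' logits by `sigmoid > 0.5` (equivalently logit > 0).
#'
#' @param logits array (batch, channels, H, W), tensor accepted
#' @return binary array (batch, H, W)
#' @export
logits_to_mask <- function(logits) {
  v <- tval(logits)
  d <- dim(v)
  if (d[2] == 1L) {
    out <- (v[, 1L, , , drop = FALSE] > 0) * 1
  } else {
    out <- (v[, 2L, , , drop = FALSE] > v[, 1L, , , drop = FALSE]) * 1
  }
  dim(out) <- d[-2]
  out
}

#' Write per-image metrics and a summary row to CSV
#'
#' One row per image with the seven metrics and the four confusion counts,
#' plus a trailing aggregate row formatted "mean +/- sd".
#'
#' @param rows list of lists with `id`, `counts`, `metrics` entries
#' @param path output CSV path
#' @return invisibly, the data frame written
#' @export
write_metrics_csv <- function(rows, path) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r$id,
               as.data.frame(r$metrics),
               tp = r$counts$tp, fp = r$counts$fp,
               fn = r$counts$fn, tn = r$counts$tn)
  }))
  agg <- aggregate_reports(lapply(rows, `[[`, "metrics"))
  sm <- data.frame(id = "summary",
                   t(stats::setNames(agg$summary, metric_names)),
                   tp = NA, fp = NA, fn = NA, tn = NA)
  names(sm) <- names(df)
  out <- rbind(df, sm)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
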