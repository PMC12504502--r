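# Training losses and evaluation metrics, numeric (non-graph) versions.
# The differentiable counterparts used inside the training graph live in
# autograd-losses.R; tests assert both agree.

#' Mean (or summed) absolute reconstruction error
#'
#' The l1 reconstruction penalty applied to the foreground, background and
#' whole-image reconstructions. Mean reduction keeps the reconstruction and
#' mask losses commensurate under unit weights; `"sum"` gives the
#' unnormalized norm.
#'
#' @param pred,target numeric arrays of one shape.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return nonnegative scalar.
#' @export
l1_loss <- function(pred, target, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    stop("l1_loss: shape mismatch", call. = FALSE)
  }
  s <- sum(abs(pred - target))
  if (reduction == "mean") s / length(pred) else s
}

#' Binary cross-entropy over a probability map
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]`.
#'
#' @param prob numeric array of probabilities.
#' @param target binary array of the same shape.
#' @param eps clamping floor (default `1e-7`).
#' @return nonnegative scalar.
#' @export
bce_loss <- function(prob, target, eps = 1e-7) {
  if (length(prob) != length(target)) stop("bce_loss: shape mismatch", call. = FALSE)
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)`, the un-thresholded
#' overlap penalty; 0 at perfect (binary) agreement, near 1 for disjoint
#' supports.
#'
#' @inheritParams bce_loss
#' @param eps smoothing constant (default `1e-6`).
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(prob, target, eps = 1e-6) {
  if (length(prob) != length(target)) stop("dice_loss: shape mismatch", call. = FALSE)
  1 - (2 * sum(prob * target) + eps) / (sum(prob) + sum(target) + eps)
}

#' Assemble the composite training loss
#'
#' Unit-weight sums: `Lrec = Lf + Lb + Ls`, `Lmask = Lbce + Ldice`,
#' `Ltotal = Lrec + Lmask`. Under the `no_fiir` ablation the reconstruction
#' components are absent and `Ltotal == Lmask`.
#'
#' @param Lf,Lb,Ls foreground / background / whole-image reconstruction
#'   losses; all three `NULL` when the reconstruction branch is disabled.
#' @param Lbce,Ldice segmentation loss components.
#' @param fiir_enabled logical; when `TRUE`, missing reconstruction
#'   components are an error.
#' @return named list of class `batch_losses` with components `Lf`, `Lb`,
#'   `Ls`, `Lrec`, `Lbce`, `Ldice`, `Lmask`, `Ltotal`.
#' @export
total_loss <- function(Lf = NULL, Lb = NULL, Ls = NULL, Lbce, Ldice,
                       fiir_enabled = TRUE) {
  if (fiir_enabled) {
    if (is.null(Lf) || is.null(Lb) || is.null(Ls)) {
      stop("total_loss: reconstruction components missing while the branch is enabled",
           call. = FALSE)
    }
  } else {
    Lf <- 0; Lb <- 0; Ls <- 0
  }
  Lrec <- Lf + Lb + Ls
  Lmask <- Lbce + Ldice
  structure(list(Lf = Lf, Lb = Lb, Ls = Ls, Lrec = Lrec,
                 Lbce = Lbce, Ldice = Ldice, Lmask = Lmask,
                 Ltotal = Lrec + Lmask),
            class = "batch_losses")
}

#' Pixel confusion counts
#'
#' @param pred_mask,gt_mask binary arrays of one shape.
#' @return list with integer `TP`, `FP`, `TN`, `FN`
#'   (`TP + FP + TN + FN == length(gt_mask)`).
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (length(pred_mask) != length(gt_mask)) {
    stop("confusion: shape mismatch", call. = FALSE)
  }
  assert_binary(pred_mask, "pred_mask")
  assert_binary(gt_mask, "gt_mask")
  p <- pred_mask == 1; g <- gt_mask == 1
  list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g), FN = sum(!p & g))
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 `2PR/(P+R)` and IoU
#' `TP/(TP+FP+FN)`. Degenerate cases follow the standard benchmark
#' convention: if both masks are empty all metrics are 1; if `TP = 0` with
#' any positive elsewhere, all are 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion()]).
#' @return named numeric vector `precision`, `recall`, `f1`, `iou`, each in
#'   `[0, 1]`.
#' @export
seg_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (TP == 0) {
    val <- if (FP + FN == 0) 1 else 0
    return(c(precision = val, recall = val, f1 = val, iou = val))
  }
  precision <- TP / (TP + FP)
  recall <- TP / (TP + FN)
  c(precision = precision, recall = recall,
    f1 = 2 * precision * recall / (precision + recall),
    iou = TP / (TP + FP + FN))
}

#' Evaluate a set of predicted masks against ground truth
#'
#' Per-image metrics are averaged arithmetically (the dermoscopy-benchmark
#' convention); the globally pooled variant (one confusion matrix over all
#' pixels) is reported alongside for transparency.
#'
#' @param pairs list of `list(pred = , gt = )` binary masks, optionally
#'   with an `id` element each.
#' @param csv,json optional output paths for the per-image table and the
#'   summary.
#' @return list with `per_image` (data frame: id, precision, recall, f1,
#'   iou), `mean` and `pooled` (named numeric vectors).
#' @export
evaluate_dataset <- function(pairs, csv = NULL, json = NULL) {
  if (!length(pairs)) stop("evaluate_dataset: empty pair list", call. = FALSE)
  per <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    m <- seg_metrics(confusion(pr$pred, pr$gt))
    data.frame(id = if (!is.null(pr$id)) pr$id else sprintf("sample_%03d", k),
               precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], iou = m["iou"], row.names = NULL)
  })
  per <- do.call(rbind, per)
  mean_m <- colMeans(per[, c("precision", "recall", "f1", "iou")])
  pooled_counts <- Reduce(function(a, b) Map(`+`, a, b),
                          lapply(pairs, function(pr) confusion(pr$pred, pr$gt)))
  pooled <- seg_metrics(pooled_counts)
  out <- list(per_image = per, mean = mean_m, pooled = pooled)
  if (!is.null(csv)) utils::write.csv(per, csv, row.names = FALSE)
  if (!is.null(json)) {
    writeLines(metrics_json(mean_m, pooled, nrow(per)), json)
  }
  out
}

metrics_json <- function(mean_m, pooled, n) {
  fmt <- function(v) paste(sprintf('"%s": %.10g', names(v), v), collapse = ", ")
  sprintf('{"n_images": %d, "mean": {%s}, "pooled": {%s}}',
          n, fmt(mean_m), fmt(pooled))
}

#' Error overlay visualization
#'
#' Tint false negatives (missed lesion pixels) green and false positives
#' red over the source image, the standard qualitative-comparison
#' convention.
#'
#' @param pred,gt binary `[1, H, W]` masks.
#' @param image numeric `[3, H, W]` source image.
#' @param strength tint blend weight in `[0, 1]`.
#' @return numeric `[3, H, W]` array.
#' @export
error_overlay <- function(pred, gt, image, strength = 0.5) {
  assert_binary(pred, "pred"); assert_binary(gt, "gt")
  fn <- gt[1, , ] == 1 & pred[1, , ] == 0
  fp <- pred[1, , ] == 1 & gt[1, , ] == 0
  out <- image
  tint <- function(out, where, rgb) {
    for (c in 1:3) {
      plane <- out[c, , ]
      plane[where] <- (1 - strength) * plane[where] + strength * rgb[c]
      out[c, , ] <- plane
    }
    out
  }
  out <- tint(out, fn, c(0, 1, 0))
  out <- tint(out, fp, c(1, 0, 0))
  out
}
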