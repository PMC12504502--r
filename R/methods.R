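# S3 methods for the fitted model.

#' @export
print.mfel <- function(x, ...) {
  np <- sum(vapply(model_params(x$model), function(p) length(p$v), numeric(1)))
  cat(sprintf("<mfel> %s variant, %s px, stages [%s], %d epochs trained, %s parameters\n",
              x$config$ablation, x$config$working_size,
              paste(x$config$stage_channels, collapse = ","),
              x$epochs_done, format(np, big.mark = ",")))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: Ltotal %.4f (Lrec %.4f, Lmask %.4f)\n",
                last$Ltotal, last$Lrec, last$Lmask))
  }
  invisible(x)
}

#' @export
summary.mfel <- function(object, ...) {
  h <- object$history
  structure(list(config = object$config,
                 epochs_done = object$epochs_done,
                 n_train = object$n_train,
                 n_params = sum(vapply(model_params(object$model),
                                       function(p) length(p$v), numeric(1))),
                 first = if (!is.null(h)) h[1, ],
                 last = if (!is.null(h)) h[nrow(h), ]),
            class = "summary.mfel")
}

#' @export
print.summary.mfel <- function(x, ...) {
  cat(sprintf("Dual-task segmentation fit (%s variant)\n", x$config$ablation))
  cat(sprintf("  training: %d samples, %d/%d epochs, batch %d, lr %.1e -> %.1e\n",
              x$n_train, x$epochs_done, x$config$epochs, x$config$batch_size,
              x$config$lr_init, x$config$lr_final))
  cat(sprintf("  parameters: %s\n", format(x$n_params, big.mark = ",")))
  if (!is.null(x$first)) {
    cat(sprintf("  Ltotal: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                x$first$Ltotal, x$last$Ltotal, x$last$epoch))
    cat(sprintf("  final components: Lf %.4f Lb %.4f Ls %.4f Lbce %.4f Ldice %.4f\n",
                x$last$Lf, x$last$Lb, x$last$Ls, x$last$Lbce, x$last$Ldice))
  }
  invisible(x)
}

#' Extract model weights
#'
#' @param object an `mfel` fit.
#' @param ... unused.
#' @return named list of numeric arrays, one per parameter tensor.
#' @export
coef.mfel <- function(object, ...) {
  lapply(model_params(object$model), function(p) p$v)
}

#' Plot the training loss history
#'
#' @param x an `mfel` fit.
#' @param components loss columns to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mfel <- function(x, components = c("Ltotal", "Lrec", "Lmask"), ...) {
  h <- x$history
  if (is.null(h)) stop("no training history to plot", call. = FALSE)
  components <- intersect(components, names(h))
  graphics::matplot(h$epoch, as.matrix(h[, components, drop = FALSE]),
                    type = "l", lty = 1, lwd = 2,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = components, lty = 1, lwd = 2,
                   col = seq_along(components), bty = "n")
  invisible(x)
}

#' Predict segmentation masks
#'
#' Inference-mode forward pass per image (ground-truth masks are never
#' read), probability map, binary mask at `threshold`, and — when the
#' sample carries a mask — an error overlay with false negatives tinted
#' green and false positives red.
#'
#' @param object an `mfel` fit.
#' @param newdata list of `image_sample` objects, or a single numeric
#'   `[3, H, W]` image array.
#' @param threshold binarization threshold.
#' @param out_dir optional directory to write `<id>_pred.png` masks and
#'   `<id>_overlay.png` images.
#' @param ... unused.
#' @return list per image with `id`, `prob`, `mask`, and `overlay` when
#'   ground truth was available.
#' @export
predict.mfel <- function(object, newdata, threshold = 0.5, out_dir = NULL, ...) {
  if (is.array(newdata)) {
    newdata <- list(new_image_sample("image_001", newdata, NULL,
                                     dim(newdata)[2:3]))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lapply(newdata, function(s) {
    prob <- predict_prob(object$model, s$image)
    mask <- binarize_mask(prob >= threshold)
    out <- list(id = s$id, prob = prob, mask = mask)
    if (!is.null(s$mask)) out$overlay <- error_overlay(mask, s$mask, s$image)
    if (!is.null(out_dir)) {
      write_prediction(mask, file.path(out_dir, paste0(s$id, "_pred.png")))
      if (!is.null(out$overlay)) {
        EBImage::writeImage(chw_to_ebimage(out$overlay),
                            file.path(out_dir, paste0(s$id, "_overlay.png")))
      }
    }
    out
  })
}
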