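# Training engine: warm-up + cosine learning-rate schedule, Adam, the
# per-sample gradient-accumulation loop, checkpoint/resume, evaluation and
# batch prediction.

#' Learning rate at a given epoch
#'
#' Linear ramp from `lr_final` to `lr_init` over the warm-up epochs, then
#' cosine annealing back to `lr_final` over the remaining epochs:
#' `lr = lr_final + (lr_init - lr_final)/2 * (1 + cos(pi * t))` with `t`
#' the post-warm-up fraction. Updated once per epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < config$epochs`.
#' @param config an [mfel_config()].
#' @return the learning rate.
#' @export
lr_at <- function(epoch, config) {
  if (epoch < 0 || epoch >= config$epochs) {
    stop("lr_at: epoch ", epoch, " outside [0, ", config$epochs, ")", call. = FALSE)
  }
  w <- config$warmup_epochs
  if (epoch < w) {
    return(config$lr_final + (config$lr_init - config$lr_final) * epoch / w)
  }
  t <- if (config$epochs - 1L == w) 1 else (epoch - w) / (config$epochs - 1L - w)
  config$lr_final + 0.5 * (config$lr_init - config$lr_final) * (1 + cos(pi * t))
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0))
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$g
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  state
}

# build loss graph for one sample; returns list(nodes = named loss nodes,
# total = Ltotal node)
sample_losses_ag <- function(model, sample) {
  cfg <- model$config
  fiir_on <- cfg$ablation != "no_fiir"
  fwd <- model_forward_ag(model, sample$image, sample$mask, training = fiir_on)
  Lbce <- ag_bce(fwd$prob, sample$mask)
  Ldice <- ag_dice(fwd$prob, sample$mask)
  Lmask <- ag_add(Lbce, Ldice)
  if (fiir_on) {
    Lf <- ag_l1(fwd$recon_fore, fwd$foreground, cfg$reduction)
    Lb <- ag_l1(fwd$recon_back, fwd$background, cfg$reduction)
    Ls <- ag_l1(fwd$recon_medical, sample$image, cfg$reduction)
    Lrec <- ag_add(ag_add(Lf, Lb), Ls)
    list(nodes = list(Lf = Lf, Lb = Lb, Ls = Ls, Lrec = Lrec, Lbce = Lbce,
                      Ldice = Ldice, Lmask = Lmask),
         total = ag_add(Lrec, Lmask))
  } else {
    list(nodes = list(Lf = NULL, Lb = NULL, Ls = NULL, Lrec = NULL,
                      Lbce = Lbce, Ldice = Ldice, Lmask = Lmask),
         total = Lmask)
  }
}

loss_components_numeric <- function(ls) {
  out <- c(Lf = 0, Lb = 0, Ls = 0, Lrec = 0, Lbce = 0, Ldice = 0,
           Lmask = 0, Ltotal = 0)
  for (nm in names(ls$nodes)) {
    if (!is.null(ls$nodes[[nm]])) out[nm] <- ls$nodes[[nm]]$v
  }
  out["Ltotal"] <- ls$total$v
  out
}

#' Fit the dual-task segmentation model
#'
#' Trains the configured variant with Adam under the warm-up + cosine
#' schedule, accumulating gradients per sample within each minibatch. The
#' composite loss is the unit-weight sum of the three l1 reconstruction
#' losses (when the reconstruction branch is active) and the BCE + soft
#' Dice segmentation losses. All randomness (initialization, batch
#' shuffling) derives from `config$seed`, so fixed-seed runs are
#' bit-reproducible.
#'
#' @param data list of `image_sample` objects with masks (see
#'   [generate_fixtures()], [read_dataset()]).
#' @param config an [mfel_config()].
#' @param stop_after optionally pause after this many epochs (the returned
#'   fit can be checkpointed and resumed to `config$epochs`).
#' @param resume a fit or checkpoint to continue training from; `data` must
#'   be the same dataset for trajectory-preserving resume.
#' @param verbose print one line per epoch.
#' @return an object of class `mfel`: the trained model, config, per-epoch
#'   loss history (`history`), and bookkeeping needed for resume.
#' @export
mfel_fit <- function(data, config = mfel_config(), stop_after = NULL,
                     resume = NULL, verbose = FALSE) {
  if (!length(data)) stop("mfel_fit: empty dataset", call. = FALSE)
  for (s in data) {
    if (is.null(s$mask)) stop("mfel_fit: sample '", s$id, "' has no mask", call. = FALSE)
  }
  if (is.null(resume)) {
    set.seed(config$seed)
    model <- mfel_model(config)
    params <- model_params(model)
    opt <- adam_init(params)
    start_epoch <- 0L
    history <- NULL
    grad_touched <- NULL
  } else {
    fit <- if (inherits(resume, "mfel")) resume else load_checkpoint(resume)
    model <- fit$model
    config <- fit$config
    params <- model_params(model)
    opt <- fit$optimizer
    start_epoch <- fit$epochs_done
    history <- fit$history
    grad_touched <- fit$grad_touched
    assign(".Random.seed", fit$rng_state, envir = globalenv())
  }
  n <- length(data)
  bs <- min(config$batch_size, n)
  end_epoch <- if (is.null(stop_after)) config$epochs else
    min(config$epochs, as.integer(stop_after))
  epoch <- start_epoch
  while (epoch < end_epoch) {
    lr <- lr_at(epoch, config)
    order <- sample.int(n)
    comp_sum <- NULL
    for (b0 in seq(1L, n, by = bs)) {
      idx <- order[b0:min(b0 + bs - 1L, n)]
      ag_zero_grad(params)
      for (i in idx) {
        ls <- sample_losses_ag(model, data[[i]])
        comps <- loss_components_numeric(ls)
        if (any(!is.finite(comps))) {
          bad <- names(comps)[!is.finite(comps)][1]
          stop("mfel_fit: non-finite loss component ", bad,
               " at epoch ", epoch, call. = FALSE)
        }
        comp_sum <- if (is.null(comp_sum)) comps else comp_sum + comps
        ag_backward(ag_mul_const(ls$total, 1 / length(idx)))
      }
      if (is.null(grad_touched)) {
        grad_touched <- vapply(params, function(p) isTRUE(p$touched), logical(1))
      }
      opt <- adam_step(params, opt, lr)
    }
    epoch <- epoch + 1L
    row <- as.data.frame(as.list(comp_sum / n))
    row <- cbind(data.frame(epoch = epoch, lr = lr), row)
    history <- if (is.null(history)) row else rbind(history, row)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  Ltotal %.4f  Lmask %.4f",
                      epoch, lr, row$Ltotal, row$Lmask))
    }
  }
  structure(list(model = model, config = config, history = history,
                 optimizer = opt, epochs_done = epoch,
                 grad_touched = grad_touched,
                 rng_state = get(".Random.seed", envir = globalenv()),
                 n_train = n),
            class = "mfel")
}

#' Save / load a training checkpoint
#'
#' The checkpoint stores weights, optimizer state, epoch counter, config
#' and RNG state, so `mfel_fit(data, resume = load_checkpoint(path))`
#' continues the exact trajectory of an uninterrupted run.
#'
#' @param fit an `mfel` fit.
#' @param path file path for the serialized checkpoint.
#' @return `path` (save) or an `mfel` object (load).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mfel"))
  params <- model_params(fit$model)
  obj <- list(weights = lapply(params, function(p) p$v),
              optimizer = fit$optimizer,
              epochs_done = fit$epochs_done,
              config = fit$config,
              history = fit$history,
              grad_touched = fit$grad_touched,
              rng_state = fit$rng_state,
              n_train = fit$n_train,
              config_hash = config_hash(fit$config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  rng_save <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  model <- mfel_model(obj$config)   # disturbs RNG; restored just below
  if (!is.null(rng_save)) assign(".Random.seed", rng_save, envir = globalenv())
  params <- model_params(model)
  if (!identical(sort(names(params)), sort(names(obj$weights)))) {
    stop("checkpoint parameter set does not match its config", call. = FALSE)
  }
  for (nm in names(params)) params[[nm]]$v <- obj$weights[[nm]]
  structure(list(model = model, config = obj$config, history = obj$history,
                 optimizer = obj$optimizer, epochs_done = obj$epochs_done,
                 grad_touched = obj$grad_touched, rng_state = obj$rng_state,
                 n_train = obj$n_train),
            class = "mfel")
}

config_hash <- function(config) {
  paste(vapply(config, function(v) paste(format(v), collapse = ","), ""),
        collapse = "|")
}

#' Evaluate a fit on a labeled dataset
#'
#' Inference-mode forward passes (ground-truth masks are never read during
#' prediction), binarization at 0.5, then [evaluate_dataset()]. Samples
#' without masks are predicted but skipped from the metrics, with a
#' warning.
#'
#' @param fit an `mfel` fit (or checkpoint path).
#' @param data list of `image_sample` objects.
#' @param out_dir optional directory for `metrics.csv`, `summary.json` and
#'   predicted masks.
#' @param threshold binarization threshold for the probability maps.
#' @return list with `metrics` (see [evaluate_dataset()]; `NULL` when no
#'   sample had a mask) and `predictions` (per-sample prob map + mask).
#' @export
mfel_evaluate <- function(fit, data, out_dir = NULL, threshold = 0.5) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  stopifnot(inherits(fit, "mfel"))
  if (!length(data)) stop("mfel_evaluate: empty dataset", call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  preds <- lapply(data, function(s) {
    prob <- predict_prob(fit$model, s$image)
    list(id = s$id, prob = prob, mask = binarize_mask(prob >= threshold))
  })
  labeled <- which(!vapply(data, function(s) is.null(s$mask), logical(1)))
  metrics <- NULL
  if (length(labeled) < length(data)) {
    warning(length(data) - length(labeled),
            " sample(s) without ground truth skipped from metrics",
            call. = FALSE)
  }
  if (length(labeled)) {
    pairs <- lapply(labeled, function(k) {
      list(pred = preds[[k]]$mask, gt = data[[k]]$mask, id = data[[k]]$id)
    })
    metrics <- evaluate_dataset(
      pairs,
      csv = if (!is.null(out_dir)) file.path(out_dir, "metrics.csv"),
      json = if (!is.null(out_dir)) file.path(out_dir, "summary.json"))
  }
  if (!is.null(out_dir)) {
    for (p in preds) {
      write_prediction(p$mask, file.path(out_dir, paste0(p$id, "_pred.png")))
    }
  }
  list(metrics = metrics, predictions = preds)
}
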