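# The full dual-branch model: a self-supervised reconstruction branch
# (foreground / background / medical-image encoders + decoders with adaptive
# feature modulation) and a segmentation branch (segmentation encoder,
# per-level bi-directional fusion, multi-branch mamba on the deepest level,
# U-Net-style segmentation head).

ABLATIONS <- c("full", "no_fiir", "afm_summary", "afm_concat",
               "bfm_summary", "bfm_concat", "no_mamba")

#' Training / model configuration
#'
#' Defaults follow the published training regime: 150 epochs, batch 4, Adam
#' with a linear warm-up from 1e-5 to 1e-3 over 5 epochs followed by cosine
#' annealing back down to 1e-5, working resolution 256 (dermoscopy preset;
#' use `preset = "histology"` for 128). The `ablation` switch selects one of
#' the six reduced variants studied alongside the full model: removing the
#' reconstruction branch (`no_fiir`), replacing adaptive feature modulation
#' by elementwise summation or channel concatenation (`afm_summary`,
#' `afm_concat`), replacing bi-directional fusion likewise (`bfm_summary`,
#' `bfm_concat`), or bypassing the mamba block (`no_mamba`).
#'
#' @param epochs,batch_size training length and minibatch size.
#' @param lr_init,lr_final,warmup_epochs learning-rate schedule, see [lr_at()].
#' @param seed integer seed driving initialization and batch shuffling.
#' @param working_size square working resolution in pixels (divisible by 8).
#' @param stage_channels encoder widths per stage (3 integers).
#' @param state_dim state dimension of the selective scan.
#' @param ablation one of `"full"`, `"no_fiir"`, `"afm_summary"`,
#'   `"afm_concat"`, `"bfm_summary"`, `"bfm_concat"`, `"no_mamba"`.
#' @param attention_scale `"sqrt_d"` (default, numerically stabilized) or
#'   `"d"` for the raw printed form of the attention logits' divisor.
#' @param reduction l1 reconstruction reduction, `"mean"` (default, keeps
#'   reconstruction and mask losses commensurate at unit weights) or `"sum"`.
#' @param preset `"dermoscopy"` (256 px) or `"histology"` (128 px); only
#'   sets `working_size` when that is not supplied.
#' @return an object of class `mfel_config`.
#' @export
mfel_config <- function(epochs = 150L, batch_size = 4L,
                        lr_init = 1e-3, lr_final = 1e-5, warmup_epochs = 5L,
                        seed = 1L, working_size = NULL,
                        stage_channels = c(32L, 64L, 128L), state_dim = 16L,
                        ablation = "full", attention_scale = "sqrt_d",
                        reduction = "mean",
                        preset = c("dermoscopy", "histology")) {
  preset <- match.arg(preset)
  if (is.null(working_size)) working_size <- if (preset == "histology") 128L else 256L
  ablation <- match.arg(ablation, ABLATIONS)
  attention_scale <- match.arg(attention_scale, c("sqrt_d", "d"))
  reduction <- match.arg(reduction, c("mean", "sum"))
  epochs <- as.integer(epochs); warmup_epochs <- as.integer(warmup_epochs)
  if (warmup_epochs >= epochs) stop("warmup_epochs must be < epochs", call. = FALSE)
  if (lr_final >= lr_init) stop("lr_final must be < lr_init", call. = FALSE)
  if (working_size %% 8L != 0L) stop("working_size must be divisible by 8", call. = FALSE)
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_final = lr_final,
                 warmup_epochs = warmup_epochs, seed = as.integer(seed),
                 working_size = as.integer(working_size),
                 stage_channels = as.integer(stage_channels),
                 state_dim = as.integer(state_dim), ablation = ablation,
                 attention_scale = attention_scale, reduction = reduction,
                 preset = preset),
            class = "mfel_config")
}

#' Build an untrained model
#'
#' Allocates all parameter tensors for the configured variant (a variant's
#' removed components have no parameters). Initialization uses the current
#' RNG state; seed beforehand for reproducibility.
#'
#' @param config an [mfel_config()].
#' @return an object of class `mfel_model` whose components (`enc_s`,
#'   `enc_r`, `enc_f`, `enc_b`, `dec_f`, `dec_b`, `dec_r`, `afm`, `bfm`,
#'   `mamba`, `head`) can be addressed directly.
#' @export
mfel_model <- function(config = mfel_config()) {
  ch <- config$stage_channels
  ecfg <- encoder_config(3L, ch)
  ab <- config$ablation
  m <- list(config = config)
  m$enc_s <- new_encoder(ecfg)
  m$head <- new_decoder(ecfg, 1L)
  if (ab != "no_mamba") m$mamba <- new_mamba(ch[3], config$state_dim)
  if (ab != "no_fiir") {
    m$enc_r <- new_encoder(ecfg)
    m$enc_f <- new_encoder(ecfg)
    m$enc_b <- new_encoder(ecfg)
    m$dec_f <- new_decoder(ecfg, 3L)
    m$dec_b <- new_decoder(ecfg, 3L)
    m$dec_r <- new_decoder(ecfg, 3L)
    if (ab == "afm_concat") {
      m$afm_cat <- lapply(ch, function(C) new_conv1x1(3L * C, C))
    } else if (ab != "afm_summary") {
      m$afm <- lapply(ch, new_afm)
    }
    if (ab == "bfm_concat") {
      m$bfm_cat <- lapply(ch, function(C) new_conv1x1(2L * C, C))
    } else if (ab != "bfm_summary") {
      m$bfm <- lapply(ch, new_bfm)
    }
  }
  structure(m, class = "mfel_model")
}

# flatten all ag_param nodes of a model into a named list
model_params <- function(x, prefix = "") {
  if (inherits(x, "ag_node")) {
    if (isTRUE(x$is_param)) return(stats::setNames(list(x), prefix))
    return(list())
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (k in seq_along(x)) {
      if (identical(nms[k], "config")) next
      sub <- model_params(x[[k]],
                          if (nzchar(prefix)) paste0(prefix, ".", nms[k]) else nms[k])
      if (length(sub)) out <- c(out, sub)
    }
    return(out)
  }
  list()
}

# calibrated reconstruction pyramid for the active variant (training path)
calibrate_pyramid <- function(model, pyr_f, pyr_b, pyr_r) {
  ab <- model$config$ablation
  lapply(1:3, function(i) {
    if (ab == "afm_summary") {
      ag_add(ag_add(pyr_f[[i]], pyr_b[[i]]), pyr_r[[i]])
    } else if (ab == "afm_concat") {
      cc <- model$afm_cat[[i]]
      ag_conv1x1(ag_concat_ch(list(pyr_f[[i]], pyr_b[[i]], pyr_r[[i]])), cc$W, cc$b)
    } else {
      p <- afm_forward(model$afm[[i]], pyr_f[[i]], pyr_b[[i]], pyr_r[[i]])
      ag_affine_channels(pyr_r[[i]], p$alpha, p$beta)
    }
  })
}

# Reconstruction branch. training = TRUE decomposes by the ground-truth
# mask, runs all three encoders, calibrates per level, and decodes the three
# reconstructions. training = FALSE runs the medical-image encoder only and
# returns its (uncalibrated) pyramid — the mask is never touched.
fiir_forward_ag <- function(model, image_node, mask = NULL, training = FALSE) {
  if (!training) {
    pyr_r <- encoder_forward(model$enc_r, image_node)
    return(list(calibrated_pyramid = pyr_r))
  }
  if (is.null(mask)) {
    stop("fiir_forward: training mode requires the ground-truth mask", call. = FALSE)
  }
  img <- ag_value(image_node)
  dec <- fb_decompose(img, mask)
  pyr_f <- encoder_forward(model$enc_f, ag_const(dec$foreground))
  pyr_b <- encoder_forward(model$enc_b, ag_const(dec$background))
  pyr_r <- encoder_forward(model$enc_r, image_node)
  calib <- calibrate_pyramid(model, pyr_f, pyr_b, pyr_r)
  list(recon_fore = decoder_forward(model$dec_f, pyr_f),
       recon_back = decoder_forward(model$dec_b, pyr_b),
       recon_medical = decoder_forward(model$dec_r, calib),
       calibrated_pyramid = calib,
       foreground = dec$foreground, background = dec$background)
}

#' Run the reconstruction branch
#'
#' In training mode the ground-truth mask splits the image into foreground
#' and background, the three encoders run, each level of the medical-image
#' pyramid is calibrated, and the three reconstructions are decoded. In
#' inference mode only the medical-image encoder runs and its uncalibrated
#' pyramid is returned (calibration is a training-time device: with
#' zero-initialized modulation output layers it starts as the identity, so
#' the segmentation branch sees consistently distributed features in both
#' modes).
#'
#' @param model an [mfel_model()] built with a reconstruction branch.
#' @param image numeric `[3, H, W]` array in `[0, 1]`.
#' @param mask binary `[1, H, W]` array; required when `training = TRUE`.
#' @param training logical.
#' @return list with `calibrated_pyramid` (3 numeric arrays) and, in
#'   training mode, `recon_fore`, `recon_back`, `recon_medical`
#'   (`[3, H, W]` arrays in (0, 1)).
#' @export
fiir_forward <- function(model, image, mask = NULL, training = FALSE) {
  stopifnot(inherits(model, "mfel_model"))
  if (model$config$ablation == "no_fiir") {
    stop("fiir_forward: this model was built without the reconstruction branch",
         call. = FALSE)
  }
  out <- fiir_forward_ag(model, ag_const(image), mask, training)
  out$calibrated_pyramid <- lapply(out$calibrated_pyramid, ag_value)
  for (k in c("recon_fore", "recon_back", "recon_medical")) {
    if (!is.null(out[[k]])) out[[k]] <- ag_value(out[[k]])
  }
  out
}

# Segmentation branch: encoder, per-level fusion with the reconstruction
# pyramid, mamba block on the deepest fused level, decoder head.
fris_forward_ag <- function(model, image_node, rec_pyramid = NULL) {
  cfg <- model$config
  pyr_s <- encoder_forward(model$enc_s, image_node)
  fused <- if (is.null(rec_pyramid)) {
    pyr_s
  } else if (cfg$ablation == "bfm_summary") {
    lapply(1:3, function(i) ag_add(pyr_s[[i]], rec_pyramid[[i]]))
  } else if (cfg$ablation == "bfm_concat") {
    lapply(1:3, function(i) {
      cc <- model$bfm_cat[[i]]
      ag_conv1x1(ag_concat_ch(list(pyr_s[[i]], rec_pyramid[[i]])), cc$W, cc$b)
    })
  } else {
    lapply(1:3, function(i) {
      bfm_forward(model$bfm[[i]], pyr_s[[i]], rec_pyramid[[i]], cfg$attention_scale)
    })
  }
  deep <- if (is.null(model$mamba)) fused[[3]] else mamba_forward(model$mamba, fused[[3]])
  decoder_forward(model$head, list(fused[[1]], fused[[2]], deep))
}

#' Segmentation head over a fused pyramid
#'
#' U-Net-style decoding of the three fused levels (the deepest already
#' passed through the mamba block) to a per-pixel foreground probability.
#'
#' @param model an [mfel_model()].
#' @param fused_pyramid list of 3 numeric feature arrays.
#' @return numeric `[1, H, W]` probability map with values in (0, 1).
#' @export
segmentation_head <- function(model, fused_pyramid) {
  stopifnot(inherits(model, "mfel_model"))
  ag_value(decoder_forward(model$head, lapply(fused_pyramid, ag_const)))
}

# full training/inference graph for one sample; returns nodes
model_forward_ag <- function(model, image, mask = NULL, training = FALSE) {
  cfg <- model$config
  img <- ag_const(image)
  if (cfg$ablation == "no_fiir") {
    prob <- fris_forward_ag(model, img, NULL)
    return(list(prob = prob))
  }
  fi <- fiir_forward_ag(model, img, mask, training)
  prob <- fris_forward_ag(model, img, fi$calibrated_pyramid)
  c(list(prob = prob), fi)
}

# per-pixel probability map for one image (inference path, mask never read)
predict_prob <- function(model, image) {
  ag_value(model_forward_ag(model, image, training = FALSE)$prob)
}
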