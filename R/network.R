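# Network building blocks. Builders allocate parameter nodes (He-initialized
# with the caller's RNG); *_forward functions assemble the differentiable
# graph. Convention: conv features are [C, H, W] arrays, token features
# [L, C] matrices.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_conv3x3 <- function(cin, cout) {
  list(W = ag_param(he_init(c(cout, cin, 3, 3), cin * 9)),
       b = ag_param(rep(0, cout)))
}

new_conv1x1 <- function(cin, cout, zero = FALSE) {
  W <- if (zero) array(0, c(cout, cin)) else he_init(c(cout, cin), cin)
  list(W = ag_param(W), b = ag_param(rep(0, cout)))
}

new_linear <- function(cin, cout, zero = FALSE) new_conv1x1(cin, cout, zero)

new_ln <- function(C) list(g = ag_param(rep(1, C)), b = ag_param(rep(0, C)))

# per-channel instance normalization of a [C,H,W] feature
ag_ln_feat <- function(x, ln) {
  ag_instnorm_channels(x, ln$g, ln$b)
}

# multiply token columns by a per-channel vector node (the SSM skip D)
ag_mul_cols <- function(x, dvec) {
  xv <- x$v; dv <- as.numeric(dvec$v)
  L <- nrow(xv)
  ag_node(xv * rep(dv, each = L), list(x, dvec), function(g) {
    list(g * rep(dv, each = L), colSums(g * xv))
  })
}

ag_as_row <- function(x) {
  n <- length(x$v)
  ag_node(matrix(x$v, 1, n), list(x), function(g) list(as.numeric(g)))
}

ag_as_vec <- function(x) {
  d <- dim(x$v)
  ag_node(as.numeric(x$v), list(x), function(g) list(matrix(g, d[1], d[2])))
}

## ---- encoder ---------------------------------------------------------------

#' Encoder configuration
#'
#' Describes the shared three-stage convolutional encoder architecture used
#' by the foreground, background, medical-image and segmentation encoders
#' (four independent weight sets, one architecture). Each stage applies two
#' 3x3 convolutions (channel layer norm + ReLU after each) and then halves
#' the spatial size, so level `i` of the resulting feature pyramid has shape
#' `[stage_channels[i], H/2^i, W/2^i]`.
#'
#' @param in_channels number of input channels (3 for RGB images).
#' @param stage_channels integer vector of exactly three per-stage widths.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(in_channels = 3L, stage_channels = c(32L, 64L, 128L)) {
  if (length(stage_channels) != 3L) {
    stop("encoder_config: exactly 3 stages are required", call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 stage_channels = as.integer(stage_channels)),
            class = "encoder_config")
}

new_encoder <- function(config) {
  ch <- config$stage_channels
  prev <- config$in_channels
  stages <- vector("list", 3L)
  for (i in 1:3) {
    stages[[i]] <- list(conv_a = new_conv3x3(prev, ch[i]), ln_a = new_ln(ch[i]),
                        conv_b = new_conv3x3(ch[i], ch[i]), ln_b = new_ln(ch[i]))
    prev <- ch[i]
  }
  structure(list(stages = stages, config = config), class = "mfel_encoder")
}

encoder_forward <- function(enc, x) {
  d <- dim(x$v)
  if (d[2] %% 8L != 0L || d[3] %% 8L != 0L) {
    stop("encoder_forward: spatial size must be divisible by 8, got ",
         d[2], "x", d[3], call. = FALSE)
  }
  levels <- vector("list", 3L)
  cur <- x
  for (i in 1:3) {
    st <- enc$stages[[i]]
    cur <- ag_relu(ag_ln_feat(ag_conv3x3(cur, st$conv_a$W, st$conv_a$b), st$ln_a))
    cur <- ag_relu(ag_ln_feat(ag_conv3x3(cur, st$conv_b$W, st$conv_b$b), st$ln_b))
    cur <- ag_avgpool2(cur)
    levels[[i]] <- cur
  }
  levels
}

#' Run one encoder over an image
#'
#' @param encoder an encoder built inside [mfel_model()] or via the internal
#'   builder; pick one of the model's four encoders with `which`.
#' @param image numeric array `[C, H, W]`, `H` and `W` divisible by 8.
#' @return list of 3 numeric arrays (the feature pyramid), level `i` of
#'   shape `[stage_channels[i], H/2^i, W/2^i]`.
#' @export
encode <- function(encoder, image) {
  stopifnot(inherits(encoder, "mfel_encoder"))
  lapply(encoder_forward(encoder, ag_const(image)), ag_value)
}

## ---- decoder ---------------------------------------------------------------

new_decoder <- function(config, out_channels) {
  ch <- config$stage_channels
  structure(list(
    b2 = list(conv_a = new_conv3x3(ch[3] + ch[2], ch[2]), ln_a = new_ln(ch[2]),
              conv_b = new_conv3x3(ch[2], ch[2]), ln_b = new_ln(ch[2])),
    b1 = list(conv_a = new_conv3x3(ch[2] + ch[1], ch[1]), ln_a = new_ln(ch[1]),
              conv_b = new_conv3x3(ch[1], ch[1]), ln_b = new_ln(ch[1])),
    b0 = list(conv_a = new_conv3x3(ch[1], ch[1]), ln_a = new_ln(ch[1])),
    head = new_conv1x1(ch[1], out_channels),
    out_channels = out_channels
  ), class = "mfel_decoder")
}

dec_block <- function(blk, x) {
  x <- ag_relu(ag_ln_feat(ag_conv3x3(x, blk$conv_a$W, blk$conv_a$b), blk$ln_a))
  ag_relu(ag_ln_feat(ag_conv3x3(x, blk$conv_b$W, blk$conv_b$b), blk$ln_b))
}

decoder_forward <- function(dec, pyramid) {
  x <- dec_block(dec$b2, ag_concat_ch(list(ag_upsample2(pyramid[[3]]), pyramid[[2]])))
  x <- dec_block(dec$b1, ag_concat_ch(list(ag_upsample2(x), pyramid[[1]])))
  x <- ag_upsample2(x)
  x <- ag_relu(ag_ln_feat(ag_conv3x3(x, dec$b0$conv_a$W, dec$b0$conv_a$b), dec$b0$ln_a))
  ag_sigmoid(ag_conv1x1(x, dec$head$W, dec$head$b))
}

#' Decode a feature pyramid back to image space
#'
#' Mirror decoder with bilinear x2 upsampling and skip connections from the
#' matching pyramid levels; the bounded (logistic) output keeps values in
#' (0, 1). Reconstruction decoders emit 3 channels, the segmentation head 1.
#'
#' @param decoder a decoder from an [mfel_model()] (e.g. `model$dec_r`).
#' @param pyramid list of 3 numeric feature arrays.
#' @return numeric array `[out_channels, H, W]` with values in (0, 1).
#' @export
decode_reconstruction <- function(decoder, pyramid) {
  stopifnot(inherits(decoder, "mfel_decoder"))
  ag_value(decoder_forward(decoder, lapply(pyramid, ag_const)))
}

## ---- adaptive feature modulation (AFM) -------------------------------------

new_afm <- function(C) {
  structure(list(
    a1 = new_linear(3L * C, C), a2 = new_linear(C, C, zero = TRUE),
    b1 = new_linear(3L * C, C), b2 = new_linear(C, C, zero = TRUE),
    channels = C
  ), class = "mfel_afm")
}

afm_forward <- function(afm, f_fore, f_back, f_rec) {
  u <- ag_as_row(ag_gap(ag_concat_ch(list(f_fore, f_back, f_rec))))
  stream <- function(l1, l2) {
    ag_as_vec(ag_linear(ag_relu(ag_linear(u, l1$W, l1$b)), l2$W, l2$b))
  }
  list(alpha = stream(afm$a1, afm$a2), beta = stream(afm$b1, afm$b2))
}

#' Adaptive feature modulation: calibration parameters
#'
#' Concatenates the foreground, background and reconstruction features of
#' one pyramid level on channels, pools globally, and maps the pooled
#' vector through two parallel streams (1x1 conv, ReLU, 1x1 conv) to the
#' per-channel calibration pair (alpha, beta). The final layers are
#' zero-initialized, so a fresh module emits alpha = beta = 0 and
#' calibration starts as the identity.
#'
#' @param afm an AFM module (e.g. `model$afm[[i]]`).
#' @param f_fore,f_back,f_rec numeric `[C, h, w]` features of equal shape.
#' @return list with numeric vectors `alpha` and `beta` of length `C`.
#' @export
afm_parameters <- function(afm, f_fore, f_back, f_rec) {
  stopifnot(inherits(afm, "mfel_afm"))
  if (!identical(dim(f_fore), dim(f_back)) || !identical(dim(f_fore), dim(f_rec))) {
    stop("afm_parameters: the three features must share one shape", call. = FALSE)
  }
  p <- afm_forward(afm, ag_const(f_fore), ag_const(f_back), ag_const(f_rec))
  list(alpha = ag_value(p$alpha), beta = ag_value(p$beta))
}

#' Apply per-channel calibration `(1 + alpha) * f + beta`
#'
#' @param f_rec numeric `[C, h, w]` reconstruction feature.
#' @param params list with `alpha`, `beta` (length-`C` vectors), as returned
#'   by [afm_parameters()].
#' @return calibrated numeric array of the same shape.
#' @export
afm_calibrate <- function(f_rec, params) {
  if (length(params$alpha) != dim(f_rec)[1]) {
    stop("afm_calibrate: channel counts disagree", call. = FALSE)
  }
  ag_value(ag_affine_channels(ag_const(f_rec), ag_const(params$alpha),
                              ag_const(params$beta)))
}

## ---- bi-directional fusion module (BFM) ------------------------------------

new_bfm <- function(C) {
  structure(list(
    Wqs = ag_param(he_init(c(C, C), C)), Wks = ag_param(he_init(c(C, C), C)),
    Wvs = ag_param(he_init(c(C, C), C)), Wqr = ag_param(he_init(c(C, C), C)),
    Wkr = ag_param(he_init(c(C, C), C)), Wvr = ag_param(he_init(c(C, C), C)),
    out_s = new_linear(C, C), out_r = new_linear(C, C),
    fuse = new_conv1x1(2L * C, C),
    channels = C
  ), class = "mfel_bfm")
}

attn_scale_factor <- function(d, attention_scale) {
  if (identical(attention_scale, "d")) d else sqrt(d)
}

bfm_forward <- function(bfm, f_seg, f_rec, attention_scale = "sqrt_d") {
  d <- dim(f_seg$v)
  S <- ag_feat_to_tokens(f_seg)
  R <- ag_feat_to_tokens(f_rec)
  sc <- attn_scale_factor(bfm$channels, attention_scale)
  Qs <- ag_matmul_t(S, bfm$Wqs); Ks <- ag_matmul_t(S, bfm$Wks)
  Vs <- ag_matmul_t(S, bfm$Wvs)
  Qr <- ag_matmul_t(R, bfm$Wqr); Kr <- ag_matmul_t(R, bfm$Wkr)
  Vr <- ag_matmul_t(R, bfm$Wvr)
  attn_r <- ag_softmax_rows(ag_mul_const(ag_matmul_t(Qs, Kr), 1 / sc))
  attn_s <- ag_softmax_rows(ag_mul_const(ag_matmul_t(Qr, Ks), 1 / sc))
  enh_s <- ag_add(ag_linear(ag_matmul(attn_r, Vr), bfm$out_s$W, bfm$out_s$b), S)
  enh_r <- ag_add(ag_linear(ag_matmul(attn_s, Vs), bfm$out_r$W, bfm$out_r$b), R)
  both <- ag_concat_ch(list(ag_tokens_to_feat(enh_s, d[1], d[2], d[3]),
                            ag_tokens_to_feat(enh_r, d[1], d[2], d[3])))
  ag_conv1x1(both, bfm$fuse$W, bfm$fuse$b)
}

#' Bi-directional cross-attention maps
#'
#' Each stream queries the other: `attn_r = softmax(Qs Kr' / s)` is the
#' segmentation-guided map, `attn_s = softmax(Qr Ks' / s)` the
#' reconstruction-guided map, with `s = sqrt(d)` by default (`s = d` under
#' `attention_scale = "d"`). Every row is a probability distribution.
#'
#' @param bfm a fusion module (e.g. `model$bfm[[i]]`).
#' @param f_seg,f_rec numeric `[C, h, w]` features of equal shape.
#' @param attention_scale `"sqrt_d"` (default) or `"d"`.
#' @return list with row-stochastic matrices `attn_r`, `attn_s` (both
#'   `[h*w, h*w]`) and the head dimension `d`.
#' @export
bfm_attention <- function(bfm, f_seg, f_rec, attention_scale = "sqrt_d") {
  stopifnot(inherits(bfm, "mfel_bfm"))
  if (!identical(dim(f_seg), dim(f_rec))) {
    stop("bfm_attention: features must share one shape", call. = FALSE)
  }
  S <- t(matrix(aperm(f_seg, c(1, 3, 2)), dim(f_seg)[1], prod(dim(f_seg)[2:3])))
  R <- t(matrix(aperm(f_rec, c(1, 3, 2)), dim(f_rec)[1], prod(dim(f_rec)[2:3])))
  sc <- attn_scale_factor(bfm$channels, attention_scale)
  soft <- function(m) { e <- exp(m - apply(m, 1, max)); e / rowSums(e) }
  list(attn_r = soft(tcrossprod(tcrossprod(S, bfm$Wqs$v), tcrossprod(R, bfm$Wkr$v)) / sc),
       attn_s = soft(tcrossprod(tcrossprod(R, bfm$Wqr$v), tcrossprod(S, bfm$Wks$v)) / sc),
       d = bfm$channels)
}

#' Fuse segmentation and reconstruction features
#'
#' Cross-retrieved values are 1x1-convolved and residually added to each
#' stream's own feature; the two enhanced features are concatenated on
#' channels and reduced back to `C` channels by a 1x1 convolution.
#'
#' @inheritParams bfm_attention
#' @param maps attention maps from [bfm_attention()] computed on the same
#'   inputs; recomputed when `NULL`.
#' @return refined segmentation feature, numeric `[C, h, w]`.
#' @export
bfm_fuse <- function(bfm, f_seg, f_rec, maps = NULL, attention_scale = "sqrt_d") {
  stopifnot(inherits(bfm, "mfel_bfm"))
  if (is.null(maps)) maps <- bfm_attention(bfm, f_seg, f_rec, attention_scale)
  d <- dim(f_seg)
  S <- t(matrix(aperm(f_seg, c(1, 3, 2)), d[1], d[2] * d[3]))
  R <- t(matrix(aperm(f_rec, c(1, 3, 2)), d[1], d[2] * d[3]))
  lin <- function(X, l) tcrossprod(X, l$W$v) + rep(l$b$v, each = nrow(X))
  enh_s <- lin(maps$attn_r %*% tcrossprod(R, bfm$Wvr$v), bfm$out_s) + S
  enh_r <- lin(maps$attn_s %*% tcrossprod(S, bfm$Wvs$v), bfm$out_r) + R
  both <- rbind2feat(enh_s, enh_r, d)
  ag_value(ag_conv1x1(ag_const(both), bfm$fuse$W, bfm$fuse$b))
}

# stack two token matrices back into a [2C, h, w] feature
rbind2feat <- function(tok_a, tok_b, d) {
  fa <- aperm(array(t(tok_a), c(d[1], d[3], d[2])), c(1, 3, 2))
  fb <- aperm(array(t(tok_b), c(d[1], d[3], d[2])), c(1, 3, 2))
  out <- array(0, c(2L * d[1], d[2], d[3]))
  out[1:d[1], , ] <- fa
  out[(d[1] + 1L):(2L * d[1]), , ] <- fb
  out
}

## ---- multi-branch vision mamba ---------------------------------------------

new_mamba <- function(C, state_dim = 16L) {
  N <- as.integer(state_dim)
  structure(list(
    ln1 = new_ln(C),
    Wd = new_linear(C, C),
    WB = new_linear(C, N), WC = new_linear(C, N),
    A_log = ag_param(matrix(log(seq_len(N)), C, N, byrow = TRUE)),
    D = ag_param(rep(1, C)),
    gamma = ag_param(1),
    ln2 = new_ln(C),
    proj = new_linear(C, C),
    channels = C, state_dim = N
  ), class = "mfel_mamba")
}

# shared selective-scan branch: M(x) = scan(x) + D * x
ssm_branch <- function(mb, x) {
  delta <- ag_softplus(ag_linear(x, mb$Wd$W, mb$Wd$b))
  B <- ag_linear(x, mb$WB$W, mb$WB$b)
  Cm <- ag_linear(x, mb$WC$W, mb$WC$b)
  A <- ag_neg_exp(mb$A_log)
  ag_add(ag_ssm_core(x, delta, B, Cm, A), ag_mul_cols(x, mb$D))
}

mamba_forward <- function(mb, f_deep) {
  d <- dim(f_deep$v)
  L <- d[2] * d[3]
  if (L %% 4L != 0L) {
    stop("multi-branch mamba: token count ", L, " not divisible by 4", call. = FALSE)
  }
  tok <- ag_layernorm(ag_feat_to_tokens(f_deep), mb$ln1$g, mb$ln1$b)
  q <- L %/% 4L
  outs <- lapply(0:3, function(j) {
    blk <- ag_rows(tok, j * q + 1L, (j + 1L) * q)
    ag_add(ssm_branch(mb, blk), ag_scale_scalar(blk, mb$gamma))
  })
  cat_tok <- ag_layernorm(ag_rowbind(outs), mb$ln2$g, mb$ln2$b)
  ag_tokens_to_feat(ag_linear(cat_tok, mb$proj$W, mb$proj$b), d[1], d[2], d[3])
}

#' Split a token sequence into four contiguous groups
#'
#' @param tokens numeric `[L, C]` matrix with `L` divisible by 4.
#' @return list of four `[L/4, C]` matrices in scan order; `rbind`-ing them
#'   restores the input exactly.
#' @export
split_sequence <- function(tokens) {
  L <- nrow(tokens)
  if (L %% 4L != 0L) {
    stop("split_sequence: sequence length ", L, " not divisible by 4", call. = FALSE)
  }
  q <- L %/% 4L
  lapply(0:3, function(j) tokens[(j * q + 1L):((j + 1L) * q), , drop = FALSE])
}

#' Selective state-space scan
#'
#' Runs the input-dependent (selective) state-space recurrence of the shared
#' Mamba branch over a token sequence: `delta`, `B` and `C` are projected
#' from each token, the state transition is discretized as
#' `exp(delta * A)`, and a learned skip `D * x` is added.
#'
#' @param tokens numeric `[L, C]` matrix (`C` must equal the module width).
#' @param params a mamba module (e.g. `model$mamba`) holding the shared
#'   scan parameters.
#' @return numeric `[L, C]` matrix.
#' @export
ssm_scan <- function(tokens, params) {
  stopifnot(inherits(params, "mfel_mamba"))
  if (any(!is.finite(tokens))) stop("ssm_scan: non-finite input", call. = FALSE)
  ag_value(ssm_branch(params, ag_const(tokens)))
}

#' Multi-branch vision mamba block
#'
#' Flattens the deepest fused feature to a raster token sequence,
#' layer-normalizes, splits it into four contiguous groups, applies the
#' weight-shared selective scan to each with a learnable gamma-scaled
#' residual, concatenates, normalizes and projects back to `[C, h, w]`.
#'
#' @param mamba a mamba module (e.g. `model$mamba`).
#' @param f_deep numeric `[C, h, w]` feature with `h*w` divisible by 4.
#' @return numeric array of the same shape as `f_deep`.
#' @export
multi_branch_mamba <- function(mamba, f_deep) {
  stopifnot(inherits(mamba, "mfel_mamba"))
  ag_value(mamba_forward(mamba, ag_const(f_deep)))
}
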