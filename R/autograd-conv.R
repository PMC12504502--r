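# Spatial ops on [C, H, W] feature arrays. Convolutions are realized as nine
# shifted matrix products (3x3, pad 1) so all heavy lifting stays in BLAS.

pad_hw <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L))
  xp[, 2:(d[2] + 1L), 3:(d[3] + 2L) - 1L] <- x
  xp
}

# cached im2col gather indices for a given input shape
.im2col_cache <- new.env(parent = emptyenv())
im2col_index <- function(C, H, W) {
  key <- paste(C, H, W, sep = "x")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  off_h <- rep(0:2, times = 3)  # matches the [Cout, Cin, 3, 3] kernel layout
  off_w <- rep(0:2, each = 3)
  hh <- rep(seq_len(H), times = W)
  ww <- rep(seq_len(W), each = H)
  kidx <- rep(rep(1:9, each = C), times = H * W)
  nidx <- rep(seq_len(H * W), each = 9L * C)
  cvec <- rep(seq_len(C), times = 9L * H * W)
  hp <- hh[nidx] + off_h[kidx]
  wp <- ww[nidx] + off_w[kidx]
  idx <- cvec + C * ((hp - 1L) + (H + 2L) * (wp - 1L))
  out <- list(idx = idx, off_h = off_h, off_w = off_w)
  .im2col_cache[[key]] <- out
  out
}

# 3x3 same-padding convolution; w has dim [Cout, Cin, 3, 3], b length Cout.
# One im2col gather + one BLAS matmul each way.
ag_conv3x3 <- function(x, w, b) {
  xv <- x$v; wv <- w$v; bv <- b$v
  C <- dim(xv)[1]; H <- dim(xv)[2]; W <- dim(xv)[3]
  Cout <- dim(wv)[1]
  ii <- im2col_index(C, H, W)
  xp <- pad_hw(xv)
  Xcol <- xp[ii$idx]
  dim(Xcol) <- c(9L * C, H * W)
  Wmat <- wv
  dim(Wmat) <- c(Cout, 9L * C)
  Y <- Wmat %*% Xcol + bv
  ag_node(array(Y, c(Cout, H, W)), list(x, w, b), function(g) {
    g2 <- matrix(g, Cout, H * W)
    dw <- tcrossprod(g2, Xcol)
    dim(dw) <- dim(wv)
    dx <- NULL
    if (isTRUE(x$req)) {
      dxcol <- crossprod(Wmat, g2)
      dxp <- array(0, dim(xp))
      for (k in 1:9) {
        rh <- ii$off_h[k] + (1:H); rw <- ii$off_w[k] + (1:W)
        blk <- dxcol[(k - 1L) * C + (1:C), , drop = FALSE]
        dim(blk) <- c(C, H, W)
        dxp[, rh, rw] <- dxp[, rh, rw, drop = FALSE] + blk
      }
      dx <- dxp[, 2:(H + 1L), 2:(W + 1L), drop = FALSE]
    }
    list(dx, dw, rowSums(g2))
  })
}

# 1x1 convolution: pure channel mixing; w [Cout, Cin], b length Cout
ag_conv1x1 <- function(x, w, b) {
  xv <- x$v; wv <- w$v; bv <- b$v
  C <- dim(xv)[1]; H <- dim(xv)[2]; W <- dim(xv)[3]
  Cout <- nrow(wv)
  X <- matrix(xv, C, H * W)
  Y <- wv %*% X + bv
  ag_node(array(Y, c(Cout, H, W)), list(x, w, b), function(g) {
    g2 <- matrix(g, Cout, H * W)
    list(array(crossprod(wv, g2), c(C, H, W)),
         tcrossprod(g2, X),
         rowSums(g2))
  })
}

# 2x2 average pooling, stride 2
ag_avgpool2 <- function(x) {
  xv <- x$v
  d <- dim(xv)
  oh <- seq(1L, d[2], 2L); ow <- seq(1L, d[3], 2L)
  v <- (xv[, oh, ow, drop = FALSE] + xv[, oh + 1L, ow, drop = FALSE] +
        xv[, oh, ow + 1L, drop = FALSE] + xv[, oh + 1L, ow + 1L, drop = FALSE]) / 4
  ag_node(v, list(x), function(g) {
    dx <- array(0, d)
    g4 <- g / 4
    dx[, oh, ow] <- g4; dx[, oh + 1L, ow] <- g4
    dx[, oh, ow + 1L] <- g4; dx[, oh + 1L, ow + 1L] <- g4
    list(dx)
  })
}

# cached x2 bilinear interpolation matrices (align-corners = FALSE)
.up_cache <- new.env(parent = emptyenv())
upsample_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.up_cache[[key]])) return(.up_cache[[key]])
  U <- matrix(0, 2L * n, n)
  for (j in seq_len(2L * n)) {
    s <- (j - 0.5) / 2 + 0.5   # source coordinate, 1-based
    i0 <- floor(s)
    w <- s - i0
    i0c <- min(max(i0, 1L), n)
    i1c <- min(max(i0 + 1L, 1L), n)
    U[j, i0c] <- U[j, i0c] + (1 - w)
    U[j, i1c] <- U[j, i1c] + w
  }
  .up_cache[[key]] <- U
  U
}

ag_upsample2 <- function(x) {
  xv <- x$v
  d <- dim(xv)
  UH <- upsample_matrix(d[2]); UW <- upsample_matrix(d[3])
  v <- array(0, c(d[1], 2L * d[2], 2L * d[3]))
  for (c in seq_len(d[1])) v[c, , ] <- UH %*% xv[c, , ] %*% t(UW)
  ag_node(v, list(x), function(g) {
    dx <- array(0, d)
    for (c in seq_len(d[1])) dx[c, , ] <- crossprod(UH, g[c, , ]) %*% UW
    list(dx)
  })
}

ag_concat_ch <- function(nodes) {
  vs <- lapply(nodes, ag_value)
  cs <- vapply(vs, function(v) dim(v)[1], integer(1))
  d <- dim(vs[[1]])
  out <- array(0, c(sum(cs), d[2], d[3]))
  ends <- cumsum(cs); starts <- ends - cs + 1L
  for (j in seq_along(vs)) out[starts[j]:ends[j], , ] <- vs[[j]]
  ag_node(out, nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , , drop = FALSE])
  })
}

# global average pooling [C,H,W] -> [C]
ag_gap <- function(x) {
  xv <- x$v
  d <- dim(xv)
  n <- d[2] * d[3]
  ag_node(rowMeans(matrix(xv, d[1], n)), list(x), function(g) {
    list(array(rep(g / n, times = n), d))
  })
}

# instance normalization of a [C,H,W] feature: each channel map normalized
# over space (the standard small-batch choice in medical segmentation),
# learnable gain/bias per channel; rowwise on the C x HW matrix view
ag_instnorm_channels <- function(x, gain, bias, eps = 1e-5) {
  xv <- x$v; gv <- gain$v; bv <- bias$v
  d <- dim(xv)
  C <- d[1]; n <- d[2] * d[3]
  X <- xv
  dim(X) <- c(C, n)
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- xhat * gv + bv
  dim(v) <- d
  ag_node(v, list(x, gain, bias), function(g) {
    g2 <- g
    dim(g2) <- c(C, n)
    dxhat <- g2 * gv
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    dim(dx) <- d
    list(dx, rowSums(g2 * xhat), rowSums(g2))
  })
}

# (1 + alpha) * x + beta with alpha, beta per channel (length C)
ag_affine_channels <- function(x, alpha, beta) {
  xv <- x$v; av <- as.numeric(alpha$v); bv <- as.numeric(beta$v)
  d <- dim(xv)
  ag_node((1 + av) * xv + bv, list(x, alpha, beta), function(g) {
    gm <- matrix(g, d[1], d[2] * d[3])
    list(g * (1 + av),
         rowSums(gm * matrix(xv, d[1], d[2] * d[3])),
         rowSums(gm))
  })
}

# [C,H,W] feature <-> [L,C] token matrix, row-major raster
# (token t = (row-1)*W + col)
ag_feat_to_tokens <- function(x) {
  xv <- x$v
  d <- dim(xv)
  v <- t(matrix(aperm(xv, c(1, 3, 2)), d[1], d[2] * d[3]))
  ag_node(v, list(x), function(g) {
    list(aperm(array(t(g), c(d[1], d[3], d[2])), c(1, 3, 2)))
  })
}

ag_tokens_to_feat <- function(x, C, H, W) {
  xv <- x$v
  v <- aperm(array(t(xv), c(C, W, H)), c(1, 3, 2))
  ag_node(v, list(x), function(g) {
    list(t(matrix(aperm(g, c(1, 3, 2)), C, H * W)))
  })
}
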