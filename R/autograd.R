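# Reverse-mode automatic differentiation on dense R arrays.
#
# A node is an environment holding a value `v`, parents, and a backward
# closure `bw(g)` returning one gradient per parent (NULL for parents that
# need none). Graphs are built eagerly by the ops below and freed when the
# last reference to the output node is dropped. Gradients accumulate into
# `$g` on every node that requires them, so calling ag_backward() repeatedly
# (e.g. per sample of a batch) sums gradients — the optimizer zeroes them.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

ag_node <- function(v, parents = list(), bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$parents <- parents
  n$bw <- bw
  n$req <- length(parents) > 0L &&
    any(vapply(parents, function(p) isTRUE(p$req), logical(1)))
  n$g <- NULL
  .ag_env$counter <- .ag_env$counter + 1L
  n$id <- .ag_env$counter
  class(n) <- "ag_node"
  n
}

ag_const <- function(v) ag_node(v)

ag_param <- function(v) {
  n <- ag_node(v)
  n$req <- TRUE
  n$is_param <- TRUE
  n$touched <- FALSE
  n
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$v else x

# coerce plain arrays to constants so forward code can mix both
ag_wrap <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

# Topological order over the subgraph that requires gradients (iterative DFS).
ag_topo <- function(root) {
  order <- vector("list", 64L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = seen)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    kids <- node$parents
    advanced <- FALSE
    i <- top$i
    while (i < length(kids)) {
      i <- i + 1L
      p <- kids[[i]]
      key <- as.character(p$id)
      if (isTRUE(p$req) && !exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        stack[[length(stack)]]$i <- i
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  order[seq_len(n_ord)]
}

# Accumulate gradients of `root` (a scalar node unless `seed` is given)
# into every requiring node's $g.
ag_backward <- function(root, seed = NULL) {
  if (!isTRUE(root$req)) return(invisible(NULL))
  if (is.null(seed)) {
    seed <- if (is.null(dim(root$v))) rep(1, length(root$v)) else array(1, dim(root$v))
  }
  root$g <- if (is.null(root$g)) seed else root$g + seed
  order <- ag_topo(root)
  for (k in rev(seq_along(order))) {
    node <- order[[k]]
    if (is.null(node$bw) || is.null(node$g)) next
    grads <- node$bw(node$g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- grads[[j]]
      if (!isTRUE(p$req) || is.null(gj)) next
      p$g <- if (is.null(p$g)) gj else p$g + gj
      if (isTRUE(p$is_param)) p$touched <- TRUE
    }
    if (!isTRUE(node$is_param)) node$g <- NULL  # free intermediate grads early
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) { p$g <- NULL; p$touched <- FALSE }
  invisible(NULL)
}

## ---- elementwise and scalar ops -------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_mul_const <- function(a, k) {
  ag_node(a$v * k, list(a), function(g) list(g * k))
}

ag_add_const <- function(a, k) {
  ag_node(a$v + k, list(a), function(g) list(g))
}

# multiply tensor by a learnable scalar (length-1 node), e.g. the mamba gamma
ag_scale_scalar <- function(x, s) {
  sv <- as.numeric(s$v); xv <- x$v
  ag_node(xv * sv, list(x, s),
          function(g) list(g * sv, sum(g * xv)))
}

ag_relu <- function(x) {
  xv <- x$v
  ag_node(pmax(xv, 0), list(x), function(g) list(g * (xv > 0)))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_softplus <- function(x) {
  xv <- x$v
  v <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  ag_node(v, list(x), function(g) list(g / (1 + exp(-xv))))
}

# -exp(x); used to keep the state matrix A strictly negative
ag_neg_exp <- function(x) {
  v <- -exp(x$v)
  ag_node(v, list(x), function(g) list(g * v))
}

ag_sum_nodes <- function(nodes) {
  out <- nodes[[1]]
  for (k in seq_along(nodes)[-1]) out <- ag_add(out, nodes[[k]])
  out
}

## ---- matrix ops ------------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

# A %*% t(B)
ag_matmul_t <- function(a, b) {
  av <- a$v; bv <- b$v
  ag_node(tcrossprod(av, bv), list(a, b),
          function(g) list(g %*% bv, crossprod(g, av)))
}

# tokens [L,C] -> [L,Cout] via weight [Cout,C] plus bias [Cout]
ag_linear <- function(x, w, b) {
  xv <- x$v; wv <- w$v; bv <- b$v
  L <- nrow(xv)
  v <- tcrossprod(xv, wv) + rep(bv, each = L)
  ag_node(v, list(x, w, b),
          function(g) list(g %*% wv, crossprod(g, xv), colSums(g)))
}

ag_softmax_rows <- function(x) {
  xv <- x$v
  rmax <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - rmax)
  y <- e / rowSums(e)
  ag_node(y, list(x), function(g) list(y * (g - rowSums(g * y))))
}

# row-wise layer normalization of tokens [L,C] with learnable gain/bias [C]
ag_layernorm <- function(x, gain, bias, eps = 1e-5) {
  xv <- x$v; gv <- gain$v; bv <- bias$v
  L <- nrow(xv); C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- xhat * rep(gv, each = L) + rep(bv, each = L)
  ag_node(v, list(x, gain, bias), function(g) {
    dxhat <- g * rep(gv, each = L)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# contiguous row block [from:to] of a token matrix
ag_rows <- function(x, from, to) {
  xv <- x$v
  L <- nrow(xv)
  ag_node(xv[from:to, , drop = FALSE], list(x), function(g) {
    dx <- matrix(0, L, ncol(xv))
    dx[from:to, ] <- g
    list(dx)
  })
}

ag_rowbind <- function(nodes) {
  vs <- lapply(nodes, ag_value)
  ns <- vapply(vs, nrow, integer(1))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  ag_node(do.call(rbind, vs), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}
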