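# Differentiable loss nodes used inside the training graph. Their numeric
# counterparts (exported to users) live in objectives.R; tests assert the
# two agree.

ag_l1 <- function(pred, target, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  tv <- ag_value(target)
  d <- pred$v - tv
  n <- if (reduction == "mean") length(d) else 1
  ag_node(sum(abs(d)) / n, list(pred), function(g) list(g * sign(d) / n))
}

ag_bce <- function(prob, target, eps = 1e-7) {
  yv <- ag_value(target)
  pv <- prob$v
  pc <- pmin(pmax(pv, eps), 1 - eps)
  n <- length(pv)
  v <- -sum(yv * log(pc) + (1 - yv) * log(1 - pc)) / n
  ag_node(v, list(prob), function(g) {
    inside <- (pv > eps) & (pv < 1 - eps)
    list(g * inside * (pc - yv) / (pc * (1 - pc)) / n)
  })
}

ag_dice <- function(prob, target, eps = 1e-6) {
  yv <- ag_value(target)
  pv <- prob$v
  num <- 2 * sum(pv * yv) + eps
  den <- sum(pv) + sum(yv) + eps
  ag_node(1 - num / den, list(prob), function(g) {
    list(g * (num / den^2 - 2 * yv / den))
  })
}
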