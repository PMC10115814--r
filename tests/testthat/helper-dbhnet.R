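# Shared fixtures: finite-difference gradient checking, a brute-force
# convolution oracle, and small deterministic inputs.

numgrad <- function(fn, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# max |analytic - numeric| gradient discrepancy for a scalar-valued fn(x)
grad_err <- function(fn, x) {
  xt <- dbhnet::dbh_param(x)
  dbhnet::dbh_backward(fn(xt))
  ng <- numgrad(function(v) as.numeric(dbhnet::tval(fn(dbhnet::dbh_param(v)))), x)
  max(abs(xt$grad - ng))
}

# direct quadruple-loop convolution (stride 1, symmetric padding)
conv_brute <- function(x, w, b, pad = 1) {
  d <- dim(x); dw <- dim(w)
  xp <- array(0, c(d[1], d[2], d[3] + 2 * pad, d[4] + 2 * pad))
  xp[, , pad + seq_len(d[3]), pad + seq_len(d[4])] <- x
  y <- array(0, c(d[1], dw[1], d[3], d[4]))
  for (n in seq_len(d[1])) for (co in seq_len(dw[1]))
    for (h in seq_len(d[3])) for (wd in seq_len(d[4])) {
      acc <- b[co]
      for (ci in seq_len(d[2])) for (i in seq_len(dw[3])) for (j in seq_len(dw[4]))
        acc <- acc + xp[n, ci, h + i - 1, wd + j - 1] * w[co, ci, i, j]
      y[n, co, h, wd] <- acc
    }
  y
}

rand4 <- function(n, c, h, w, sd = 1) array(stats::rnorm(n * c * h * w, sd = sd),
                                            c(n, c, h, w))

# explicit softmax(QK'/sqrt(d) + B)V on one window, all heads
dense_attention_oracle <- function(att, x) {
  n <- dim(x)[1]; dimc <- dim(x)[2]; h <- att$heads; dh <- dimc / h
  QKV <- x %*% dbhnet::tval(att$qkv$w) +
    rep(dbhnet::tval(att$qkv$b), each = n)
  O <- matrix(0, n, dimc)
  for (hh in seq_len(h)) {
    sel <- (hh - 1) * dh + seq_len(dh)
    Q <- QKV[, sel]; K <- QKV[, dimc + sel]; V <- QKV[, 2 * dimc + sel]
    B <- matrix(dbhnet::tval(att$bias_table)[att$rel_index, hh], n, n)
    S <- Q %*% t(K) / sqrt(dh) + B
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    O[, sel] <- P %*% V
  }
  O %*% dbhnet::tval(att$proj$w) + rep(dbhnet::tval(att$proj$b), each = n)
}

# tiny synthetic pair
tiny_pair <- function(seed = 1, size = 64) {
  dbhnet::generate_sample(dbhnet::synthetic_config(image_size = size), seed)
}
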