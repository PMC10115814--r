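# Spatial network primitives on NCHW arrays: convolution (im2col + BLAS),
# batch normalization, max pooling, bilinear resampling, softmax cross-entropy.

pad_nchw <- function(x, ph, pw, fill = 0) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2], d[3] + 2L * ph, d[4] + 2L * pw))
  xp[, , ph + seq_len(d[3]), pw + seq_len(d[4])] <- x
  xp
}

# lowered patch matrix: rows index (channel, kernel offset), cols (n, ho, wo)
im2col <- function(x, kh, kw, stride, pad, dil, Ho, Wo) {
  d <- dim(x)
  xp <- pad_nchw(x, pad[1], pad[2])
  N <- d[1]; C <- d[2]
  X2 <- array(0, c(N, C, kh * kw, Ho, Wo))
  for (j in seq_len(kw)) {
    cols <- (seq_len(Wo) - 1L) * stride[2] + (j - 1L) * dil[2] + 1L
    for (i in seq_len(kh)) {
      rows <- (seq_len(Ho) - 1L) * stride[1] + (i - 1L) * dil[1] + 1L
      X2[, , i + (j - 1L) * kh, , ] <- xp[, , rows, cols]
    }
  }
  matrix(aperm(X2, c(2, 3, 1, 4, 5)), C * kh * kw, N * Ho * Wo)
}

conv_out_size <- function(n, k, stride, pad, dil) {
  eff <- (k - 1L) * dil + 1L
  (n + 2L * pad - eff) %/% stride + 1L
}

# 2-D convolution; w: (Cout, Cin, kh, kw), b: (Cout) or NULL
t_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                     dil = c(1L, 1L)) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); dw <- dim(wv)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Co <- dw[1]; kh <- dw[3]; kw <- dw[4]
  if (dw[2] != C) stop("conv2d: input has ", C, " channels, weights expect ", dw[2])
  Ho <- conv_out_size(H, kh, stride[1], pad[1], dil[1])
  Wo <- conv_out_size(W, kw, stride[2], pad[2], dil[2])
  Xm <- im2col(xv, kh, kw, stride, pad, dil, Ho, Wo)
  Wm <- matrix(wv, Co, C * kh * kw)
  Y <- Wm %*% Xm
  if (!is.null(b)) Y <- Y + b$value
  y <- aperm(array(Y, c(Co, N, Ho, Wo)), c(2, 1, 3, 4))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  make_op(y, parents, function(g) {
    G <- matrix(aperm(g, c(2, 1, 3, 4)), Co, N * Ho * Wo)
    gW <- array(tcrossprod(G, Xm), dim(wv))
    gXm <- crossprod(Wm, G)
    gX2 <- aperm(array(gXm, c(C, kh * kw, N, Ho, Wo)), c(3, 1, 2, 4, 5))
    Hp <- H + 2L * pad[1]; Wp <- W + 2L * pad[2]
    gxp <- array(0, c(N, C, Hp, Wp))
    for (j in seq_len(kw)) {
      cols <- (seq_len(Wo) - 1L) * stride[2] + (j - 1L) * dil[2] + 1L
      for (i in seq_len(kh)) {
        rows <- (seq_len(Ho) - 1L) * stride[1] + (i - 1L) * dil[1] + 1L
        sl <- gX2[, , i + (j - 1L) * kh, , , drop = FALSE]
        dim(sl) <- c(N, C, Ho, Wo)
        gxp[, , rows, cols] <- gxp[, , rows, cols, drop = FALSE] + sl
      }
    }
    gx <- gxp[, , pad[1] + seq_len(H), pad[2] + seq_len(W), drop = FALSE]
    if (is.null(b)) list(gx, gW) else list(gx, gW, rowSums(G))
  })
}

# per-(n,c) sums over the spatial axes, then over the batch -> per-channel
channel_sum <- function(v, N, C) {
  m <- matrix(v, N * C)
  colSums(matrix(rowSums(m), N, C))
}

# broadcast a per-channel vector over an NCHW array (values recycle with
# period N*C, matching column-major (N, C, H, W) layout)
channel_bc <- function(vec, N) rep(vec, each = N)

# Batch normalization over (N, H, W) per channel. `state` carries running
# moments for evaluation mode; biased variance is used throughout.
t_bn2d <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  xv <- x$value
  d <- dim(xv); N <- d[1]; C <- d[2]; m <- N * d[3] * d[4]
  if (training) {
    mean_c <- channel_sum(xv, N, C) / m
    xc <- xv - channel_bc(mean_c, N)
    var_c <- channel_sum(xc * xc, N, C) / m
    state$rmean <- (1 - momentum) * state$rmean + momentum * mean_c
    state$rvar <- (1 - momentum) * state$rvar + momentum * var_c
  } else {
    mean_c <- state$rmean
    var_c <- state$rvar
    xc <- xv - channel_bc(mean_c, N)
  }
  inv <- 1 / sqrt(var_c + eps)
  xhat <- xc * channel_bc(inv, N)
  y <- xhat * channel_bc(gamma$value, N) + channel_bc(beta$value, N)
  make_op(y, list(x, gamma, beta), function(g) {
    dgamma <- channel_sum(g * xhat, N, C)
    dbeta <- channel_sum(g, N, C)
    if (training) {
      dxh <- g * channel_bc(gamma$value, N)
      dx <- channel_bc(gamma$value * inv / m, N) *
        (m * g - channel_bc(dbeta, N) - xhat * channel_bc(dgamma, N))
    } else {
      dx <- g * channel_bc(gamma$value * inv, N)
    }
    list(dx, dgamma, dbeta)
  })
}

# 2x2 max pooling with stride 2 (spatial dims must be even)
t_maxpool2 <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[3]; W <- d[4]
  if (H %% 2L || W %% 2L) {
    ax <- if (H %% 2L) "height" else "width"
    stop("maxpool2: ", ax, " is odd (", if (H %% 2L) H else W, ")")
  }
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  sl <- list(
    xv[, , ri, ci, drop = FALSE], xv[, , ri + 1L, ci, drop = FALSE],
    xv[, , ri, ci + 1L, drop = FALSE], xv[, , ri + 1L, ci + 1L, drop = FALSE]
  )
  y <- pmax(sl[[1]], sl[[2]], sl[[3]], sl[[4]])
  make_op(y, list(x), function(g) {
    gx <- array(0, d)
    rem <- array(TRUE, dim(y))
    off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (k in 1:4) {
      hit <- (sl[[k]] == y) & rem
      rem <- rem & !hit
      gx[, , ri + off[[k]][1], ci + off[[k]][2]] <- g * hit
    }
    list(gx)
  })
}

# 3x3 max pooling, stride 2, padding 1 (the fusion module's downsampler)
t_maxpool3s2 <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[3]; W <- d[4]
  Ho <- (H - 1L) %/% 2L + 1L; Wo <- (W - 1L) %/% 2L + 1L
  xp <- pad_nchw(xv, 1L, 1L, fill = -Inf)
  slice <- function(i, j) {
    rows <- (seq_len(Ho) - 1L) * 2L + i
    cols <- (seq_len(Wo) - 1L) * 2L + j
    xp[, , rows, cols, drop = FALSE]
  }
  y <- NULL
  for (j in 1:3) for (i in 1:3) {
    s <- slice(i, j)
    y <- if (is.null(y)) s else pmax(y, s)
  }
  make_op(y, list(x), function(g) {
    gxp <- array(0, dim(xp))
    rem <- array(TRUE, dim(y))
    for (j in 1:3) for (i in 1:3) {
      s <- slice(i, j)
      hit <- (s == y) & rem
      rem <- rem & !hit
      rows <- (seq_len(Ho) - 1L) * 2L + i
      cols <- (seq_len(Wo) - 1L) * 2L + j
      gxp[, , rows, cols] <- gxp[, , rows, cols, drop = FALSE] + g * hit
    }
    list(gxp[, , 1L + seq_len(H), 1L + seq_len(W), drop = FALSE])
  })
}

# interpolation weights for bilinear scaling (half-pixel centers, edges clamped)
.upmat_cache <- new.env(parent = emptyenv())
bilinear_matrix <- function(n_in, scale) {
  key <- paste0(n_in, "x", scale)
  if (!is.null(.upmat_cache[[key]])) return(.upmat_cache[[key]])
  n_out <- as.integer(round(n_in * scale))
  A <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) / scale - 0.5
    i0 <- floor(src)
    tt <- src - i0
    i0c <- min(max(i0, 0), n_in - 1)
    i1c <- min(max(i0 + 1, 0), n_in - 1)
    A[o, i0c + 1] <- A[o, i0c + 1] + (1 - tt)
    A[o, i1c + 1] <- A[o, i1c + 1] + tt
  }
  .upmat_cache[[key]] <- A
  A
}

apply_h <- function(v, A) {
  d <- dim(v)
  ym <- A %*% matrix(aperm(v, c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])
  aperm(array(ym, c(nrow(A), d[1], d[2], d[4])), c(2, 3, 1, 4))
}

apply_w <- function(v, A) {
  d <- dim(v)
  ym <- A %*% matrix(aperm(v, c(4, 1, 2, 3)), d[4], d[1] * d[2] * d[3])
  aperm(array(ym, c(nrow(A), d[1], d[2], d[3])), c(2, 3, 4, 1))
}

# bilinear up/down-sampling by an integer or simple rational factor
t_upsample <- function(x, scale) {
  xv <- x$value
  d <- dim(xv)
  Ah <- bilinear_matrix(d[3], scale)
  Aw <- bilinear_matrix(d[4], scale)
  y <- apply_w(apply_h(xv, Ah), Aw)
  make_op(y, list(x), function(g) {
    list(apply_h(apply_w(g, t(Aw)), t(Ah)))
  })
}

# mean binary cross-entropy with a single logit channel (sigmoid head)
t_bce1 <- function(logits, target) {
  xv <- logits$value
  d <- dim(xv)
  x <- as.numeric(xv)
  tg <- as.numeric(target)
  if (!all(tg %in% c(0, 1))) stop("t_bce1: target mask must be binary {0,1}")
  # stable softplus form: max(x,0) - x*t + log1p(exp(-|x|))
  loss <- mean(pmax(x, 0) - x * tg + log1p(exp(-abs(x))))
  n <- length(x)
  make_op(loss, list(logits), function(g) {
    gx <- (1 / (1 + exp(-x)) - tg) * (as.numeric(g) / n)
    dim(gx) <- d
    list(gx)
  })
}

# mean two-class softmax cross-entropy between logits (N,2,H,W) and a binary
# target (N,H,W); fused forward/backward for stability
t_ce2 <- function(logits, target) {
  xv <- logits$value
  d <- dim(xv)
  if (d[2] != 2L) stop("t_ce2: expected 2 logit channels, got ", d[2])
  tg <- as.numeric(target)
  if (!all(tg %in% c(0, 1))) stop("t_ce2: target mask must be binary {0,1}")
  l0 <- as.numeric(xv[, 1L, , ])
  l1 <- as.numeric(xv[, 2L, , ])
  mx <- pmax(l0, l1)
  logz <- mx + log(exp(l0 - mx) + exp(l1 - mx))
  loss <- mean(logz - ifelse(tg == 1, l1, l0))
  npix <- length(tg)
  make_op(loss, list(logits), function(g) {
    p1 <- exp(l1 - logz)
    gl1 <- (p1 - tg) * (as.numeric(g) / npix)
    gl0 <- -gl1
    gx <- array(0, d)
    gx[, 1L, , ] <- gl0
    gx[, 2L, , ] <- gl1
    list(gx)
  })
}
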