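# Reverse-mode automatic differentiation on dense R arrays.
#
# Tensors are environments holding a value, links to parent tensors and a
# vector-Jacobian-product closure. The graph is dynamic: each op records its
# backward only while gradients are enabled, so evaluation-mode forwards keep
# no graph and intermediate values are garbage-collected as usual.

.dbh <- new.env(parent = emptyenv())
.dbh$grad_enabled <- TRUE

grad_enabled <- function() .dbh$grad_enabled

#' Evaluate an expression without recording gradients
#'
#' Forward passes inside `with_no_grad()` build no autodiff graph, which is
#' both faster and far lighter on memory; use it for inference/evaluation.
#'
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_no_grad <- function(expr) {
  old <- .dbh$grad_enabled
  .dbh$grad_enabled <- FALSE
  on.exit(.dbh$grad_enabled <- old)
  expr
}

new_tensor <- function(value, parents = list(), backward = NULL, requires = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$parents <- parents
  t$backward <- backward
  t$requires <- requires
  t$grad <- NULL
  class(t) <- "dbh_tensor"
  t
}

#' @export
print.dbh_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<dbh_tensor ", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires) " grad" else "", ">\n", sep = "")
  invisible(x)
}

is_tensor <- function(x) inherits(x, "dbh_tensor")

#' Create a trainable parameter tensor
#' @param value numeric array holding the initial value
#' @return a tensor that accumulates gradients
#' @export
dbh_param <- function(value) new_tensor(value, requires = TRUE)

#' Create a constant (non-trainable) tensor
#' @param value numeric array
#' @return a tensor that never receives gradients
#' @export
dbh_const <- function(value) new_tensor(value)

#' Extract the numeric value of a tensor
#' @param x tensor or numeric
#' @return the underlying array
#' @export
tval <- function(x) if (is_tensor(x)) x$value else x

as_tensor <- function(x) if (is_tensor(x)) x else new_tensor(x)

# Record an op node. `backward` maps the output gradient to a list of parent
# gradients (NULL entries for parents that need none).
make_op <- function(value, parents, backward) {
  if (.dbh$grad_enabled &&
      any(vapply(parents, function(p) p$requires, FALSE))) {
    new_tensor(value, parents, backward, requires = TRUE)
  } else {
    new_tensor(value)
  }
}

#' Backpropagate gradients from a scalar (or seeded) tensor
#'
#' Runs reverse-mode accumulation over the recorded graph. Multi-consumer
#' nodes are handled by reference counting so every node's backward fires
#' exactly once, after all of its consumers have contributed.
#'
#' @param root tensor to differentiate (typically a scalar loss)
#' @param grad seed gradient; defaults to ones of `root`'s shape
#' @return invisibly, the root tensor
#' @export
dbh_backward <- function(root, grad = NULL) {
  stopifnot(is_tensor(root))
  if (is.null(grad)) {
    grad <- if (is.null(dim(root$value))) rep(1, length(root$value))
            else array(1, dim(root$value))
  }
  if (!root$requires) return(invisible(root))

  # discover reachable grad-requiring subgraph, counting consumer edges
  nodes <- vector("list", 64L); nn <- 0L
  queue <- list(root)
  root$.seen <- TRUE
  while (length(queue)) {
    node <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- node
    for (p in node$parents) {
      if (!p$requires) next
      p$.pending <- (if (is.null(p$.pending)) 0L else p$.pending) + 1L
      if (is.null(p$.seen)) {
        p$.seen <- TRUE
        queue[[length(queue) + 1L]] <- p
      }
    }
  }

  root$grad <- grad
  ready <- list(root)
  while (length(ready)) {
    node <- ready[[length(ready)]]
    ready[[length(ready)]] <- NULL
    if (!is.null(node$backward) && !is.null(node$grad)) {
      gs <- node$backward(node$grad)
      ps <- node$parents
      for (j in seq_along(ps)) {
        p <- ps[[j]]
        if (!p$requires) next
        g <- gs[[j]]
        if (!is.null(g)) {
          p$grad <- if (is.null(p$grad)) g else p$grad + g
        }
        p$.pending <- p$.pending - 1L
        if (p$.pending == 0L) ready[[length(ready) + 1L]] <- p
      }
      node$grad <- NULL # free interior gradients; leaves keep theirs
    }
  }

  for (i in seq_len(nn)) {
    nodes[[i]]$.seen <- NULL
    nodes[[i]]$.pending <- NULL
  }
  invisible(root)
}

#' Reset accumulated gradients on a list of parameters
#' @param params list of parameter tensors
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementwise ops -------------------------------------------------------

t_add <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  make_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

t_sub <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  make_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

t_mul <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  av <- a$value; bv <- b$value
  make_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a plain scalar
t_smul <- function(a, s) {
  make_op(a$value * s, list(a), function(g) list(g * s))
}

# add a plain (constant) array of the same shape
t_addc <- function(a, cst) {
  make_op(a$value + cst, list(a), function(g) list(g))
}

t_relu <- function(a) {
  av <- a$value
  make_op(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

t_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  make_op(s, list(a), function(g) list(g * s * (1 - s)))
}

# exact (erf-based) GELU: x * pnorm(x)
t_gelu <- function(a) {
  av <- a$value
  make_op(av * stats::pnorm(av), list(a),
          function(g) list(g * (stats::pnorm(av) + av * stats::dnorm(av))))
}

t_mean_all <- function(a) {
  n <- length(a$value)
  d <- dim(a$value)
  make_op(sum(a$value) / n, list(a), function(g) {
    gv <- rep(as.numeric(g) / n, n)
    if (!is.null(d)) dim(gv) <- d
    list(gv)
  })
}

# weighted sum of scalar tensors (convex combination for the joint loss)
t_wsum <- function(tensors, weights) {
  vals <- vapply(tensors, function(t) as.numeric(t$value), 0)
  make_op(sum(vals * weights), tensors,
          function(g) lapply(weights, function(w) as.numeric(g) * w))
}

## ---- shape ops -------------------------------------------------------------

t_reshape <- function(a, newdim) {
  v <- a$value
  olddim <- dim(v)
  dim(v) <- newdim
  make_op(v, list(a), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

# permutation gather: y_flat = x_flat[idx]; idx must be a bijection
t_gather <- function(a, idx, newdim) {
  v <- a$value[idx]
  if (!is.null(newdim)) dim(v) <- newdim
  olddim <- dim(a$value)
  n <- length(a$value)
  make_op(v, list(a), function(g) {
    gx <- numeric(n)
    gx[idx] <- g
    if (!is.null(olddim)) dim(gx) <- olddim
    list(gx)
  })
}

# row lookup with repetition: y = table[idx, ] for a (R x h) table
t_index_rows <- function(table, idx) {
  tv <- table$value
  y <- tv[idx, , drop = FALSE]
  make_op(y, list(table), function(g) {
    gt <- matrix(0, nrow(tv), ncol(tv))
    agg <- rowsum(g, group = idx)
    gt[as.integer(rownames(agg)), ] <- agg
    list(gt)
  })
}

# replicate an array along a new leading axis of size k:
# value at (j, rest) = x[rest]; output dim c(k, dim(x)) flattened
t_rep_each <- function(a, k, newdim = NULL) {
  v <- rep(a$value, each = k)
  if (!is.null(newdim)) dim(v) <- newdim
  olddim <- dim(a$value)
  n <- length(a$value)
  make_op(v, list(a), function(g) {
    gm <- matrix(g, nrow = k, ncol = n)
    gx <- colSums(gm)
    if (!is.null(olddim)) dim(gx) <- olddim
    list(gx)
  })
}

# concatenate NCHW tensors along the channel axis
t_cat_ch <- function(tensors) {
  vals <- lapply(tensors, tval)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[2], 0L)
  out <- array(0, c(d1[1], sum(chans), d1[3], d1[4]))
  at <- 0L
  for (v in vals) {
    cc <- dim(v)[2]
    out[, at + seq_len(cc), , ] <- v
    at <- at + cc
  }
  make_op(out, tensors, function(g) {
    gs <- vector("list", length(chans))
    at <- 0L
    for (i in seq_along(chans)) {
      gs[[i]] <- g[, at + seq_len(chans[i]), , , drop = FALSE]
      at <- at + chans[i]
    }
    gs
  })
}

## ---- linear algebra --------------------------------------------------------

t_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  make_op(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

# y = x %*% w + bias (bias broadcast over rows); x: (m,k), w: (k,n), b: (n)
t_linear <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  y <- xv %*% wv
  if (!is.null(b)) {
    y <- y + rep(b$value, each = nrow(y))
    make_op(y, list(x, w, b), function(g) {
      list(tcrossprod(g, wv), crossprod(xv, g), colSums(g))
    })
  } else {
    make_op(y, list(x, w), function(g) {
      list(tcrossprod(g, wv), crossprod(xv, g))
    })
  }
}

# batched matmul on 3D arrays: A (K,m,p), B (K,p,n) -> (K,m,n);
# tB=TRUE computes A %*% t(B) with B (K,n,p)
t_bmm <- function(a, b, tB = FALSE) {
  av <- a$value; bv <- b$value
  K <- dim(av)[1]; m <- dim(av)[2]
  n <- if (tB) dim(bv)[2] else dim(bv)[3]
  out <- array(0, c(K, m, n))
  for (k in seq_len(K)) {
    A <- matrix(av[k, , ], m)
    B <- matrix(bv[k, , ], dim(bv)[2])
    out[k, , ] <- if (tB) tcrossprod(A, B) else A %*% B
  }
  make_op(out, list(a, b), function(g) {
    ga <- array(0, dim(av)); gb <- array(0, dim(bv))
    for (k in seq_len(K)) {
      G <- matrix(g[k, , ], m)
      A <- matrix(av[k, , ], m)
      B <- matrix(bv[k, , ], dim(bv)[2])
      if (tB) {
        ga[k, , ] <- G %*% B          # Y = A B^T
        gb[k, , ] <- crossprod(G, A)  # dB = G^T A
      } else {
        ga[k, , ] <- tcrossprod(G, B)
        gb[k, , ] <- crossprod(A, G)
      }
    }
    list(ga, gb)
  })
}

# softmax over the last axis of a 3D array
t_softmax3 <- function(a) {
  av <- a$value
  d <- dim(av)
  m <- matrix(av, d[1] * d[2], d[3])
  mx <- m[, 1]
  for (j in seq_len(d[3])[-1]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  pv <- array(p, d)
  make_op(pv, list(a), function(g) {
    gm <- matrix(g, d[1] * d[2], d[3])
    s <- rowSums(gm * p)
    gx <- p * (gm - s)
    dim(gx) <- d
    list(gx)
  })
}

# layer normalization over the columns of a (m, d) matrix
t_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  m <- nrow(xv); d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * rep(gamma$value, each = m) + rep(beta$value, each = m)
  make_op(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxh <- g * rep(gamma$value, each = m)
    s1 <- rowSums(dxh)
    s2 <- rowSums(dxh * xhat)
    dx <- (inv / d) * (d * dxh - s1 - xhat * s2)
    list(dx, dgamma, dbeta)
  })
}
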