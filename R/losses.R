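# Three-head loss: pixel-wise two-class softmax cross-entropy per output head,
# combined as a convex weighted sum (fused head, attention branch,
# convolutional branch).

#' Loss weights for the three output heads
#'
#' @param alpha weight of the fused-decoder loss (default 0.5)
#' @param beta weight of the attention-branch loss (default 0.2)
#' @param gamma weight of the convolutional-branch loss (default 0.3)
#' @return validated `loss_weights` object
#' @export
loss_weights <- function(alpha = 0.5, beta = 0.2, gamma = 0.3) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(w < 0) || any(w > 1))
    stop("loss_weights: each weight must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("loss_weights: weights must sum to 1 (got ", sum(w), ")")
  structure(as.list(w), class = "loss_weights")
}

#' Pixel-wise cross-entropy
#'
#' Mean over pixels of `-[G log p + (1-G) log(1-p)]` where `p` is the
#' foreground probability: a two-class softmax over two logit channels, or a
#' sigmoid in the single-channel configuration.
#'
#' @param logits tensor or array (batch, 2, H, W), or (batch, 1, H, W) for the
#'   sigmoid variant
#' @param mask binary ground truth (batch, H, W) or (H, W)
#' @return scalar loss tensor (use [tval()] for the number)
#' @export
pixel_ce <- function(logits, mask) {
  if (!is_tensor(logits)) logits <- dbh_const(logits)
  m <- as.array(mask)
  dl <- dim(tval(logits))
  if (length(dim(m)) == 2L) dim(m) <- c(1L, dim(m))
  if (!identical(as.integer(dim(m)), as.integer(dl[-2])))
    stop("pixel_ce: mask shape ", paste(dim(m), collapse = "x"),
         " does not match logits ", paste(dl, collapse = "x"))
  if (!all(m %in% c(0, 1))) stop("pixel_ce: mask must be binary {0,1}")
  if (dl[2] == 1L) t_bce1(logits, m) else t_ce2(logits, m)
}

#' Weighted total of the three head losses
#'
#' `L = alpha * L_ff + beta * L_st + gamma * L_u`.
#'
#' @param l_ff,l_st,l_u scalar losses (tensors or numbers)
#' @param w a [loss_weights()] object
#' @return scalar tensor
#' @export
total_loss <- function(l_ff, l_st, l_u, w = loss_weights()) {
  if (!inherits(w, "loss_weights")) w <- do.call(loss_weights, as.list(w))
  parts <- lapply(list(l_ff, l_st, l_u), as_tensor)
  t_wsum(parts, c(w$alpha, w$beta, w$gamma))
}
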