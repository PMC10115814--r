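# Attention-gated fusion decoder: starting from the deepest fusion output,
# the decoder state is upsampled x2, channel-aligned to the next fusion
# feature, gated by an additive attention map, and finally decoded by three
# convolution units and a x4 bilinear interpolation to full resolution.

# channel-broadcast multiply: a (N,C,H,W) scaled by a single-channel gate
t_mul_gate <- function(a, g) {
  av <- a$value; gv <- g$value
  d <- dim(av)
  N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  idx <- rep(seq_len(N), times = C) + rep((seq_len(HW) - 1L) * N, each = N * C)
  ge <- gv[idx]
  dim(ge) <- d
  make_op(av * ge, list(a, g), function(grad) {
    gsum <- colSums(matrix(aperm(array(grad * av, c(N, C, HW)), c(2, 1, 3)), C))
    dim(gsum) <- dim(gv)
    list(grad * ge, gsum)
  })
}

nn_att_gate <- function(c_up, c_skip, per_channel = FALSE) {
  gate_ch <- if (per_channel) c_skip else 1L
  m <- list(
    proj = nn_conv2d(c_up, c_skip, k = 1L),
    w_f = nn_conv2d(c_skip, c_skip, k = 1L),
    w_up = nn_conv2d(c_skip, c_skip, k = 1L),
    sig_conv = nn_conv2d(c_skip, gate_ch, k = 1L),
    sig_bn = nn_bn2d(gate_ch),
    per_channel = per_channel
  )
  class(m) <- c("nn_att_gate", "dbh_module")
  m
}

#' Attention-gated combination of a fusion feature and the decoder state
#'
#' The decoder state is bilinearly upsampled x2 and 1x1-projected to the
#' fusion feature's width; `T = ReLU(W_f(ff) + W_up(aligned))`; the gate is
#' `Sigmoid(BN(1x1 conv(T)))`, a single channel broadcast multiplicatively
#' onto the aligned decoder state.
#'
#' @param gate gate module
#' @param ff_i fusion feature at scale i
#' @param up_next decoder state at scale i+1 (half the spatial size)
#' @param training logical
#' @return gated decoder state at scale i, with `ff_i`'s channel count
#' @export
attention_gate <- function(gate, ff_i, up_next, training = FALSE) {
  if (!is_tensor(ff_i)) ff_i <- dbh_const(ff_i)
  if (!is_tensor(up_next)) up_next <- dbh_const(up_next)
  df <- dim(tval(ff_i)); du <- dim(tval(up_next))
  if (df[3] != 2L * du[3] || df[4] != 2L * du[4])
    stop("attention_gate: decoder state must be exactly half the skip's ",
         "spatial size (skip ", df[3], "x", df[4], ", state ", du[3], "x",
         du[4], ")")
  aligned <- fwd(gate$proj, t_upsample(up_next, 2), training)
  tmap <- t_relu(t_add(fwd(gate$w_f, ff_i, training),
                       fwd(gate$w_up, aligned, training)))
  gmap <- t_sigmoid(fwd(gate$sig_bn, fwd(gate$sig_conv, tmap, training),
                        training))
  if (isTRUE(gate$per_channel)) t_mul(aligned, gmap)
  else t_mul_gate(aligned, gmap)
}

#' Build the attention-gated decoder
#' @param C pyramid base width
#' @param n_classes logit channels
#' @param per_channel_gate gate each channel separately instead of the classic
#'   single broadcast gate
#' @return a module
#' @export
nn_gated_decoder <- function(C = 96L, n_classes = 2L,
                             per_channel_gate = FALSE) {
  dims <- C * 2L^(0:3)
  half <- max(C %/% 2L, n_classes)
  m <- list(
    g3 = nn_att_gate(dims[4], dims[3], per_channel_gate),
    g2 = nn_att_gate(dims[3], dims[2], per_channel_gate),
    g1 = nn_att_gate(dims[2], dims[1], per_channel_gate),
    h1 = nn_cbr(dims[1], half),
    h2 = nn_cbr(half, half),
    h3 = nn_cbr(half, half),
    head = nn_conv2d(half, n_classes, k = 1L)
  )
  class(m) <- c("nn_gated_decoder", "dbh_module")
  m
}

#' Decode the four fusion features to segmentation logits
#'
#' The decoder state starts as `ff_4` (no convolution, plain interpolation
#' only); each gate upsamples it x2, aligns channels and gates it against the
#' next-shallower fusion feature (scales 3, 2, 1); the result passes three
#' convolution units (3x3 conv + BN + ReLU), a 1x1 logit projection and a x4
#' bilinear interpolation to input resolution.
#'
#' @param dec module from [nn_gated_decoder()]
#' @param ff_list fusion features `ff_1..ff_4`
#' @param training logical
#' @return logits at input resolution
#' @export
gated_decode <- function(dec, ff_list, training = FALSE) {
  ff4 <- ff_list[[4]]
  if (!is_tensor(ff4)) ff4 <- dbh_const(ff4)
  up <- ff4
  up <- attention_gate(dec$g3, ff_list[[3]], up, training)
  up <- attention_gate(dec$g2, ff_list[[2]], up, training)
  up <- attention_gate(dec$g1, ff_list[[1]], up, training)
  x <- fwd(dec$h3, fwd(dec$h2, fwd(dec$h1, up, training), training), training)
  t_upsample(fwd(dec$head, x, training), 4)
}
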