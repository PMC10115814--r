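# Deep Feature Aggregation decoder: receptive-field-block refinement of the
# three deepest pyramid levels to 48 channels, two multiplicative/concatenating
# aggregation steps at 1/8 scale, and a convolutional head upsampled x8 to
# full-resolution logits. One instance serves as the lightweight decoder of
# either branch.

#' Build a 48-channel receptive field block
#'
#' Multi-branch dilated refinement: a 1x1 branch plus, for each dilation rate
#' in `dilations[-1]`, a 1x1 reduction, a pair of 1xk/kx1 convolutions and a
#' 3x3 convolution dilated at that rate; branch outputs are concatenated,
#' merged by a 3x3 convolution and combined with a 1x1 residual shortcut.
#'
#' @param cin input channels
#' @param channels output channels (default 48)
#' @param dilations dilation schedule; default `c(1, 3, 5, 7)`
#' @return a module
#' @export
nn_rfb48 <- function(cin, channels = 48L, dilations = c(1L, 3L, 5L, 7L)) {
  rates <- dilations[dilations > 1L]
  branches <- lapply(rates, function(r) {
    list(reduce = nn_cbr(cin, channels, k = 1L),
         kx = nn_cbr(channels, channels, k = c(1L, r)),
         ky = nn_cbr(channels, channels, k = c(r, 1L)),
         dil = nn_cbr(channels, channels, k = 3L, dil = r))
  })
  names(branches) <- paste0("r", rates)
  m <- list(
    b0 = nn_cbr(cin, channels, k = 1L),
    branches = branches,
    merge = nn_cbr((length(rates) + 1L) * channels, channels),
    shortcut = nn_cbr(cin, channels, k = 1L, relu = FALSE)
  )
  class(m) <- c("nn_rfb48", "dbh_module")
  m
}

#' Apply a receptive field block
#' @param mod module from [nn_rfb48()]
#' @param x input tensor (any spatial size)
#' @param training logical
#' @return tensor with the block's channel count, same spatial size
#' @export
rfb48 <- function(mod, x, training = FALSE) {
  if (!is_tensor(x)) x <- dbh_const(x)
  outs <- list(fwd(mod$b0, x, training))
  for (br in mod$branches) {
    y <- fwd(br$reduce, x, training)
    y <- fwd(br$ky, fwd(br$kx, y, training), training)
    outs[[length(outs) + 1L]] <- fwd(br$dil, y, training)
  }
  merged <- fwd(mod$merge, t_cat_ch(outs), training)
  t_relu(t_add(merged, fwd(mod$shortcut, x, training)))
}

#' Aggregate the three refined deep features
#'
#' `AD1 = concat[ Up2( Up2(F3') * F2' ), Up4(F3') ]` and
#' `AD2 = concat[ Up2(F2') * F1', AD1 ]`, all products elementwise, product
#' term first in each concatenation; both aggregates live at 1/8 scale.
#'
#' @param f1p,f2p,f3p refined features at scales 1/8, 1/16, 1/32 with equal
#'   channel counts
#' @return list with tensors `ad1` (2x channels) and `ad2` (3x channels)
#' @export
aggregation_decode <- function(f1p, f2p, f3p) {
  if (!is_tensor(f1p)) f1p <- dbh_const(f1p)
  if (!is_tensor(f2p)) f2p <- dbh_const(f2p)
  if (!is_tensor(f3p)) f3p <- dbh_const(f3p)
  c1 <- dim(tval(f1p))[2]; c2 <- dim(tval(f2p))[2]; c3 <- dim(tval(f3p))[2]
  if (c1 != c2 || c2 != c3)
    stop("aggregation_decode: refined features must share channels, got ",
         c1, "/", c2, "/", c3)
  prod1 <- t_mul(t_upsample(f3p, 2), f2p)              # 1/16
  ad1 <- t_cat_ch(list(t_upsample(prod1, 2), t_upsample(f3p, 4))) # 1/8
  prod2 <- t_mul(t_upsample(f2p, 2), f1p)              # 1/8
  ad2 <- t_cat_ch(list(prod2, ad1))
  list(ad1 = ad1, ad2 = ad2)
}

#' Build the aggregation decoder
#'
#' @param in_channels channel counts of the three deepest pyramid levels
#'   (scales 1/8, 1/16, 1/32); default matches C = 96
#' @param channels refinement width (default 48)
#' @param dilations dilation schedule of the receptive field blocks
#' @param n_classes logit channels
#' @return a module
#' @export
dfa_decoder <- function(in_channels = c(192L, 384L, 768L), channels = 48L,
                        dilations = c(1L, 3L, 5L, 7L), n_classes = 2L) {
  m <- list(
    rfb1 = nn_rfb48(in_channels[1], channels, dilations),
    rfb2 = nn_rfb48(in_channels[2], channels, dilations),
    rfb3 = nn_rfb48(in_channels[3], channels, dilations),
    h1 = nn_cbr(3L * channels, channels),
    h2 = nn_conv2d(channels, n_classes)
  )
  class(m) <- c("dfa_decoder", "dbh_module")
  m
}

#' Head of the aggregation decoder
#'
#' Two 3x3 convolutions (BN + ReLU on the first) reducing to the logit
#' channels, then bilinear x8 upsampling to input resolution.
#'
#' @param dfa module from [dfa_decoder()]
#' @param ad2 aggregate at 1/8 scale
#' @param training logical
#' @return full-resolution logits
#' @export
dfa_head <- function(dfa, ad2, training = FALSE) {
  if (!is_tensor(ad2)) ad2 <- dbh_const(ad2)
  t_upsample(fwd(dfa$h2, fwd(dfa$h1, ad2, training), training), 8)
}

#' Full aggregation-decoder pass over a feature pyramid
#'
#' Refines pyramid levels 2-4 (scales 1/8..1/32), aggregates, and decodes to
#' full-resolution segmentation logits.
#'
#' @param dfa module from [dfa_decoder()]
#' @param pyramid list of 4 tensors (the FeaturePyramid contract)
#' @param training logical
#' @return logits at input resolution
#' @export
dfa_forward <- function(dfa, pyramid, training = FALSE) {
  f1p <- rfb48(dfa$rfb1, pyramid[[2]], training)
  f2p <- rfb48(dfa$rfb2, pyramid[[3]], training)
  f3p <- rfb48(dfa$rfb3, pyramid[[4]], training)
  ag <- aggregation_decode(f1p, f2p, f3p)
  dfa_head(dfa, ag$ad2, training)
}
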