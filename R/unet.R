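# Convolutional branch: a five-unit encoder whose last four outputs form the
# shared four-scale feature pyramid, plus the classic symmetric decoder used
# by the stand-alone convolutional baseline.
#
# Each unit is (3x3 conv + BN + ReLU) x2 followed by a 2x2 max-pool, so unit i
# emits spatial scale 1/2^i. With base width 48 the units emit
# 48, 96, 192, 384, 768 channels; units 2-5 give the pyramid scales
# 1/4, 1/8, 1/16, 1/32 with C, 2C, 4C, 8C channels (C = 96).

#' Build one encoder convolution unit
#'
#' Two 3x3 stride-1 convolutions (each with batch normalization and ReLU)
#' followed by a 2x2 max-pool that halves the spatial size.
#'
#' @param cin,cout input/output channel counts
#' @return a module
#' @export
conv_unit <- function(cin, cout) {
  m <- list(c1 = nn_cbr(cin, cout), c2 = nn_cbr(cout, cout))
  class(m) <- c("conv_unit", "dbh_module")
  m
}

#' Forward pass of a convolution unit
#'
#' @param unit module from [conv_unit()]
#' @param x input tensor, NCHW with even spatial dims
#' @param training logical
#' @return tensor with `cout` channels at half the spatial size
#' @export
conv_unit_forward <- function(unit, x, training = FALSE) {
  d <- dim(tval(x))
  if (d[3] %% 2L) stop("conv_unit_forward: height ", d[3], " is odd")
  if (d[4] %% 2L) stop("conv_unit_forward: width ", d[4], " is odd")
  t_maxpool2(fwd(unit$c2, fwd(unit$c1, x, training), training))
}

#' @export
fwd.conv_unit <- function(mod, x, training = FALSE, ...) {
  conv_unit_forward(mod, x, training)
}

#' Build the five-unit convolutional encoder
#'
#' @param base_channels width of the first unit (default 48, i.e. C/2 for
#'   the default pyramid width C = 96)
#' @param in_channels input image channels
#' @return a module with units `u1..u5`
#' @export
unet_encoder <- function(base_channels = 48L, in_channels = 3L) {
  ch <- base_channels * 2L^(0:4)
  m <- list(
    u1 = conv_unit(in_channels, ch[1]),
    u2 = conv_unit(ch[1], ch[2]),
    u3 = conv_unit(ch[2], ch[3]),
    u4 = conv_unit(ch[3], ch[4]),
    u5 = conv_unit(ch[4], ch[5]),
    channels = ch
  )
  class(m) <- c("unet_encoder", "dbh_module")
  m
}

check_image_batch <- function(x) {
  v <- tval(x)
  d <- dim(v)
  if (length(d) != 4L || d[2] != 3L)
    stop("ImageBatch must be (batch, 3, height, width); got ",
         paste(d, collapse = "x"))
  if (d[3] %% 32L) stop("ImageBatch height ", d[3], " not divisible by 32")
  if (d[4] %% 32L) stop("ImageBatch width ", d[4], " not divisible by 32")
  if (!all(is.finite(v))) stop("ImageBatch contains non-finite values")
  invisible(d)
}

# all five unit outputs (scales 1/2 .. 1/32); the baseline decoder needs them
unet_forward_units <- function(enc, image, training = FALSE) {
  check_image_batch(image)
  outs <- vector("list", 5L)
  x <- image
  for (i in 1:5) {
    x <- conv_unit_forward(enc[[paste0("u", i)]], x, training)
    outs[[i]] <- x
  }
  outs
}

#' Encode an image batch into the four-scale feature pyramid
#'
#' Returns the outputs of units 2-5: scales 1/4, 1/8, 1/16, 1/32 with
#' C, 2C, 4C, 8C channels. The first unit's 1/2-scale output is internal.
#'
#' @param enc module from [unet_encoder()]
#' @param image image tensor or array, (batch, 3, H, W), H and W divisible by 32
#' @param training logical
#' @return list of 4 tensors (the FeaturePyramid contract)
#' @export
unet_encode <- function(enc, image, training = FALSE) {
  if (!is_tensor(image)) image <- dbh_const(image)
  unet_forward_units(enc, image, training)[2:5]
}

## ---- classic symmetric decoder (baseline variant only) ---------------------

# one decoder level: upsample x2, concat the skip, two 3x3 conv+BN+ReLU
unet_dec_level <- function(cin_up, cin_skip, cout) {
  m <- list(c1 = nn_cbr(cin_up + cin_skip, cout), c2 = nn_cbr(cout, cout))
  class(m) <- c("unet_dec_level", "dbh_module")
  m
}

#' Build the classic symmetric decoder for the convolutional baseline
#'
#' Interpolate-and-convolve levels with skip concatenation from encoder units
#' 4..1, one skip-free level back to full resolution, and a 1x1 logit head.
#'
#' @param base_channels encoder base width
#' @param n_classes logit channels (default 2: background/lesion)
#' @return a module
#' @export
unet_decoder <- function(base_channels = 48L, n_classes = 2L) {
  ch <- base_channels * 2L^(0:4)
  m <- list(
    d4 = unet_dec_level(ch[5], ch[4], ch[4]),
    d3 = unet_dec_level(ch[4], ch[3], ch[3]),
    d2 = unet_dec_level(ch[3], ch[2], ch[2]),
    d1 = unet_dec_level(ch[2], ch[1], ch[1]),
    d0 = list(c1 = nn_cbr(ch[1], ch[1]), c2 = nn_cbr(ch[1], ch[1])),
    head = nn_conv2d(ch[1], n_classes, k = 1L)
  )
  class(m) <- c("unet_decoder", "dbh_module")
  m
}

unet_decode <- function(dec, units, training = FALSE) {
  x <- units[[5]]
  for (i in 4:1) {
    lev <- dec[[paste0("d", i)]]
    x <- t_cat_ch(list(t_upsample(x, 2), units[[i]]))
    x <- fwd(lev$c2, fwd(lev$c1, x, training), training)
  }
  x <- t_upsample(x, 2)
  x <- fwd(dec$d0$c2, fwd(dec$d0$c1, x, training), training)
  fwd(dec$head, x, training)
}
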