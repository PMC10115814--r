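# Feature Fusion module: at each pyramid scale the two branch features (and
# the previous scale's fusion output, max-pooled down) are refined by 3x3
# convolutions to a common width, combined by an elementwise Hadamard product
# into an interaction map, concatenated with the raw branch features, and
# merged by a residual block back to the branch width. Fusion outputs thread
# scale-to-scale (the multi-modal mechanism).

nn_ff_module <- function(channels, has_prev, residual_depth = 2L) {
  d <- as.integer(channels)
  m <- list(
    w_st = nn_cbr(d, d),
    w_u = nn_cbr(d, d),
    w_ff = if (has_prev) nn_cbr(d %/% 2L, d) else NULL,
    res1 = nn_cbr(3L * d, d, relu = (residual_depth > 1L)),
    res2 = if (residual_depth > 1L) nn_cbr(d, d, relu = FALSE) else NULL,
    shortcut = nn_cbr(3L * d, d, k = 1L, relu = FALSE),
    channels = d
  )
  class(m) <- c("nn_ff_module", "dbh_module")
  m
}

#' Fuse the two branch features at one scale
#'
#' Each input is refined by a 3x3 convolution; the previous scale's fusion
#' output, when present, is first downsampled by a 3x3/stride-2 max-pool. The
#' refined maps are multiplied elementwise into the interaction map `b_i`,
#' concatenated with the raw branch features, and merged by a residual block
#' whose output keeps the branch channel width.
#'
#' @param mod fusion module for this scale
#' @param st,u branch features of identical shape
#' @param ff_prev previous-scale fusion output (spatially 2x larger), or NULL
#' @param training logical
#' @return fused tensor with `st`'s shape
#' @export
ff_forward <- function(mod, st, u, ff_prev = NULL, training = FALSE) {
  if (!is_tensor(st)) st <- dbh_const(st)
  if (!is_tensor(u)) u <- dbh_const(u)
  dst <- dim(tval(st)); du <- dim(tval(u))
  if (!identical(dst, du))
    stop("ff_forward: branch features differ in shape: ",
         paste(dst, collapse = "x"), " vs ", paste(du, collapse = "x"))
  f_st <- fwd(mod$w_st, st, training)
  f_u <- fwd(mod$w_u, u, training)
  b <- t_mul(f_st, f_u)
  if (!is.null(mod$w_ff)) {
    if (is.null(ff_prev))
      stop("ff_forward: this scale expects the previous fusion output")
    if (!is_tensor(ff_prev)) ff_prev <- dbh_const(ff_prev)
    dp <- dim(tval(ff_prev))
    if (dp[3] != 2L * dst[3] || dp[4] != 2L * dst[4])
      stop("ff_forward: ff_prev must be exactly 2x the spatial size (got ",
           dp[3], "x", dp[4], " for ", dst[3], "x", dst[4], ")")
    f_ff <- fwd(mod$w_ff, t_maxpool3s2(ff_prev), training)
    b <- t_mul(b, f_ff)
  }
  cc <- t_cat_ch(list(st, u, b))
  main <- fwd(mod$res1, cc, training)
  if (!is.null(mod$res2)) main <- fwd(mod$res2, main, training)
  t_relu(t_add(main, fwd(mod$shortcut, cc, training)))
}

#' Build the four-scale fusion stack
#' @param C pyramid base width
#' @param residual_depth convolutions in the residual merge (1 or 2)
#' @return a module with per-scale fusion modules `ff1..ff4`
#' @export
nn_ff_stack <- function(C = 96L, residual_depth = 2L) {
  m <- list(
    ff1 = nn_ff_module(C, has_prev = FALSE, residual_depth),
    ff2 = nn_ff_module(2L * C, has_prev = TRUE, residual_depth),
    ff3 = nn_ff_module(4L * C, has_prev = TRUE, residual_depth),
    ff4 = nn_ff_module(8L * C, has_prev = TRUE, residual_depth)
  )
  class(m) <- c("nn_ff_stack", "dbh_module")
  m
}

#' Fuse two feature pyramids scale by scale
#'
#' Applies the four fusion modules sequentially, threading each scale's output
#' into the next scale's module.
#'
#' @param stack module from [nn_ff_stack()]
#' @param st_pyr,u_pyr four-level feature pyramids from the two branches
#' @param training logical
#' @return list of fused tensors `ff_1..ff_4`
#' @export
fuse_pyramids <- function(stack, st_pyr, u_pyr, training = FALSE) {
  out <- vector("list", 4L)
  prev <- NULL
  for (i in 1:4) {
    out[[i]] <- ff_forward(stack[[paste0("ff", i)]], st_pyr[[i]], u_pyr[[i]],
                           ff_prev = prev, training = training)
    prev <- out[[i]]
  }
  out
}
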