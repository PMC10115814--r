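# Model registry: the six ablation variants assembled from the two encoders,
# the two lightweight aggregation decoders, the per-scale fusion stack and the
# attention-gated decoder.
#
#   unet       convolutional encoder + classic symmetric decoder
#   st         attention encoder + minimal upsampling head
#   unet_dfa   convolutional encoder + aggregation decoder
#   st_dfa     attention encoder + aggregation decoder
#   fusion_ff  both original networks + fusion stack + gated decoder
#   ours       both encoders + two aggregation decoders + fusion + gated decoder
#
# Multi-branch variants return three logit maps (fused, attention branch,
# convolutional branch) for the three-head loss.

#' Names of the six ablation variants
#' @format character vector
#' @export
model_variants <- c("unet", "st", "unet_dfa", "st_dfa", "fusion_ff", "ours")

st_baseline_head <- function(C, n_classes) {
  m <- list(c1 = nn_cbr(8L * C, C), c2 = nn_conv2d(C, n_classes))
  class(m) <- c("st_baseline_head", "dbh_module")
  m
}

st_head_forward <- function(head, pyr, training = FALSE) {
  t_upsample(fwd(head$c2, fwd(head$c1, pyr[[4]], training), training), 32)
}

#' Build one of the six model variants
#'
#' @param variant one of `"unet"`, `"st"`, `"unet_dfa"`, `"st_dfa"`,
#'   `"fusion_ff"`, `"ours"`
#' @param config model configuration, see [dbh_config()]
#' @return a `dbhnet_model` object
#' @export
build_model <- function(variant = "ours", config = dbh_config()) {
  if (!variant %in% model_variants)
    stop("unknown variant '", variant, "'; valid names: ",
         paste(model_variants, collapse = ", "))
  mc <- config$model
  C <- as.integer(mc$C)
  ncl <- as.integer(mc$n_classes)
  scfg <- swin_config(embed_dim = C, depths = mc$swin$depths,
                      heads = mc$swin$heads, window = mc$swin$window,
                      mlp_ratio = mc$swin$mlp_ratio)
  dfa_in <- C * c(2L, 4L, 8L)
  need_u <- variant %in% c("unet", "unet_dfa", "fusion_ff", "ours")
  need_s <- variant %in% c("st", "st_dfa", "fusion_ff", "ours")
  m <- list(variant = variant, config = config)
  if (need_u) m$u_enc <- unet_encoder(mc$unet$base_channels)
  if (need_s) {
    s_levels <- switch(variant, st = 4L, st_dfa = 2:4, 1:4)
    m$s_enc <- swin_encoder(scfg, out_levels = s_levels)
  }
  if (variant %in% c("unet", "fusion_ff"))
    m$u_dec <- unet_decoder(mc$unet$base_channels, ncl)
  if (variant %in% c("st", "fusion_ff"))
    m$st_head <- st_baseline_head(C, ncl)
  if (variant %in% c("unet_dfa", "ours"))
    m$dfa_u <- dfa_decoder(dfa_in, mc$dfa$channels, mc$dfa$dilations, ncl)
  if (variant %in% c("st_dfa", "ours"))
    m$dfa_st <- dfa_decoder(dfa_in, mc$dfa$channels, mc$dfa$dilations, ncl)
  if (variant %in% c("fusion_ff", "ours")) {
    m$ff <- nn_ff_stack(C, residual_depth = mc$ff$residual_depth %||% 2L)
    m$dec <- nn_gated_decoder(C, ncl,
                              per_channel_gate = isTRUE(mc$att$per_channel_gate))
  }
  class(m) <- c("dbhnet_model", "dbh_module")
  m
}

#' Forward pass of a model variant
#'
#' @param model object from [build_model()]
#' @param image tensor or array (batch, 3, H, W), H and W divisible by 32
#' @param training logical
#' @return named list of logit tensors: multi-branch variants return
#'   `ff`, `st`, `u`; single-branch variants return their one head
#' @export
model_forward <- function(model, image, training = FALSE) {
  if (!is_tensor(image)) image <- dbh_const(image)
  check_image_batch(image)
  v <- model$variant
  out <- list()
  u_units <- NULL; u_pyr <- NULL; s_pyr <- NULL
  if (!is.null(model$u_enc)) {
    u_units <- unet_forward_units(model$u_enc, image, training)
    u_pyr <- u_units[2:5]
  }
  if (!is.null(model$s_enc))
    s_pyr <- swin_encode(model$s_enc, image, training)
  if (v == "unet") {
    out$u <- unet_decode(model$u_dec, u_units, training)
  } else if (v == "st") {
    out$st <- st_head_forward(model$st_head, s_pyr, training)
  } else if (v == "unet_dfa") {
    out$u <- dfa_forward(model$dfa_u, u_pyr, training)
  } else if (v == "st_dfa") {
    out$st <- dfa_forward(model$dfa_st, s_pyr, training)
  } else {
    ffs <- fuse_pyramids(model$ff, s_pyr, u_pyr, training)
    out$ff <- gated_decode(model$dec, ffs, training)
    if (v == "fusion_ff") {
      out$st <- st_head_forward(model$st_head, s_pyr, training)
      out$u <- unet_decode(model$u_dec, u_units, training)
    } else {
      out$st <- dfa_forward(model$dfa_st, s_pyr, training)
      out$u <- dfa_forward(model$dfa_u, u_pyr, training)
    }
  }
  out
}

#' Combined loss of a forward pass
#'
#' Multi-branch variants use the convex three-head combination; single-branch
#' variants use their head's cross-entropy directly.
#'
#' @param outputs list from [model_forward()]
#' @param mask binary ground truth (batch, H, W)
#' @param w [loss_weights()]
#' @return scalar loss tensor
#' @export
model_loss <- function(outputs, mask, w = loss_weights()) {
  if (!is.null(outputs$ff)) {
    total_loss(pixel_ce(outputs$ff, mask), pixel_ce(outputs$st, mask),
               pixel_ce(outputs$u, mask), w)
  } else {
    pixel_ce(outputs[[1]], mask)
  }
}

#' Map published attention-encoder weights into a model
#'
#' Accepts a named list of arrays (for example a converted
#' `swin_tiny_patch4_window7_224` state dict saved as RDS) and loads every
#' key whose name and shape match the attention encoder; the mapping report
#' lists missing, unexpected and shape-mismatched keys. Entirely optional:
#' models train from random initialization without it.
#'
#' @param model a `dbhnet_model` with an attention encoder
#' @param state named list of arrays, or a path to an RDS file holding one
#' @return invisibly, the report from [load_state_dict()]
#' @export
load_pretrained_swin <- function(model, state) {
  if (is.character(state)) state <- readRDS(state)
  if (is.null(model$s_enc))
    stop("load_pretrained_swin: variant '", model$variant,
         "' has no attention encoder")
  # accept keys with or without the model-level "s_enc." prefix
  nms <- names(state)
  pref <- startsWith(nms, "s_enc.")
  names(state)[pref] <- substring(nms[pref], 7L)
  rep <- load_state_dict(model$s_enc, state)
  if (length(rep$shape_mismatch)) {
    message("load_pretrained_swin: ", length(rep$shape_mismatch),
            " shape mismatches:\n  ",
            paste(rep$shape_mismatch, collapse = "\n  "))
  }
  invisible(rep)
}
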