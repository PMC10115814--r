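# Configuration: one nested list covers the model, training and synthetic-data
# settings; YAML round-trip for the command-line tools.

#' Default configuration
#'
#' Model: pyramid width `C = 96`, convolutional base width 48 (= C/2, so the
#' four shared scales carry C, 2C, 4C, 8C), attention depths `c(2,2,6,2)` with
#' heads `c(3,6,12,24)` and window 7, aggregation-decoder width 48 with
#' dilations 1/3/5/7. Training: 300 epochs, batch 16, Adam with learning rate
#' 1e-3 and weight decay 1e-4, 224x224 inputs, loss weights (0.5, 0.2, 0.3).
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `model = list(C = 32)`
#' @return nested configuration list
#' @export
dbh_config <- function(...) {
  cfg <- list(
    model = list(
      C = 96L,
      n_classes = 2L,
      unet = list(base_channels = 48L),
      swin = list(depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                  window = 7L, mlp_ratio = 4),
      dfa = list(channels = 48L, dilations = c(1L, 3L, 5L, 7L)),
      ff = list(residual_depth = 2L),
      att = list(per_channel_gate = FALSE)
    ),
    train = list(
      epochs = 300L, batch_size = 16L, optimizer = "adam",
      learning_rate = 1e-3, weight_decay = 1e-4, image_size = 224L,
      seed = 42L, loss_weights = c(0.5, 0.2, 0.3)
    ),
    synth = list(
      image_size = 224L, n_lesions = c(1L, 3L), area_fraction = c(0.02, 0.35),
      fold_frequency = c(2, 6), fold_amplitude = 0.08, noise_sd = 0.02,
      aug_factor = 4L, val_fraction = 0.05
    )
  )
  merge_cfg(cfg, list(...))
}

merge_cfg <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a configuration from a YAML file, merged over the defaults
#' @param path YAML file path
#' @return nested configuration list
#' @export
load_config <- function(path) {
  merge_cfg(dbh_config(), yaml::read_yaml(path))
}

#' Write a configuration to YAML
#' @param cfg configuration list
#' @param path output path
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' A small configuration for desk-scale experiments
#'
#' Pyramid width 16, one attention block per stage, window 2, 64x64 inputs:
#' every architectural mechanism is exercised at a size that trains on a CPU
#' in minutes.
#'
#' @param image_size input size (divisible by 32)
#' @param C pyramid base width (even)
#' @return nested configuration list
#' @export
tiny_config <- function(image_size = 64L, C = 16L) {
  dbh_config(
    model = list(
      C = as.integer(C),
      unet = list(base_channels = as.integer(C) %/% 2L),
      swin = list(depths = c(1L, 1L, 1L, 1L), heads = c(2L, 2L, 2L, 2L),
                  window = 2L)
    ),
    train = list(image_size = as.integer(image_size), batch_size = 4L),
    synth = list(image_size = as.integer(image_size))
  )
}
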