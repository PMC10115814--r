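# Seeded generator of endoscopy-like image/mask pairs, the augmentation
# pipeline, and dataset I/O. The generator emulates the coarse structure of
# gastric endoscopy frames: a smooth pink-red mucosa color field with
# sinusoidal fold texture and speckle noise, plus one or more smooth
# star-convex lesion blobs with shifted hue and finer texture, each with an
# exact ground-truth support mask.

# derived per-file seeds, kept inside the 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 10007 + k) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  code
}

#' Synthetic dataset configuration
#'
#' @param image_size square image size in pixels (divisible by 32)
#' @param n_lesions inclusive range of lesion counts per image
#' @param area_fraction admissible range of total lesion area fraction
#' @param fold_frequency range of mucosal fold frequencies (cycles per image)
#' @param fold_amplitude luminance amplitude of the fold texture
#' @param noise_sd speckle noise standard deviation (on the 0-1 scale)
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(image_size = 224L, n_lesions = c(1L, 3L),
                             area_fraction = c(0.02, 0.35),
                             fold_frequency = c(2, 6), fold_amplitude = 0.08,
                             noise_sd = 0.02) {
  if (image_size %% 32L) stop("synthetic_config: image_size must be divisible by 32")
  if (any(area_fraction <= 0) || any(area_fraction >= 1))
    stop("synthetic_config: area fractions must lie in (0,1)")
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 area_fraction = area_fraction,
                 fold_frequency = fold_frequency,
                 fold_amplitude = fold_amplitude, noise_sd = noise_sd),
            class = "synthetic_config")
}

# bilinear upsampling of a coarse random grid, written as plain indexed
# arithmetic (no matrix products) so repeated generation is bitwise identical
smooth_field <- function(S, grid = 8L, center, spread) {
  g <- matrix(stats::rnorm(grid * grid, center, spread), grid, grid)
  sc <- S / grid
  src <- (seq_len(S) - 0.5) / sc - 0.5
  i0 <- floor(src)
  tt <- src - i0
  i0c <- pmin(pmax(i0, 0), grid - 1) + 1
  i1c <- pmin(pmax(i0 + 1, 0), grid - 1) + 1
  rows <- g[i0c, , drop = FALSE] * (1 - tt) + g[i1c, , drop = FALSE] * tt
  rows[, i0c, drop = FALSE] * rep(1 - tt, each = S) +
    rows[, i1c, drop = FALSE] * rep(tt, each = S)
}

# star-convex blob support: radius r(theta) = r0 (1 + sum a_k cos(k theta + phi))
lesion_support <- function(S, cx, cy, r0) {
  ks <- 2:5
  a <- stats::runif(length(ks), 0, 0.25) / sqrt(ks)
  phi <- stats::runif(length(ks), 0, 2 * pi)
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  dx <- rr - cy
  dy <- cc - cx
  theta <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_along(ks), function(i)
    a[i] * cos(ks[i] * theta + phi[i]))))
  (dx * dx + dy * dy) <= rad * rad
}

#' Generate one synthetic image/mask pair
#'
#' Deterministic given `seed`: identical seeds produce bitwise-identical
#' pairs. Total lesion area is drawn from the configured range; generation is
#' retried (advancing the private RNG stream) up to 20 times if clipping or
#' overlap pushes the realized foreground fraction outside the range, and
#' errors afterwards.
#'
#' @param cfg a [synthetic_config()]
#' @param seed integer seed
#' @param n_lesions optional fixed lesion count (0 permitted, for an all-
#'   background test image)
#' @return list with `image` (H x W x 3 array, values in 0..255) and `mask`
#'   (H x W binary array)
#' @export
generate_sample <- function(cfg = synthetic_config(), seed = 1L,
                            n_lesions = NULL) {
  with_seed(seed, {
    S <- cfg$image_size
    # mucosa background: smooth color field + folds + speckle
    base <- list(
      r = smooth_field(S, center = 0.78, spread = 0.05),
      g = smooth_field(S, center = 0.47, spread = 0.05),
      b = smooth_field(S, center = 0.42, spread = 0.05)
    )
    freq <- stats::runif(1, cfg$fold_frequency[1], cfg$fold_frequency[2])
    ang <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)
    folds <- cfg$fold_amplitude *
      sin(2 * pi * freq * (cos(ang) * rr + sin(ang) * cc) / S + phase)
    nles <- if (!is.null(n_lesions)) as.integer(n_lesions)
            else sample(seq(cfg$n_lesions[1], cfg$n_lesions[2]), 1)
    mask <- matrix(0, S, S)
    lesion_mix <- matrix(0, S, S)
    lesion_col <- c(0.45, 0.2, 0.22) + stats::rnorm(3, 0, 0.04)
    if (nles > 0L) {
      ok <- FALSE
      for (attempt in 1:20) {
        mask[] <- 0
        target <- stats::runif(1, cfg$area_fraction[1], cfg$area_fraction[2])
        shares <- stats::runif(nles, 0.5, 1)
        shares <- shares / sum(shares)
        for (l in seq_len(nles)) {
          r0 <- sqrt(shares[l] * target * S * S / pi)
          cx <- stats::runif(1, 0.2 * S, 0.8 * S)
          cy <- stats::runif(1, 0.2 * S, 0.8 * S)
          mask[lesion_support(S, cx, cy, r0)] <- 1
        }
        frac <- mean(mask)
        if (frac >= cfg$area_fraction[1] && frac <= cfg$area_fraction[2]) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("generate_sample: could not satisfy area constraints ",
                    "after 20 attempts (seed ", seed, ")")
      lesion_mix <- mask
    }
    fine <- matrix(stats::rnorm(S * S, 0, 0.05), S, S)
    img <- array(0, c(S, S, 3))
    chans <- c("r", "g", "b")
    for (k in 1:3) {
      bg <- base[[chans[k]]] + folds
      le <- lesion_col[k] + 0.6 * folds + fine
      v <- bg * (1 - lesion_mix) + le * lesion_mix +
        stats::rnorm(S * S, 0, cfg$noise_sd)
      img[, , k] <- pmin(pmax(v, 0), 1) * 255
    }
    list(image = img, mask = mask)
  })
}

## ---- augmentation -----------------------------------------------------------

reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j < 0L, j + 2L * n - 2L, j)
  ifelse(j >= n, 2L * n - 2L - j, j) + 1L
}

#' Deterministic augmentation with explicit parameters
#'
#' Flips and an affine map (rotation about the image center by any angle,
#' translation, zoom) applied identically to image and mask — bilinear with
#' reflect padding for the image, nearest-neighbor with zero fill for the
#' mask — plus photometric jitter (hue, saturation, brightness) on the image
#' only. All defaults give the identity.
#'
#' @param pair list with `image` (H x W x 3, 0..255) and binary `mask`
#' @param hflip,vflip logical flips
#' @param angle rotation in degrees
#' @param tx,ty translation in pixels (columns, rows)
#' @param zoom scale factor
#' @param hue additive hue shift in `[-0.5, 0.5]` (hue wraps)
#' @param sat,bright multiplicative saturation/brightness factors
#' @return augmented pair; the mask stays binary
#' @export
augment_apply <- function(pair, hflip = FALSE, vflip = FALSE, angle = 0,
                          tx = 0, ty = 0, zoom = 1, hue = 0, sat = 1,
                          bright = 1) {
  img <- pair$image
  mask <- pair$mask
  H <- dim(mask)[1]; W <- dim(mask)[2]
  if (hflip) { img <- img[, W:1, , drop = FALSE]; mask <- mask[, W:1, drop = FALSE] }
  if (vflip) { img <- img[H:1, , , drop = FALSE]; mask <- mask[H:1, , drop = FALSE] }
  if (angle != 0 || tx != 0 || ty != 0 || zoom != 1) {
    th <- angle * pi / 180
    crow <- (H + 1) / 2; ccol <- (W + 1) / 2
    rr <- matrix(seq_len(H), H, W) - crow
    cc <- matrix(seq_len(W), H, W, byrow = TRUE) - ccol
    # inverse map: source = center + R(-th) ((dest - t)) / zoom
    dr <- rr - ty; dc <- cc - tx
    sr <- (cos(th) * dr + sin(th) * dc) / zoom + crow
    sc <- (-sin(th) * dr + cos(th) * dc) / zoom + ccol
    # bilinear for image (reflect padding)
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ri0 <- reflect_idx(as.integer(r0), H); ri1 <- reflect_idx(as.integer(r0) + 1L, H)
    ci0 <- reflect_idx(as.integer(c0), W); ci1 <- reflect_idx(as.integer(c0) + 1L, W)
    out <- array(0, dim(img))
    for (k in 1:3) {
      ch <- img[, , k]
      out[, , k] <- ch[cbind(c(ri0), c(ci0))] * (1 - fr) * (1 - fc) +
        ch[cbind(c(ri1), c(ci0))] * fr * (1 - fc) +
        ch[cbind(c(ri0), c(ci1))] * (1 - fr) * fc +
        ch[cbind(c(ri1), c(ci1))] * fr * fc
    }
    img <- out
    # nearest with zero fill for the mask
    rn <- as.integer(round(sr)); cn <- as.integer(round(sc))
    inside <- rn >= 1L & rn <= H & cn >= 1L & cn <= W
    mv <- numeric(H * W)
    mv[inside] <- mask[cbind(rn[inside], cn[inside])]
    mask <- matrix(mv, H, W)
  }
  if (hue != 0 || sat != 1 || bright != 1) {
    rgb <- matrix(c(img[, , 1], img[, , 2], img[, , 3]) / 255, nrow = 3,
                  byrow = TRUE)
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + hue) %% 1
    hsv[2, ] <- pmin(pmax(hsv[2, ] * sat, 0), 1)
    hsv[3, ] <- pmin(pmax(hsv[3, ] * bright, 0), 1)
    rgb2 <- hsv_to_rgb(hsv)
    for (k in 1:3) img[, , k] <- matrix(rgb2[k, ], H, W) * 255
  }
  list(image = img, mask = mask)
}

# vectorized HSV -> RGB (grDevices::hsv returns strings, so done by formula)
hsv_to_rgb <- function(hsv) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Random augmentation of an image/mask pair
#'
#' Samples horizontal/vertical flips, an arbitrary rotation angle in
#' `[0, 360)`, translation up to 10% of the image size, zoom in `[0.9, 1.1]`,
#' and hue/saturation/brightness jitter, then applies [augment_apply()].
#' Deterministic given `seed`.
#'
#' @param pair list with `image` and `mask`
#' @param seed integer seed
#' @return augmented pair
#' @export
augment <- function(pair, seed = 1L) {
  with_seed(seed, {
    S <- dim(pair$mask)[1]
    augment_apply(pair,
                  hflip = stats::runif(1) < 0.5,
                  vflip = stats::runif(1) < 0.5,
                  angle = stats::runif(1, 0, 360),
                  tx = stats::runif(1, -0.1, 0.1) * S,
                  ty = stats::runif(1, -0.1, 0.1) * S,
                  zoom = stats::runif(1, 0.9, 1.1),
                  hue = stats::runif(1, -0.03, 0.03),
                  sat = stats::runif(1, 0.8, 1.2),
                  bright = stats::runif(1, 0.85, 1.15))
  })
}

## ---- PNG I/O ----------------------------------------------------------------

#' Write an RGB image (values 0..255) as PNG
#' @param img H x W x 3 array in 0..255
#' @param path output path
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Read an RGB PNG as an H x W x 3 array with values 0..255
#' @param path input path
#' @export
read_image_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3), c(dim(v), 3))
  v[, , 1:3, drop = FALSE] * 255
}

#' Write a binary mask as a single-channel PNG (0 = background, 255 = lesion)
#' @param mask binary matrix
#' @param path output path
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path) # {0,1} -> {0,255} on disk
  invisible(path)
}

#' Read a mask PNG back to a binary matrix
#' @param path input path
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  (v > 0.5) * 1
}

## ---- dataset building and loading -------------------------------------------

#' Build an on-disk synthetic dataset with train/val/test splits
#'
#' Writes PNG images and masks under `images/` and `masks/` plus a JSON
#' manifest recording the split membership, per-file seeds and the full
#' configuration. Training originals are expanded by `aug_factor` (original
#' plus `aug_factor - 1` augmented copies); the validation split is carved
#' from the augmented training pool at `val_fraction`.
#'
#' @param cfg a [synthetic_config()]
#' @param n_train,n_test numbers of original pairs per split
#' @param out_dir output directory (created if needed)
#' @param seed master seed
#' @param aug_factor training multiplication factor (default 4)
#' @param val_fraction fraction of the augmented pool used for validation
#' @return invisibly, the manifest list
#' @export
build_dataset <- function(cfg = synthetic_config(), n_train = 20L,
                          n_test = 5L, out_dir, seed = 1L, aug_factor = 4L,
                          val_fraction = 0.05) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_pair <- function(pair, stem) {
    ip <- file.path(out_dir, "images", paste0(stem, ".png"))
    mp <- file.path(out_dir, "masks", paste0(stem, ".png"))
    ok <- tryCatch({
      write_image_png(pair$image, ip)
      write_mask_png(pair$mask, mp)
      TRUE
    }, error = function(e) {
      stop("build_dataset: failed writing ", ip, ": ", conditionMessage(e))
    })
    stem
  }
  train_files <- character()
  train_seeds <- integer()
  k <- 0L
  for (i in seq_len(n_train)) {
    s0 <- derive_seed(seed, i)
    orig <- generate_sample(cfg, s0)
    k <- k + 1L
    train_files <- c(train_files, write_pair(orig, sprintf("train_%04d", k)))
    train_seeds <- c(train_seeds, s0)
    for (a in seq_len(aug_factor - 1L)) {
      sa <- derive_seed(s0, a)
      k <- k + 1L
      train_files <- c(train_files,
                       write_pair(augment(orig, sa), sprintf("train_%04d", k)))
      train_seeds <- c(train_seeds, sa)
    }
  }
  test_files <- character()
  test_seeds <- integer()
  for (i in seq_len(n_test)) {
    s0 <- derive_seed(seed, 500000L + i)
    test_files <- c(test_files,
                    write_pair(generate_sample(cfg, s0),
                               sprintf("test_%04d", i)))
    test_seeds <- c(test_seeds, s0)
  }
  n_val <- if (val_fraction <= 0) 0L else
    max(1L, round(val_fraction * length(train_files)))
  val_pick <- if (n_val > 0L)
    with_seed(seed, sample(seq_along(train_files), n_val)) else integer()
  manifest <- list(
    seed = seed,
    config = unclass(cfg),
    aug_factor = aug_factor,
    val_fraction = val_fraction,
    splits = list(
      train = if (length(val_pick)) train_files[-val_pick] else train_files,
      val = train_files[val_pick],
      test = test_files
    ),
    seeds = list(train = train_seeds, test = test_seeds)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load one split of an on-disk dataset
#'
#' Reads the manifest written by [build_dataset()]; also accepts plain
#' `images/` + `masks/` folder layouts (e.g. public polyp benchmarks) when no
#' manifest is present, pairing files by name.
#'
#' @param dir dataset directory
#' @param split `"train"`, `"val"` or `"test"` (ignored for plain folders)
#' @return list of pairs, each with `image`, `mask`, `id`
#' @export
load_dataset <- function(dir, split = "train") {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    stems <- manifest$splits[[split]]
    if (is.null(stems)) stop("load_dataset: no split '", split, "' in manifest")
  } else {
    stems <- sub("\\.png$", "", list.files(file.path(dir, "images"),
                                           pattern = "\\.png$"))
  }
  lapply(stems, function(s) {
    ip <- file.path(dir, "images", paste0(s, ".png"))
    mp <- file.path(dir, "masks", paste0(s, ".png"))
    if (!file.exists(ip)) stop("load_dataset: missing image ", ip)
    if (!file.exists(mp)) stop("load_dataset: missing mask ", mp)
    list(image = read_image_png(ip), mask = read_mask_png(mp), id = s)
  })
}

#' Convert Labelme polygon annotations to a binary mask
#'
#' Reads a Labelme-style JSON file and rasterizes all polygon shapes by
#' even-odd point-in-polygon filling.
#'
#' @param path JSON file path
#' @param height,width mask size; defaults to the file's recorded size
#' @return binary matrix (height x width)
#' @export
labelme_to_mask <- function(path, height = NULL, width = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  H <- height %||% j$imageHeight
  W <- width %||% j$imageWidth
  if (is.null(H) || is.null(W))
    stop("labelme_to_mask: image size not in file; pass height/width")
  mask <- matrix(0, H, W)
  px <- matrix(seq_len(W), H, W, byrow = TRUE) - 0.5
  py <- matrix(seq_len(H), H, W) - 0.5
  for (sh in j$shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) c(p[[1]], p[[2]])))
    n <- nrow(pts)
    inside <- matrix(FALSE, H, W)
    jv <- n
    for (iv in seq_len(n)) {
      xi <- pts[iv, 1]; yi <- pts[iv, 2]
      xj <- pts[jv, 1]; yj <- pts[jv, 2]
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
      jv <- iv
    }
    mask[inside] <- 1
  }
  mask
}

#' Stack pairs into a normalized network input batch
#'
#' @param pairs list of pairs from [load_dataset()] or [generate_sample()]
#' @return list with `x` (N, 3, H, W array, normalized to `[-1, 1]`) and
#'   `y` (N, H, W binary array)
#' @export
to_batch <- function(pairs) {
  N <- length(pairs)
  d <- dim(pairs[[1]]$image)
  x <- array(0, c(N, 3L, d[1], d[2]))
  y <- array(0, c(N, d[1], d[2]))
  for (i in seq_len(N)) {
    x[i, , , ] <- aperm(pairs[[i]]$image, c(3, 1, 2))
    y[i, , ] <- pairs[[i]]$mask
  }
  list(x = (x / 255 - 0.5) / 0.5, y = y)
}
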