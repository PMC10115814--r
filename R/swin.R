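# Self-attention branch: 4x4 patch embedding, four stages of shifted-window
# multi-head self-attention blocks with patch-merging downsampling between
# stages, emitting the same four-scale pyramid as the convolutional branch.
#
# Token grids are stored as (batch, tokens, dim) arrays with the grid
# flattened row-fastest; all grid rearrangements (window partition, cyclic
# shift, patch merging, token<->spatial) are pure index permutations, cached
# per shape, and differentiable through a single gather op.

#' Configuration of the attention-branch encoder
#'
#' @param embed_dim pyramid base width C (default 96)
#' @param depths blocks per stage; default `c(2, 2, 6, 2)` (the tiny variant,
#'   compatible with published tiny checkpoints); `c(2, 2, 2, 6)` is also valid
#' @param heads attention heads per stage
#' @param window window size in tokens (default 7)
#' @param mlp_ratio MLP expansion factor
#' @return a `swin_config` list
#' @export
swin_config <- function(embed_dim = 96L, depths = c(2L, 2L, 6L, 2L),
                        heads = c(3L, 6L, 12L, 24L), window = 7L,
                        mlp_ratio = 4) {
  if (length(depths) != 4L || length(heads) != 4L)
    stop("swin_config: depths and heads must each have 4 entries")
  dims <- embed_dim * 2L^(0:3)
  if (any(dims %% heads != 0L))
    stop("swin_config: stage dim not divisible by head count")
  structure(list(embed_dim = as.integer(embed_dim), depths = as.integer(depths),
                 heads = as.integer(heads), window = as.integer(window),
                 mlp_ratio = mlp_ratio),
            class = "swin_config")
}

## ---- cached index permutations ---------------------------------------------

.idx_cache <- new.env(parent = emptyenv())
cached <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .idx_cache[[key]] <- v
  }
  v
}

wp_idx <- function(N, gh, gw, dim, win) {
  cached(paste("wp", N, gh, gw, dim, win), function() {
    arr <- array(seq_len(N * gh * gw * dim),
                 c(N, win, gh %/% win, win, gw %/% win, dim))
    as.vector(aperm(arr, c(1, 3, 5, 2, 4, 6)))
  })
}

inv_idx <- function(idx) {
  iv <- integer(length(idx))
  iv[idx] <- seq_along(idx)
  iv
}

roll_idx <- function(N, gh, gw, dim, s) {
  cached(paste("roll", N, gh, gw, dim, s), function() {
    arr <- array(seq_len(N * gh * gw * dim), c(N, gh, gw, dim))
    rr <- ((seq_len(gh) - 1L + s) %% gh) + 1L
    cc <- ((seq_len(gw) - 1L + s) %% gw) + 1L
    as.vector(arr[, rr, cc, , drop = FALSE])
  })
}

qkv_split_idx <- function(K, n, dh, h) {
  cached(paste("qkv", K, n, dh, h), function() {
    arr <- array(seq_len(K * n * dh * h * 3L), c(K, n, dh, h, 3L))
    perm <- aperm(arr, c(1, 4, 2, 3, 5)) # (K, h, n, dh, qkv)
    list(q = as.vector(perm[, , , , 1]),
         k = as.vector(perm[, , , , 2]),
         v = as.vector(perm[, , , , 3]))
  })
}

merge_heads_idx <- function(K, n, dh, h) {
  cached(paste("mh", K, n, dh, h), function() {
    arr <- array(seq_len(K * h * n * dh), c(K, h, n, dh))
    as.vector(aperm(arr, c(1, 3, 4, 2))) # (K, n, dh, h) -> dim = dh*h
  })
}

pm_idx <- function(N, gh, gw, dim) {
  cached(paste("pm", N, gh, gw, dim), function() {
    arr <- array(seq_len(N * gh * gw * dim), c(N, 2L, gh %/% 2L, 2L, gw %/% 2L, dim))
    as.vector(aperm(arr, c(1, 3, 5, 6, 2, 4))) # (N, gh/2, gw/2, dim, ph, pw)
  })
}

tok2sp_idx <- function(N, gh, gw, dim) {
  cached(paste("t2s", N, gh, gw, dim), function() {
    arr <- array(seq_len(N * gh * gw * dim), c(N, gh, gw, dim))
    as.vector(aperm(arr, c(1, 4, 2, 3)))
  })
}

sp2tok_idx <- function(N, dim, gh, gw) {
  cached(paste("s2t", N, dim, gh, gw), function() {
    arr <- array(seq_len(N * dim * gh * gw), c(N, dim, gh, gw))
    as.vector(aperm(arr, c(1, 3, 4, 2)))
  })
}

## ---- token grid -------------------------------------------------------------

token_grid <- function(tokens, gh, gw) {
  structure(list(tokens = tokens, gh = as.integer(gh), gw = as.integer(gw)),
            class = "token_grid")
}

tg_dims <- function(tg) {
  d <- dim(tval(tg$tokens))
  list(N = d[1], T = d[2], dim = d[3])
}

tokens_to_spatial <- function(tg) {
  d <- tg_dims(tg)
  t_gather(tg$tokens, tok2sp_idx(d$N, tg$gh, tg$gw, d$dim),
           c(d$N, d$dim, tg$gh, tg$gw))
}

spatial_to_tokens <- function(x) {
  d <- dim(tval(x))
  token_grid(t_gather(x, sp2tok_idx(d[1], d[2], d[3], d[4]),
                      c(d[1], d[3] * d[4], d[2])), d[3], d[4])
}

#' Partition a token grid into non-overlapping windows
#'
#' @param tg a token grid (see [patch_partition_embed()])
#' @param window window size; must divide both grid extents
#' @return tensor of shape (num_windows * batch, window^2, dim)
#' @export
window_partition <- function(tg, window) {
  d <- tg_dims(tg)
  if (tg$gh %% window || tg$gw %% window)
    stop("window_partition: grid ", tg$gh, "x", tg$gw,
         " not divisible by window ", window)
  nw <- (tg$gh %/% window) * (tg$gw %/% window)
  t_gather(tg$tokens, wp_idx(d$N, tg$gh, tg$gw, d$dim, window),
           c(d$N * nw, window * window, d$dim))
}

#' Reassemble windows into a token grid (inverse of [window_partition()])
#'
#' @param blocks tensor from [window_partition()]
#' @param window window size
#' @param gh,gw grid extents
#' @param N batch size
#' @return a token grid
#' @export
window_reverse <- function(blocks, window, gh, gw, N) {
  d <- dim(tval(blocks))
  dimc <- d[3]
  idx <- inv_idx(wp_idx(N, gh, gw, dimc, window))
  token_grid(t_gather(blocks, idx, c(N, gh * gw, dimc)), gh, gw)
}

## ---- window attention --------------------------------------------------------

# relative position bias row index for token pairs, query-fastest ordering
rel_pos_index <- function(win) {
  n <- win * win
  r <- ((seq_len(n) - 1L) %% win) + 1L
  c <- ((seq_len(n) - 1L) %/% win) + 1L
  idx <- integer(n * n)
  for (j in seq_len(n)) {
    dr <- r - r[j] + win - 1L
    dc <- c - c[j] + win - 1L
    idx[(j - 1L) * n + seq_len(n)] <- dr * (2L * win - 1L) + dc + 1L
  }
  idx
}

nn_window_attention <- function(dim, heads, window) {
  if (dim %% heads) stop("window attention: dim ", dim,
                         " not divisible by ", heads, " heads")
  m <- list(
    qkv = nn_linear(dim, 3L * dim),
    proj = nn_linear(dim, dim),
    bias_table = dbh_param(matrix(stats::rnorm((2L * window - 1L)^2 * heads,
                                               sd = 0.02),
                                  (2L * window - 1L)^2, heads)),
    rel_index = rel_pos_index(window),
    heads = as.integer(heads), window = as.integer(window),
    dim = as.integer(dim), scale = (dim / heads)^-0.5
  )
  class(m) <- c("nn_window_attention", "dbh_module")
  m
}

# expand an (nw, n, n) additive mask to the (K*h, n, n) score layout
expand_mask <- function(mask, N, h) {
  nw <- dim(mask)[1]; n <- dim(mask)[2]
  K <- N * nw
  m2 <- matrix(mask, nw, n * n)
  mN <- m2[rep(seq_len(nw), each = N), , drop = FALSE] # rows ordered (batch, window)
  a3 <- aperm(array(as.vector(mN), c(K, n * n, h)), c(1, 3, 2))
  array(a3, c(K * h, n, n))
}

#' Windowed multi-head self-attention on partitioned blocks
#'
#' Scaled dot-product attention with a learned relative position bias,
#' computed independently inside each window.
#'
#' @param attn module from the encoder (holds qkv/proj weights, bias table)
#' @param blocks tensor (num_windows * batch, window^2, dim)
#' @param mask optional additive mask, numeric (K*heads, n, n) in score layout
#' @return tensor of the same shape as `blocks`
#' @export
w_msa <- function(attn, blocks, mask = NULL) {
  d <- dim(tval(blocks))
  K <- d[1]; n <- d[2]; dimc <- d[3]
  h <- attn$heads; dh <- dimc %/% h
  qkv <- fwd(attn$qkv, t_reshape(blocks, c(K * n, dimc)))
  qkv3 <- t_reshape(qkv, c(K, n, 3L * dimc))
  ids <- qkv_split_idx(K, n, dh, h)
  q <- t_gather(qkv3, ids$q, c(K * h, n, dh))
  k <- t_gather(qkv3, ids$k, c(K * h, n, dh))
  v <- t_gather(qkv3, ids$v, c(K * h, n, dh))
  scores <- t_smul(t_bmm(q, k, tB = TRUE), attn$scale)
  bias <- t_index_rows(attn$bias_table, attn$rel_index) # (n^2, h)
  hidx <- cached(paste("b2h", n, h), function() {
    as.vector(aperm(array(seq_len(n * n * h), c(n, n, h)), c(3, 1, 2)))
  })
  bias_hnn <- t_gather(bias, hidx, c(h, n, n))
  scores <- t_add(scores, t_rep_each(bias_hnn, K, c(K * h, n, n)))
  if (!is.null(mask)) scores <- t_addc(scores, mask)
  p <- t_softmax3(scores)
  out <- t_bmm(p, v)
  merged <- t_gather(out, merge_heads_idx(K, n, dh, h), c(K, n, dimc))
  t_reshape(fwd(attn$proj, t_reshape(merged, c(K * n, dimc))), c(K, n, dimc))
}

# additive attention mask for a cyclically shifted grid: tokens from different
# wrapped regions must not attend to each other
shift_attn_mask <- function(gh, gw, win, s) {
  cached(paste("mask", gh, gw, win, s), function() {
    code <- function(ext, r) ifelse(r <= ext - win, 0L, ifelse(r <= ext - s, 1L, 2L))
    img <- outer(code(gh, seq_len(gh)), code(gw, seq_len(gw)),
                 function(a, b) 3L * a + b)
    arr <- array(img, c(win, gh %/% win, win, gw %/% win))
    wm <- matrix(aperm(arr, c(2, 4, 1, 3)), (gh %/% win) * (gw %/% win), win * win)
    nw <- nrow(wm); n <- ncol(wm)
    mask <- array(0, c(nw, n, n))
    for (w in seq_len(nw)) {
      g <- wm[w, ]
      mask[w, , ] <- ifelse(outer(g, g, "!="), -1e9, 0)
    }
    mask
  })
}

#' Shifted-window multi-head self-attention on a token grid
#'
#' Cyclically shifts the grid by `(-shift, -shift)`, applies windowed
#' attention with a mask forbidding attention across wrapped boundaries, and
#' shifts back. `shift = 0` reduces exactly to the unshifted path.
#'
#' @param attn attention module
#' @param tg token grid
#' @param shift shift size, `0 <= shift < window`
#' @param window window size
#' @return a token grid of identical shape
#' @export
sw_msa <- function(attn, tg, shift, window) {
  if (shift < 0 || shift >= window)
    stop("sw_msa: shift must satisfy 0 <= shift < window, got ", shift)
  d <- tg_dims(tg)
  if (shift == 0L) {
    blocks <- window_partition(tg, window)
    return(window_reverse(w_msa(attn, blocks), window, tg$gh, tg$gw, d$N))
  }
  rolled <- token_grid(
    t_gather(tg$tokens, roll_idx(d$N, tg$gh, tg$gw, d$dim, shift),
             dim(tval(tg$tokens))), tg$gh, tg$gw)
  blocks <- window_partition(rolled, window)
  mask <- expand_mask(shift_attn_mask(tg$gh, tg$gw, window, shift), d$N, attn$heads)
  att <- w_msa(attn, blocks, mask)
  back <- window_reverse(att, window, tg$gh, tg$gw, d$N)
  token_grid(
    t_gather(back$tokens, inv_idx(roll_idx(d$N, tg$gh, tg$gw, d$dim, shift)),
             dim(tval(back$tokens))), tg$gh, tg$gw)
}

## ---- blocks and stages -------------------------------------------------------

nn_swin_block <- function(dim, heads, window, shifted, mlp_ratio = 4) {
  hidden <- as.integer(round(dim * mlp_ratio))
  m <- list(
    ln1 = nn_ln(dim),
    attn = nn_window_attention(dim, heads, window),
    ln2 = nn_ln(dim),
    fc1 = nn_linear(dim, hidden),
    fc2 = nn_linear(hidden, dim),
    shifted = shifted, window = as.integer(window)
  )
  class(m) <- c("nn_swin_block", "dbh_module")
  m
}

#' One shifted-window transformer block on a token grid
#'
#' Pre-norm residual attention followed by a pre-norm residual two-layer MLP:
#' `z' = (S)W-MSA(LN(z)) + z; z'' = MLP(LN(z')) + z'`.
#'
#' @param block module from the encoder
#' @param tg token grid
#' @param training unused (kept for interface symmetry)
#' @return a token grid
#' @export
swin_block_forward <- function(block, tg, training = FALSE) {
  d <- tg_dims(tg)
  win <- block$window
  # windows must tile the grid; degenerate grids (== window) get no shift
  shift <- if (block$shifted && tg$gh > win && tg$gw > win) win %/% 2L else 0L
  zn <- t_reshape(fwd(block$ln1, t_reshape(tg$tokens, c(d$N * d$T, d$dim))),
                  c(d$N, d$T, d$dim))
  att <- sw_msa(block$attn, token_grid(zn, tg$gh, tg$gw), shift, win)
  z1 <- t_add(tg$tokens, att$tokens)
  mn <- fwd(block$ln2, t_reshape(z1, c(d$N * d$T, d$dim)))
  mlp <- fwd(block$fc2, t_gelu(fwd(block$fc1, mn)))
  z2 <- t_add(z1, t_reshape(mlp, c(d$N, d$T, d$dim)))
  token_grid(z2, tg$gh, tg$gw)
}

nn_patch_merge <- function(dim) {
  m <- list(norm = nn_ln(4L * dim), reduce = nn_linear(4L * dim, 2L * dim,
                                                       bias = FALSE))
  class(m) <- c("nn_patch_merge", "dbh_module")
  m
}

#' Patch merging: 2x2 token neighborhoods concatenated, then reduced to 2*dim
#'
#' @param pm patch-merge module
#' @param tg token grid with even extents
#' @return token grid at half resolution with doubled dim
#' @export
patch_merging <- function(pm, tg) {
  d <- tg_dims(tg)
  if (tg$gh %% 2L || tg$gw %% 2L)
    stop("patch_merging: grid ", tg$gh, "x", tg$gw, " has odd extent")
  gh2 <- tg$gh %/% 2L; gw2 <- tg$gw %/% 2L
  gath <- t_gather(tg$tokens, pm_idx(d$N, tg$gh, tg$gw, d$dim),
                   c(d$N * gh2 * gw2, 4L * d$dim))
  red <- fwd(pm$reduce, fwd(pm$norm, gath))
  token_grid(t_reshape(red, c(d$N, gh2 * gw2, 2L * d$dim)), gh2, gw2)
}

#' Build the attention-branch encoder
#'
#' @param cfg a [swin_config()]
#' @param out_levels which pyramid levels the consumer uses; output layer
#'   norms exist only for these, so every parameter of a built variant
#'   participates in its forward pass
#' @return a module
#' @export
swin_encoder <- function(cfg = swin_config(), out_levels = 1:4) {
  C <- cfg$embed_dim
  dims <- C * 2L^(0:3)
  stages <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- lapply(seq_len(cfg$depths[s]), function(j) {
      nn_swin_block(dims[s], cfg$heads[s], cfg$window,
                    shifted = (j %% 2L == 0L), mlp_ratio = cfg$mlp_ratio)
    })
    names(blocks) <- paste0("b", seq_along(blocks))
    stages[[s]] <- list(
      blocks = blocks,
      merge = if (s < 4L) nn_patch_merge(dims[s]) else NULL,
      out_norm = if (s %in% out_levels) nn_ln(dims[s]) else NULL
    )
  }
  names(stages) <- paste0("s", 1:4)
  m <- list(
    patch_conv = nn_conv2d(3L, C, k = 4L, stride = 4L, pad = 0L),
    embed_norm = nn_ln(C),
    stages = stages,
    cfg = cfg
  )
  class(m) <- c("swin_encoder", "dbh_module")
  m
}

#' Patch partition + linear embedding
#'
#' Splits the image into non-overlapping 4x4 patches and linearly embeds each
#' patch's 48 raw values to `embed_dim` channels (as a 4x4/stride-4
#' convolution), followed by layer normalization.
#'
#' @param enc encoder from [swin_encoder()]
#' @param image tensor or array (batch, 3, H, W), H and W divisible by 4
#' @param training logical
#' @return a token grid of extents H/4 x W/4 with `embed_dim` channels
#' @export
patch_partition_embed <- function(enc, image, training = FALSE) {
  if (!is_tensor(image)) image <- dbh_const(image)
  d <- dim(tval(image))
  if (d[3] %% 4L || d[4] %% 4L)
    stop("patch_partition_embed: spatial dims ", d[3], "x", d[4],
         " not divisible by patch size 4")
  x <- fwd(enc$patch_conv, image, training)
  tg <- spatial_to_tokens(x)
  dd <- tg_dims(tg)
  token_grid(t_reshape(fwd(enc$embed_norm,
                           t_reshape(tg$tokens, c(dd$N * dd$T, dd$dim))),
                       c(dd$N, dd$T, dd$dim)), tg$gh, tg$gw)
}

#' Encode an image batch with the attention branch
#'
#' @param enc encoder from [swin_encoder()]
#' @param image tensor or array (batch, 3, H, W), H and W divisible by 32
#' @param training logical
#' @return list of 4 spatial tensors at scales 1/4..1/32 with C..8C channels
#' @export
swin_encode <- function(enc, image, training = FALSE) {
  if (!is_tensor(image)) image <- dbh_const(image)
  check_image_batch(image)
  tg <- patch_partition_embed(enc, image, training)
  pyramid <- vector("list", 4L)
  for (s in 1:4) {
    st <- enc$stages[[s]]
    for (b in st$blocks) tg <- swin_block_forward(b, tg, training)
    if (!is.null(st$out_norm)) {
      d <- tg_dims(tg)
      normed <- token_grid(
        t_reshape(fwd(st$out_norm, t_reshape(tg$tokens, c(d$N * d$T, d$dim))),
                  c(d$N, d$T, d$dim)), tg$gh, tg$gw)
      pyramid[[s]] <- tokens_to_spatial(normed)
    }
    if (!is.null(st$merge)) tg <- patch_merging(st$merge, tg)
  }
  pyramid
}
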