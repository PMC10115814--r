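# Attention branch: patch embedding, window machinery, attention vs a dense
# oracle, shifted-window masking, patch merging, stage shapes and the
# closed-form parameter count.

test_that("patch embedding produces the expected token grid", {
  set.seed(31)
  enc <- swin_encoder(swin_config())
  tg <- with_no_grad(patch_partition_embed(enc, rand4(1, 3, 224, 224)))
  expect_equal(c(tg$gh, tg$gw), c(56L, 56L))
  expect_equal(dim(tval(tg$tokens)), c(1L, 3136L, 96L))
  # constant image -> all patches identical -> identical tokens
  tgc <- with_no_grad(patch_partition_embed(enc, array(0.3, c(1, 3, 32, 32))))
  tok <- tval(tgc$tokens)[1, , ]
  expect_lt(max(abs(sweep(tok, 2, tok[1, ]))), 1e-10)
  expect_error(patch_partition_embed(enc, dbh_const(rand4(1, 3, 30, 32))),
               "divisible by patch size")
})

test_that("patch embedding equals brute-force patch flattening", {
  set.seed(32)
  # identity-like embedding: kernel that copies the 48 raw patch values
  enc <- swin_encoder(swin_config(embed_dim = 48L, heads = c(3L, 6L, 12L, 24L)))
  w <- array(0, c(48, 3, 4, 4))
  k <- 0L
  for (j in 1:4) for (i in 1:4) for (c in 1:3) {
    k <- k + 1L
    w[k, c, i, j] <- 1
  }
  enc$patch_conv$w$value <- w
  enc$patch_conv$b$value <- rep(0, 48)
  enc$embed_norm$gamma$value <- rep(1, 48) # LN still applies; compare pre-norm
  x <- rand4(1, 3, 8, 8)
  emb <- with_no_grad(fwd(enc$patch_conv, dbh_const(x)))
  v <- tval(emb) # (1, 48, 2, 2)
  for (pi in 1:2) for (pj in 1:2) {
    hand <- as.vector(vapply(1:4, function(j) vapply(1:4, function(i)
      x[1, , (pi - 1) * 4 + i, (pj - 1) * 4 + j], numeric(3)), matrix(0, 3, 4)))
    expect_equal(v[1, , pi, pj], hand, tolerance = 1e-12)
  }
})

test_that("window partition enumerates and inverts exactly", {
  tok <- array(1:16, c(1, 16, 1))
  tg <- dbhnet:::token_grid(dbh_const(tok), 4, 4)
  bl <- tval(window_partition(tg, 2))
  expect_equal(dim(bl), c(4L, 4L, 1L))
  # hand enumeration: grid is row-fastest, so window 1 holds tokens 1,2,5,6
  expect_equal(bl[1, , 1], c(1, 2, 5, 6))
  expect_equal(bl[2, , 1], c(3, 4, 7, 8))
  expect_equal(bl[3, , 1], c(9, 10, 13, 14))
  expect_equal(bl[4, , 1], c(11, 12, 15, 16))
  set.seed(33)
  tgr <- dbhnet:::token_grid(dbh_const(array(rnorm(2 * 3136 * 8), c(2, 3136, 8))), 56, 56)
  rt <- window_reverse(window_partition(tgr, 7), 7, 56, 56, 2)
  expect_identical(tval(rt$tokens), tval(tgr$tokens))
  expect_equal(dim(tval(window_partition(tgr, 7))), c(2L * 64L, 49L, 8L))
  expect_error(window_partition(tgr, 5), "not divisible")
})

test_that("windowed attention equals the dense-attention oracle", {
  set.seed(34)
  for (h in c(1L, 2L, 4L)) {
    att <- dbhnet:::nn_window_attention(8L, h, 3L)
    att$qkv$w$value <- matrix(rnorm(8 * 24, sd = 0.2), 8)
    att$qkv$b$value <- rnorm(24, sd = 0.1)
    att$proj$w$value <- matrix(rnorm(64, sd = 0.2), 8)
    x <- array(rnorm(2 * 9 * 8), c(2, 9, 8))
    y <- tval(with_no_grad(w_msa(att, dbh_const(x))))
    for (kk in 1:2)
      expect_equal(y[kk, , ], dense_attention_oracle(att, x[kk, , ]),
                   tolerance = 1e-10)
  }
  # full 7x7 window at stage-1 width
  att7 <- dbhnet:::nn_window_attention(96L, 3L, 7L)
  att7$qkv$w$value <- matrix(rnorm(96 * 288, sd = 0.1), 96)
  x7 <- array(rnorm(49 * 96), c(1, 49, 96))
  y7 <- tval(with_no_grad(w_msa(att7, dbh_const(x7))))
  expect_equal(y7[1, , ], dense_attention_oracle(att7, x7[1, , ]),
               tolerance = 1e-5)
})

test_that("attention degenerates correctly on trivial windows", {
  set.seed(35)
  att <- dbhnet:::nn_window_attention(6L, 2L, 1L)
  # single token per window: softmax of one logit is 1 -> proj(V) exactly
  x <- array(rnorm(3 * 1 * 6), c(3, 1, 6))
  y <- tval(with_no_grad(w_msa(att, dbh_const(x))))
  for (kk in 1:3) {
    QKV <- x[kk, , , drop = TRUE] %*% tval(att$qkv$w) + tval(att$qkv$b)
    V <- QKV[13:18]
    expect_equal(y[kk, 1, ], as.vector(V %*% tval(att$proj$w)) + tval(att$proj$b),
                 tolerance = 1e-12)
  }
  # identical tokens in a window -> uniform attention, identical outputs
  att3 <- dbhnet:::nn_window_attention(8L, 2L, 2L)
  xi <- array(rep(rnorm(8), each = 4), c(1, 4, 8))
  yi <- tval(with_no_grad(w_msa(att3, dbh_const(xi))))[1, , ]
  expect_lt(max(abs(sweep(yi, 2, yi[1, ]))), 1e-12)
})

test_that("shifted attention: zero shift equals the plain path, masking isolates groups", {
  set.seed(36)
  att <- dbhnet:::nn_window_attention(8L, 2L, 2L)
  x <- array(rnorm(16 * 8), c(1, 16, 8))
  tg <- dbhnet:::token_grid(dbh_const(x), 4, 4)
  s0 <- tval(sw_msa(att, tg, 0L, 2L)$tokens)
  direct <- tval(window_reverse(w_msa(att, window_partition(tg, 2L)), 2L, 4L, 4L, 1L)$tokens)
  expect_equal(s0, direct, tolerance = 1e-14)
  expect_error(sw_msa(att, tg, 2L, 2L), "shift")

  # mask isolation: perturbing one mask group never leaks into another.
  # With a 4x4 grid, window 2, shift 1 the wrapped row/column groups are
  # separated; check every token's group only responds to itself.
  base <- tval(sw_msa(att, tg, 1L, 2L)$tokens)[1, , ]
  rc <- cbind(((1:16 - 1) %% 4) + 1, ((1:16 - 1) %/% 4) + 1)
  # group code on the shifted grid (roll by -1): shifted pos = orig - 1 (wrapped)
  shifted <- cbind(((rc[, 1] - 2) %% 4) + 1, ((rc[, 2] - 2) %% 4) + 1)
  code <- function(p) ifelse(p <= 2, 0L, ifelse(p <= 3, 1L, 2L))
  grp <- 3L * code(shifted[, 1]) + code(shifted[, 2])
  for (g in unique(grp)) {
    xz <- x
    xz[1, grp == g, ] <- xz[1, grp == g, ] + 5
    pert <- tval(sw_msa(att, dbhnet:::token_grid(dbh_const(xz), 4, 4), 1L, 2L)$tokens)[1, , ]
    moved <- apply(abs(pert - base), 1, max) > 1e-9
    # masking: only the perturbed group's own tokens may change
    expect_true(all(grp[moved] == g))
  }
})

test_that("residual structure makes zeroed blocks the identity", {
  set.seed(37)
  blk <- dbhnet:::nn_swin_block(8L, 2L, 2L, shifted = FALSE)
  blk$attn$proj$w$value[] <- 0
  blk$attn$proj$b$value[] <- 0
  blk$fc2$w$value[] <- 0
  blk$fc2$b$value[] <- 0
  x <- array(rnorm(2 * 16 * 8), c(2, 16, 8))
  tg <- dbhnet:::token_grid(dbh_const(x), 4, 4)
  out <- with_no_grad(swin_block_forward(blk, tg))
  expect_equal(tval(out$tokens), x, tolerance = 1e-12)
})

test_that("patch merging concatenates 2x2 neighborhoods in the declared order", {
  pm <- dbhnet:::nn_patch_merge(1L)
  # identity-like: LN disabled via gamma=1/beta=0 on a constant-free check is
  # awkward; instead check the gather order directly through the index map
  idx <- dbhnet:::pm_idx(1L, 4L, 4L, 1L)
  gathered <- matrix((1:16)[idx], 4, 4) # (tokens, 4*dim)
  # token grid row-fastest: block (1,1) holds grid tokens 1,2,5,6 and the
  # concat order is (even,even),(odd,even),(even,odd),(odd,odd)
  expect_equal(gathered[1, ], c(1, 2, 5, 6))
  expect_equal(gathered[2, ], c(3, 4, 7, 8))
  set.seed(38)
  tg <- dbhnet:::token_grid(dbh_const(array(rnorm(2 * 16 * 6), c(2, 16, 6))), 4, 4)
  out <- with_no_grad(patch_merging(dbhnet:::nn_patch_merge(6L), tg))
  expect_equal(c(out$gh, out$gw), c(2L, 2L))
  expect_equal(dim(tval(out$tokens)), c(2L, 4L, 12L))
  tg1 <- dbhnet:::token_grid(dbh_const(array(rnorm(4 * 6), c(1, 4, 6))), 2, 2)
  out1 <- with_no_grad(patch_merging(dbhnet:::nn_patch_merge(6L), tg1))
  expect_equal(c(out1$gh, out1$gw, dim(tval(out1$tokens))[3]), c(1L, 1L, 12L))
})

swin_count <- function(C, depths, heads, win, mlp = 4) {
  dims <- C * 2^(0:3)
  total <- 4 * 4 * 3 * C + C + 2 * C # patch conv (+bias) + embedding LN
  for (s in 1:4) {
    D <- dims[s]
    per_block <- 2 * D + (3 * D^2 + 3 * D) + (2 * win - 1)^2 * heads[s] +
      (D^2 + D) + 2 * D + (D * mlp * D + mlp * D) + (mlp * D * D + D)
    total <- total + depths[s] * per_block + 2 * D # blocks + stage output LN
    if (s < 4) total <- total + 2 * 4 * D + 4 * D * 2 * D # merge LN + reduction
  }
  total
}

test_that("stage outputs obey the pyramid contract and the parameter closed form", {
  set.seed(39)
  enc <- swin_encoder(swin_config())
  pyr <- with_no_grad(swin_encode(enc, rand4(1, 3, 224, 224)))
  expect_equal(lapply(pyr, function(p) dim(tval(p))),
               list(c(1L, 96L, 56L, 56L), c(1L, 192L, 28L, 28L),
                    c(1L, 384L, 14L, 14L), c(1L, 768L, 7L, 7L)))
  expect_equal(as.integer(count_parameters(enc)),
               swin_count(96, c(2, 2, 6, 2), c(3, 6, 12, 24), 7))
  # the published tiny encoder is quoted at 28 M; ours is encoder-only
  expect_lt(abs(attr(count_parameters(enc), "millions") - 28) / 28, 0.03)
  # tiny config: closed form again, plus determinism
  cfg <- swin_config(embed_dim = 16L, depths = c(1L, 1L, 1L, 1L),
                     heads = c(2L, 2L, 2L, 2L), window = 2L)
  enc2 <- swin_encoder(cfg)
  expect_equal(as.integer(count_parameters(enc2)),
               swin_count(16, c(1, 1, 1, 1), c(2, 2, 2, 2), 2))
  x <- rand4(2, 3, 64, 64)
  p1 <- with_no_grad(swin_encode(enc2, x))
  p2 <- with_no_grad(swin_encode(enc2, x))
  for (i in 1:4) expect_equal(tval(p1[[i]]), tval(p2[[i]]), tolerance = 1e-12)
  expect_equal(lapply(p1, function(p) dim(tval(p))),
               list(c(2L, 16L, 16L, 16L), c(2L, 32L, 8L, 8L),
                    c(2L, 64L, 4L, 4L), c(2L, 128L, 2L, 2L)))
})
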