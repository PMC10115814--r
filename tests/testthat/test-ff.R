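# Fusion module: shape contracts at all scales, annihilator and commutativity
# properties of the Hadamard interaction, pencil-and-paper oracles with
# 1x1-equivalent weights, and the threading of fusion outputs across scales.

# set all refinement convs to pure center-tap (1x1-equivalent) maps with the
# given per-module scalar, disable BN scaling (identity in eval mode)
make_linear_ff <- function(mod, s_st = 1, s_u = 1, s_ff = 1) {
  center_tap <- function(cv, s) {
    w <- tval(cv$conv$w) * 0
    co <- dim(w)[1]; ci <- dim(w)[2]
    for (k in seq_len(min(co, ci))) w[k, k, 2, 2] <- s
    cv$conv$w$value <- w
    cv$conv$b$value <- rep(0, co)
  }
  center_tap(mod$w_st, s_st)
  center_tap(mod$w_u, s_u)
  if (!is.null(mod$w_ff)) {
    w <- tval(mod$w_ff$conv$w) * 0
    ci <- dim(w)[2]
    for (k in seq_len(ci)) w[k, k, 2, 2] <- s_ff
    mod$w_ff$conv$w$value <- w
    mod$w_ff$conv$b$value <- rep(0, dim(w)[1])
  }
  mod
}

eval_bn_scale <- 1 / sqrt(1 + 1e-5) # eval-mode BN with fresh running stats

test_that("fusion preserves the branch shape at every scale", {
  set.seed(51)
  stack <- nn_ff_stack(8L)
  st_pyr <- list(rand4(1, 8, 16, 16), rand4(1, 16, 8, 8),
                 rand4(1, 32, 4, 4), rand4(1, 64, 2, 2))
  u_pyr <- lapply(st_pyr, function(a) array(rnorm(length(a)), dim(a)))
  ffs <- with_no_grad(fuse_pyramids(stack, lapply(st_pyr, dbh_const),
                                    lapply(u_pyr, dbh_const)))
  for (i in 1:4) expect_equal(dim(tval(ffs[[i]])), dim(st_pyr[[i]]))
  expect_error(ff_forward(stack$ff1, dbh_const(rand4(1, 8, 16, 16)),
                          dbh_const(rand4(1, 8, 8, 8))), "differ in shape")
  expect_error(ff_forward(stack$ff2, dbh_const(rand4(1, 16, 8, 8)),
                          dbh_const(rand4(1, 16, 8, 8)),
                          dbh_const(rand4(1, 8, 32, 32))), "2x the spatial size")
})

test_that("a zeroed refinement annihilates the interaction map", {
  set.seed(52)
  mod <- nn_ff_module(4L, has_prev = FALSE)
  mod$w_st$conv$w$value[] <- 0
  mod$w_st$conv$b$value[] <- 0
  st <- rand4(1, 4, 4, 4); u <- rand4(1, 4, 4, 4)
  f_st <- with_no_grad(fwd(mod$w_st, dbh_const(st)))
  expect_true(all(tval(f_st) == 0)) # conv 0 -> BN(0)=0 (beta 0) -> ReLU 0
  f_u <- with_no_grad(fwd(mod$w_u, dbh_const(u)))
  b <- tval(f_st) * tval(f_u)
  expect_true(all(b == 0))
})

test_that("the interaction map is symmetric under factor permutation", {
  set.seed(53)
  a <- abs(rand4(1, 3, 4, 4)); b <- abs(rand4(1, 3, 4, 4)); c3 <- abs(rand4(1, 3, 4, 4))
  t1 <- tval(dbhnet:::t_mul(dbhnet:::t_mul(dbh_const(a), dbh_const(b)), dbh_const(c3)))
  t2 <- tval(dbhnet:::t_mul(dbhnet:::t_mul(dbh_const(c3), dbh_const(a)), dbh_const(b)))
  # commutative up to floating-point re-association of the product
  expect_equal(t1, t2, tolerance = 1e-14)
  # and exactly symmetric when the association order is preserved
  t3 <- tval(dbhnet:::t_mul(dbhnet:::t_mul(dbh_const(b), dbh_const(a)), dbh_const(c3)))
  expect_identical(t1, t3)
})

test_that("fusion equals a pencil-and-paper oracle with 1x1-equivalent weights", {
  set.seed(54)
  mod <- make_linear_ff(nn_ff_module(2L, has_prev = TRUE), 2, 3, 1)
  st <- array(c(1, 2, 2, 4, 3, 6, 4, 8, 5, 10, 6, 12, 7, 14, 8, 16), c(1, 2, 2, 2)) / 4
  u <- array(rep(c(1, -1), 8), c(1, 2, 2, 2)) / 2
  # the previous-scale fusion output carries half the channels (here 1)
  prev <- dbh_const(array(seq(0.1, 1.6, by = 0.1), c(1, 1, 4, 4)))
  # oracle: refined maps are center-tap scalings through an identity-like BN
  f_st <- pmax(st * 2 * eval_bn_scale, 0)
  f_u <- pmax(u * 3 * eval_bn_scale, 0)
  pooled <- tval(dbhnet:::t_maxpool3s2(prev))
  # w_ff maps channel 1 of the pooled map onto output channel 1; channel 2
  # of the refinement has all-zero weights under the center-tap construction
  f_ff <- array(0, c(1, 2, 2, 2))
  f_ff[, 1, , ] <- pmax(pooled[, 1, , ] * eval_bn_scale, 0)
  b_ref <- f_st * f_u * f_ff
  # read the implementation's b by reconstructing from its refined maps
  f_st_i <- tval(with_no_grad(fwd(mod$w_st, dbh_const(st))))
  f_u_i <- tval(with_no_grad(fwd(mod$w_u, dbh_const(u))))
  f_ff_i <- tval(with_no_grad(fwd(mod$w_ff, dbhnet:::t_maxpool3s2(prev))))
  expect_equal(f_st_i, f_st, tolerance = 1e-12)
  expect_equal(f_u_i, f_u, tolerance = 1e-12)
  expect_equal(f_ff_i, f_ff, tolerance = 1e-12)
  expect_equal(f_st_i * f_u_i * f_ff_i, b_ref, tolerance = 1e-12)
})

test_that("zeroing the previous fusion output reduces to the two-input form", {
  set.seed(55)
  mod <- nn_ff_module(2L, has_prev = TRUE)
  st <- dbh_const(rand4(1, 2, 2, 2)); u <- dbh_const(rand4(1, 2, 2, 2))
  zero_prev <- dbh_const(array(0, c(1, 1, 4, 4)))
  # with beta=0 the refined zero map is zero, so b = 0: the fused output
  # equals the residual map of concat[st, u, 0]
  y1 <- tval(with_no_grad(ff_forward(mod, st, u, zero_prev)))
  mod2 <- nn_ff_module(2L, has_prev = FALSE)
  for (nm in c("w_st", "w_u", "res1", "res2", "shortcut")) {
    p1 <- collect_params(mod[[nm]]); p2 <- collect_params(mod2[[nm]])
    for (k in seq_along(p1)) p2[[k]]$value <- p1[[k]]$value
  }
  st_r <- with_no_grad(fwd(mod2$w_st, st))
  u_r <- with_no_grad(fwd(mod2$w_u, u))
  bzero <- dbh_const(tval(st_r) * tval(u_r) * 0)
  cc <- dbhnet:::t_cat_ch(list(st, u, bzero))
  main <- with_no_grad(fwd(mod2$res2, fwd(mod2$res1, cc)))
  ref <- tval(dbhnet:::t_relu(dbhnet:::t_add(main,
         with_no_grad(fwd(mod2$shortcut, cc)))))
  expect_equal(y1, ref, tolerance = 1e-12)
})

test_that("a depth-1 residual merge is supported and keeps the contract", {
  set.seed(56)
  mod <- nn_ff_module(4L, has_prev = FALSE, residual_depth = 1L)
  expect_null(mod$res2)
  y <- with_no_grad(ff_forward(mod, dbh_const(rand4(1, 4, 4, 4)),
                               dbh_const(rand4(1, 4, 4, 4))))
  expect_equal(dim(tval(y)), c(1L, 4L, 4L, 4L))
})
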