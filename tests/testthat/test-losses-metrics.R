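# Loss terms, metric formulas, their algebraic identities and aggregation.

test_that("uniform predictions give exactly ln 2 per pixel", {
  lg <- array(0.5, c(1, 2, 4, 4)) # equal logits in both channels
  expect_equal(tval(pixel_ce(lg, array(1, c(1, 4, 4)))), log(2), tolerance = 1e-12)
  expect_equal(tval(pixel_ce(lg, array(0, c(1, 4, 4)))), log(2), tolerance = 1e-12)
})

test_that("the loss vanishes as predictions approach the truth", {
  set.seed(71)
  g <- array(rbinom(16, 1, 0.5), c(1, 4, 4))
  conf <- function(scale) {
    lg <- array(0, c(1, 2, 4, 4))
    lg[1, 2, , ] <- scale * (2 * g[1, , ] - 1)
    tval(pixel_ce(lg, g))
  }
  expect_lt(conf(20), 1e-8)
  expect_gt(conf(1), conf(5)) # strictly decreasing toward the truth
  expect_gt(conf(5), conf(20))
})

test_that("pixel cross-entropy equals an explicit per-pixel summation", {
  set.seed(72)
  lg <- array(rnorm(2 * 2 * 16), c(2, 2, 4, 4))
  g <- array(rbinom(32, 1, 0.5), c(2, 4, 4))
  ref <- 0
  for (n in 1:2) for (h in 1:4) for (w in 1:4) {
    p1 <- exp(lg[n, 2, h, w]) / (exp(lg[n, 1, h, w]) + exp(lg[n, 2, h, w]))
    ref <- ref - (g[n, h, w] * log(p1) + (1 - g[n, h, w]) * log(1 - p1))
  }
  expect_equal(tval(pixel_ce(lg, g)), ref / 32, tolerance = 1e-6)
  expect_error(pixel_ce(lg, g + 0.5), "binary")
  expect_error(pixel_ce(lg, array(0, c(2, 4, 5))), "shape")
})

test_that("the total loss is the stated convex combination", {
  expect_equal(tval(total_loss(1, 1, 1, loss_weights(0.5, 0.2, 0.3))), 1)
  expect_equal(tval(total_loss(0.2, 0.4, 0.6, loss_weights(0.5, 0.2, 0.3))),
               0.36, tolerance = 1e-12)
  w <- loss_weights()
  expect_equal(c(w$alpha, w$beta, w$gamma), c(0.5, 0.2, 0.3)) # defaults
  expect_error(loss_weights(0.5, 0.2, 0.2), "sum to 1")
  expect_error(loss_weights(1.2, -0.1, -0.1), "\\[0, 1\\]")
  # linearity and permutation invariance with permuted weights
  expect_equal(tval(total_loss(3, 1, 2, loss_weights(0.5, 0.2, 0.3))),
               tval(total_loss(1, 2, 3, loss_weights(0.2, 0.3, 0.5))))
})

test_that("confusion counts match hand counts and sum to the pixel total", {
  pred <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  gt <- matrix(c(1, 0, 0, 0, 1, 0, 0, 1, 1), 3, byrow = TRUE)
  cts <- confusion(pred, gt)
  expect_equal(cts, list(tp = 3, fp = 1, fn = 1, tn = 4))
  expect_equal(cts$tp + cts$fp + cts$fn + cts$tn, 9)
  g2 <- matrix(rbinom(25, 1, 0.4), 5)
  expect_equal(confusion(g2, g2)[c("fp", "fn")], list(fp = 0, fn = 0))
  inv <- confusion(1 - g2, g2)
  expect_equal(inv[c("tp", "tn")], list(tp = 0, tn = 0))
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the seven metrics evaluate their formulas exactly", {
  m <- metrics_from_counts(list(tp = 50, fp = 10, fn = 10, tn = 30))
  expect_equal(m$iou, 5 / 7, tolerance = 1e-12)
  expect_equal(m$dice, 10 / 12, tolerance = 1e-12)
  expect_equal(m$acc, 0.8)
  expect_equal(m$recall, 50 / 60)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$specificity, 30 / 40)
  perfect <- metrics_from_counts(list(tp = 7, fp = 0, fn = 0, tn = 9))
  expect_true(all(unlist(perfect) == 1))
})

test_that("F1 == Dice and Dice = 2*IOU/(1+IOU) for every confusion table", {
  set.seed(73)
  for (k in 1:50) {
    cts <- as.list(stats::setNames(rmultinom(1, 400, runif(4, 0.05, 1))[, 1],
                                   c("tp", "fp", "fn", "tn")))
    m <- metrics_from_counts(cts)
    expect_equal(m$f1, m$dice, tolerance = 1e-12)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
  }
})

test_that("degenerate denominators follow the vacuous-truth convention", {
  empty <- metrics_from_counts(list(tp = 0, fp = 0, fn = 0, tn = 16))
  expect_equal(empty$iou, 1)     # nothing to find, nothing predicted
  expect_equal(empty$recall, 1)
  expect_equal(empty$precision, 1)
  expect_equal(empty$f1, 1)
  missed <- metrics_from_counts(list(tp = 0, fp = 0, fn = 5, tn = 11))
  expect_equal(missed$precision, 1) # no false alarms...
  expect_equal(missed$recall, 0)    # ...but everything missed
  expect_equal(missed$f1, 0)
})

test_that("metrics are invariant under simultaneous spatial permutation", {
  set.seed(74)
  p <- matrix(rbinom(36, 1, 0.5), 6)
  g <- matrix(rbinom(36, 1, 0.5), 6)
  perm <- sample(36)
  m1 <- metrics_from_counts(confusion(p, g))
  m2 <- metrics_from_counts(confusion(matrix(p[perm], 6), matrix(g[perm], 6)))
  expect_equal(m1, m2)
})

test_that("aggregation reports mean, population sd and the dataset-level F1", {
  r1 <- metrics_from_counts(list(tp = 30, fp = 10, fn = 5, tn = 55))
  r2 <- metrics_from_counts(list(tp = 20, fp = 2, fn = 12, tn = 66))
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(unname(agg$mean["iou"]), (r1$iou + r2$iou) / 2)
  expect_equal(unname(agg$sd["iou"]), abs(r1$iou - r2$iou) / 2) # population sd, n=2
  mp <- (r1$precision + r2$precision) / 2
  mr <- (r1$recall + r2$recall) / 2
  expect_equal(agg$dataset_f1, 2 * mp * mr / (mp + mr), tolerance = 1e-12)
  single <- aggregate_reports(list(r1))
  expect_equal(unname(single$mean["dice"]), r1$dice)
  expect_equal(unname(single$sd["dice"]), 0)
  expect_error(aggregate_reports(list()), "empty")
  expect_match(agg$summary[1], "^0\\.\\d{3} . 0\\.\\d{3}$")
})

test_that("metric CSV round-trips per-image rows plus a summary row", {
  rows <- list(
    list(id = "a", counts = list(tp = 5, fp = 1, fn = 2, tn = 8),
         metrics = metrics_from_counts(list(tp = 5, fp = 1, fn = 2, tn = 8))),
    list(id = "b", counts = list(tp = 9, fp = 0, fn = 0, tn = 7),
         metrics = metrics_from_counts(list(tp = 9, fp = 0, fn = 0, tn = 7)))
  )
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(rows, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 3)
  expect_equal(df$id, c("a", "b", "summary"))
  # the summary row mixes "mean ± sd" strings into numeric columns
  expect_equal(as.numeric(df$iou[1]), 5 / 8)
  expect_match(df$iou[3], "±")
})

test_that("the single-channel sigmoid head uses binary cross-entropy", {
  set.seed(75)
  lg <- array(rnorm(16), c(1, 1, 4, 4))
  g <- array(rbinom(16, 1, 0.5), c(1, 4, 4))
  p <- 1 / (1 + exp(-as.numeric(lg)))
  ref <- -mean(g * log(p) + (1 - g) * log(1 - p))
  expect_equal(tval(pixel_ce(lg, g)), ref, tolerance = 1e-10)
  # gradient against finite differences
  expect_lt(grad_err(function(t) pixel_ce(t, g), lg), 1e-6)
  # sigma(0) = 0.5 -> ln 2 at maximal uncertainty, matching the 2-channel head
  expect_equal(tval(pixel_ce(array(0, c(1, 1, 4, 4)), g)), log(2),
               tolerance = 1e-12)
})
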