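# Closed forms of the box-similarity terms, Hungarian matching, and the
# combined loss.

test_that("squared Wasserstein distance matches the 4-vector closed form", {
  expect_equal(wasserstein2_sq(c(0, 0, 2, 2), c(3, 4, 2, 2)), 25)
  expect_equal(wasserstein2_sq(c(1, 1, 2, 4), c(1, 1, 2, 4)), 0)
  # symmetry over random boxes
  set.seed(4)
  a <- cbind(runif(20), runif(20), runif(20, .1, 1), runif(20, .1, 1))
  b <- cbind(runif(20), runif(20), runif(20, .1, 1), runif(20, .1, 1))
  expect_equal(wasserstein2_sq(a, b), wasserstein2_sq(b, a))
  expect_error(wasserstein2_sq(c(0, 0, -1, 2), c(0, 0, 1, 1)), "positive")
})

test_that("NWD hand cases, bounds, and monotone decay hold", {
  expect_equal(nwd(c(0, 0, 2, 2), c(3, 4, 2, 2), C = 1), exp(-5))
  expect_equal(nwd(c(0, 0, 2, 2), c(0, 0, 4, 4), C = 1), exp(-sqrt(2)))
  expect_equal(nwd(c(0, 0, 2, 2), c(0, 0, 2, 2), C = 7), 1)
  # squared-exponent reading of the published formula
  expect_equal(nwd(c(0, 0, 2, 2), c(3, 4, 2, 2), C = 1,
                   squared_exponent = TRUE), exp(-25))
  # bounds and monotone decay with center distance
  offs <- seq(0, 3, by = 0.25)
  vals <- vapply(offs, function(d) nwd(c(0, 0, 1, 1), c(d, 0, 1, 1), C = 2),
                 numeric(1))
  expect_true(all(vals > 0 & vals <= 1))
  expect_true(all(diff(vals) < 0))
  # monotone decay with size mismatch
  sizes <- seq(1, 3, by = 0.25)
  vals2 <- vapply(sizes, function(s) nwd(c(0, 0, 1, 1), c(0, 0, s, s), C = 2),
                  numeric(1))
  expect_true(all(diff(vals2) < 0))
  expect_error(nwd(c(0, 0, 1, 1), c(0, 0, 1, 1), C = -1), "positive")
})

test_that("NWD is less size-sensitive than IoU at fixed absolute offset", {
  small_a <- c(0, 0, 2, 2); small_b <- c(1, 0, 2, 2)
  large_a <- c(0, 0, 20, 20); large_b <- c(1, 0, 20, 20)
  d_iou <- abs(iou(small_a, small_b) - iou(large_a, large_b))
  d_nwd <- abs(nwd(small_a, small_b, C = 10) - nwd(large_a, large_b, C = 10))
  expect_lt(d_nwd, d_iou)
})

test_that("GIoU matches hand geometry and limits", {
  expect_equal(giou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(giou(c(0, 0, 1, 1), c(0.5, 0, 1, 1)), 1 / 3)
  # disjoint unit boxes drifting apart approach -1
  far <- giou(c(0, 0, 1, 1), c(100, 0, 1, 1))
  expect_lt(far, -0.97)
  # always > -1, <= 1
  set.seed(5)
  a <- cbind(runif(50, -2, 2), runif(50, -2, 2), runif(50, .1, 2), runif(50, .1, 2))
  b <- cbind(runif(50, -2, 2), runif(50, -2, 2), runif(50, .1, 2), runif(50, .1, 2))
  g <- giou(a, b)
  expect_true(all(g > -1 & g <= 1))
})

test_that("Hungarian matching equals brute force for n <= 6", {
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  set.seed(6)
  for (trial in 1:25) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    a <- germdetr:::solve_assignment(cost)
    best <- min(vapply(perms_of(seq_len(n)),
                       function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(sum(cost[cbind(seq_len(n), a)]), best, tolerance = 1e-12)
  }
  # the 2x2 diagonal case
  expect_equal(germdetr:::solve_assignment(matrix(c(1, 10, 10, 1), 2)),
               c(1L, 2L))
})

test_that("hungarian_match assigns obvious pairs and handles empties", {
  preds <- list(boxes = rbind(c(0.5, 0.5, 0.1, 0.1), c(0.9, 0.9, 0.1, 0.1)),
                probs = rbind(c(0.9, 0.1), c(0.5, 0.5)))
  tgt <- det_tbl("a", 0L, 0.5, 0.5, 0.1, 0.1)
  m <- hungarian_match(preds, tgt)
  expect_equal(m$query, 1L)
  m0 <- hungarian_match(preds, tgt[0, ])
  expect_equal(nrow(m0), 0L)
  many <- det_tbl("a", c(0L, 1L, 0L), c(.1, .5, .9), .5, .1, .1)
  expect_error(hungarian_match(preds, many), "more targets")
})

test_that("total_loss vanishes on perfect boxes and degenerates to GIoU at r = 0", {
  tgt <- det_tbl("a", c(0L, 1L), c(0.3, 0.7), c(0.4, 0.6), 0.1, 0.2)
  probs <- matrix(1e-7, 4, 2)
  probs[1, 1] <- 1 - 1e-7; probs[2, 2] <- 1 - 1e-7
  preds <- list(boxes = rbind(as.matrix(tgt[, c("cx", "cy", "w", "h")]),
                              c(0.1, 0.1, 0.05, 0.05), c(0.9, 0.1, 0.05, 0.05)),
                probs = probs)
  res <- total_loss(preds, tgt)
  bd <- res$breakdown
  expect_equal(bd$value[bd$term == "box"], 0, tolerance = 1e-12)
  expect_equal(bd$value[bd$term == "l1"], 0, tolerance = 1e-12)
  # r = 0: box term equals mean(1 - GIoU) of the matched pairs
  preds2 <- preds
  preds2$boxes[1, 1] <- preds2$boxes[1, 1] + 0.05
  p0 <- nwd_params(r = 0)
  res2 <- total_loss(preds2, tgt, p0)
  m <- res2$matches
  pb <- preds2$boxes[m$query, , drop = FALSE]
  tb <- as.matrix(tgt[m$target, c("cx", "cy", "w", "h")])
  expect_equal(res2$breakdown$value[res2$breakdown$term == "box"],
               mean(1 - giou(pb, tb)), tolerance = 1e-12)
})

test_that("box loss term decreases monotonically as the center offset shrinks", {
  tgt <- det_tbl("a", 0L, 0.5, 0.5, 0.2, 0.2)
  offsets <- seq(0.2, 0, by = -0.02)
  vals <- vapply(offsets, function(d) {
    preds <- list(boxes = matrix(c(0.5 + d, 0.5, 0.2, 0.2), 1),
                  probs = matrix(c(1 - 1e-7, 1e-7), 1))
    res <- total_loss(preds, tgt)
    res$breakdown$value[res$breakdown$term == "box"]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[length(vals)], 0, tolerance = 1e-12)
})

test_that("autodiff box terms agree with closed forms and finite differences", {
  pb <- germdetr:::gd_param(matrix(c(.4, .4, .2, .3, .6, .5, .25, .2),
                                   2, 4, byrow = TRUE))
  tb <- matrix(c(.45, .42, .22, .28, .55, .52, .2, .22), 2, 4, byrow = TRUE)
  gt <- germdetr:::gd_giou(pb, germdetr:::gd_tensor(tb))
  expect_equal(as.vector(gt$value), giou(pb$value, tb), tolerance = 1e-12)
  nt <- germdetr:::gd_nwd(pb, germdetr:::gd_tensor(tb), C = 1)
  expect_equal(as.vector(nt$value), nwd(pb$value, tb, C = 1), tolerance = 1e-9)
  # finite differences on the mean GIoU
  f <- function() germdetr:::gd_mean(germdetr:::gd_giou(pb, germdetr:::gd_tensor(tb)))
  out <- f()
  germdetr:::gd_zero_grad(list(pb))
  germdetr:::gd_backward(out)
  g <- pb$grad
  eps <- 1e-6
  for (i in c(1, 3, 6, 8)) {
    v0 <- pb$value[i]
    pb$value[i] <- v0 + eps; up <- as.vector(f()$value)
    pb$value[i] <- v0 - eps; dn <- as.vector(f()$value)
    pb$value[i] <- v0
    expect_equal(g[i], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})
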