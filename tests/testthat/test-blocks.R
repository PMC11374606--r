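# Backbone blocks: shapes, parameter conventions, ADown against an
# independent two-branch reference, OREPA squeeze equivalence.

test_that("CBS follows stride arithmetic and the kernel parameter count", {
  set.seed(1)
  x <- array(rnorm(32 * 32 * 3 * 1), c(32, 32, 3, 1))
  blk <- m_cbs(3, 16, 3, 2)
  y <- cbs_forward(x, blk)
  expect_equal(dim(y), c(16, 16, 16, 1))
  # Cin * K^2 * Cout kernel entries
  expect_equal(length(blk$params$W$value), 3 * 9 * 16)
  expect_error(cbs_forward(array(0, c(8, 8, 4, 1)), blk), "channels")
  # zero input: output is a per-channel constant over space
  blk2 <- m_cbs(3, 4, 3, 1)
  blk2$params$beta$value <- rnorm(4)
  y0 <- cbs_forward(array(0, c(8, 8, 3, 1)), blk2)
  for (c in 1:4) expect_equal(stats::sd(y0[, , c, 1]), 0)
})

test_that("ADown halves spatial extent and matches an independent reference", {
  set.seed(2)
  x <- array(rnorm(16 * 16 * 8 * 1), c(16, 16, 8, 1))
  blk <- m_adown(8, 12)
  y <- adown_forward(x, 12, block = blk)
  expect_equal(dim(y), c(8, 8, 12, 1))
  expect_error(m_adown(7, 12), "even")

  # constant input stays constant through the average pool
  xc <- array(1, c(16, 16, 8, 1))
  yc <- adown_forward(xc, 12, block = blk)
  for (c in seq_len(12)) {
    expect_equal(stats::sd(yc[2:7, 2:7, c, 1]), 0, tolerance = 1e-12)
  }

  # independent reference: plain-R average pool / chunk / conv / max pool
  ref_avgpool21 <- function(a) {
    H <- dim(a)[1]; W <- dim(a)[2]
    out <- array(0, c(H - 1, W - 1, dim(a)[3], 1))
    for (i in 1:(H - 1)) for (j in 1:(W - 1)) {
      out[i, j, , 1] <- (a[i, j, , 1] + a[i + 1, j, , 1] +
                           a[i, j + 1, , 1] + a[i + 1, j + 1, , 1]) / 4
    }
    out
  }
  ref_maxpool32 <- function(a) {
    H <- dim(a)[1]; W <- dim(a)[2]; C <- dim(a)[3]
    pad <- array(-Inf, c(H + 2, W + 2, C, 1))
    pad[2:(H + 1), 2:(W + 1), , 1] <- a
    Ho <- (H + 2 - 3) %/% 2 + 1
    out <- array(0, c(Ho, Ho, C, 1))
    for (i in seq_len(Ho)) for (j in seq_len(Ho)) for (c in seq_len(C)) {
      out[i, j, c, 1] <- max(pad[(2 * i - 1):(2 * i + 1),
                                 (2 * j - 1):(2 * j + 1), c, 1])
    }
    out
  }
  silu <- function(v) v * stats::plogis(v)
  bn_eval <- function(a, g, b, mu, va) {
    for (c in seq_len(dim(a)[3])) {
      a[, , c, 1] <- (a[, , c, 1] - mu[c]) / sqrt(va[c] + 1e-5) * g[c] + b[c]
    }
    a
  }
  pooled <- ref_avgpool21(x)
  x1 <- pooled[, , 1:4, , drop = FALSE]
  x2 <- pooled[, , 5:8, , drop = FALSE]
  y1 <- germdetr:::cpp_conv2d_forward(x1, blk$children$cv1$params$W$value,
                                      NULL, 2L, 1L)
  y1 <- silu(bn_eval(y1, blk$children$cv1$params$gamma$value,
                     blk$children$cv1$params$beta$value,
                     blk$children$cv1$state$running_mean,
                     blk$children$cv1$state$running_var))
  y2 <- germdetr:::cpp_conv2d_forward(ref_maxpool32(x2),
                                      blk$children$cv2$params$W$value,
                                      NULL, 1L, 0L)
  y2 <- silu(bn_eval(y2, blk$children$cv2$params$gamma$value,
                     blk$children$cv2$params$beta$value,
                     blk$children$cv2$state$running_mean,
                     blk$children$cv2$state$running_var))
  ref <- array(0, dim = dim(y))
  ref[, , 1:6, ] <- y1
  ref[, , 7:12, ] <- y2
  expect_lt(max(abs(y - ref)), 1e-6)
})

test_that("GELAN preserves spatial dims and is symmetric under branch swap", {
  set.seed(3)
  x <- array(rnorm(12 * 12 * 8), c(12, 12, 8, 1))
  blk <- m_gelan(8, 16, c3 = 8, c4 = 4)
  y <- gelan_forward(x, block = blk)
  expect_equal(dim(y), c(12, 12, 16, 1))

  # symmetric channel plan (c3/2 == c4): copying b1's weights into b2 and
  # swapping the two computation blocks leaves the output unchanged
  blk2 <- m_gelan(8, 16, c3 = 8, c4 = 4)
  p1 <- germdetr:::gdm_params(blk2$children$b1)
  p2 <- germdetr:::gdm_params(blk2$children$b2)
  for (nm in names(p1)) p2[[nm]]$value <- p1[[nm]]$value
  y1 <- gelan_forward(x, block = blk2)
  tmp <- blk2$children$b1
  blk2$children$b1 <- blk2$children$b2
  blk2$children$b2 <- tmp
  y2 <- gelan_forward(x, block = blk2)
  expect_lt(max(abs(y1 - y2)), 1e-9)
})

test_that("OREPA training form sums scaled branches; degenerate cases check out", {
  set.seed(4)
  x <- array(rnorm(10 * 10 * 4), c(10, 10, 4, 1))
  # all scaling vectors zero -> zero pre-normalization output: with
  # identity normalization the output is silu(0) = 0
  b <- m_orepa(4, 6)
  for (nm in grep("^s_", names(b$params), value = TRUE)) {
    b$params[[nm]]$value[] <- 0
  }
  y <- germdetr:::gd_value(orepa_forward_train(b, x))
  expect_equal(max(abs(y)), 0)
  # single origin branch with unit scaling equals the plain convolution
  b1 <- m_orepa(4, 6, branches = "origin")
  b1$params$s_origin$value[] <- 1
  y1 <- germdetr:::gd_value(orepa_forward_train(b1, x))
  conv <- germdetr:::cpp_conv2d_forward(x, b1$params$W_origin$value, NULL, 1L, 1L)
  silu <- function(v) v * stats::plogis(v)
  expect_lt(max(abs(y1 - silu(conv))), 1e-4)  # BN identity differs by its eps
})

test_that("parallel 3x3 + 1x1 squeeze to the center-padded kernel sum", {
  set.seed(5)
  b <- m_orepa(2, 3, branches = c("origin", "conv1"))
  b$params$s_origin$value[] <- 1
  b$params$s_1x1$value[] <- 1
  sq <- orepa_squeeze(b)
  w_expect <- b$params$W_origin$value
  w_expect[2, 2, , ] <- w_expect[2, 2, , ] + b$params$W_1x1$value[1, 1, , ]
  expect_equal(sq$params$W$value, w_expect, tolerance = 1e-5)  # BN eps folds in
  # verified on an input as well
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  y_tr <- germdetr:::gd_value(orepa_forward_train(b, x))
  y_sq <- germdetr:::gd_value(germdetr:::gdm_forward(sq, x))
  expect_lt(max(abs(y_tr - y_sq)), 1e-10)
})

test_that("squeeze preserves the function and strictly drops parameters", {
  set.seed(6)
  worst <- 0
  for (trial in 1:5) {
    cin <- sample(c(4, 6), 1); cout <- sample(c(4, 8), 1)
    b <- m_orepa(cin, cout, expand = runif(1, 0.5, 2))
    for (nm in names(b$params)) {
      b$params[[nm]]$value <- b$params[[nm]]$value * runif(1, 0.5, 1.5)
    }
    b$state$running_mean <- rnorm(cout, 0, 0.3)
    b$state$running_var <- runif(cout, 0.5, 2)
    sq <- orepa_squeeze(b)
    expect_lt(germdetr:::gdm_n_params(sq), germdetr:::gdm_n_params(b))
    x <- array(rnorm(9 * 9 * cin * 2), c(9, 9, cin, 2))
    y1 <- germdetr:::gd_value(orepa_forward_train(b, x))
    y2 <- germdetr:::gd_value(germdetr:::gdm_forward(sq, x))
    worst <- max(worst, max(abs(y1 - y2)))
  }
  expect_lt(worst, 1e-4)
  # squeezing twice warns and is a no-op; training form on a squeezed
  # block is a state error
  b2 <- m_orepa(4, 4)
  sq2 <- orepa_squeeze(b2)
  expect_warning(orepa_squeeze(sq2), "already")
  expect_error(orepa_forward_train(sq2, array(0, c(4, 4, 4, 1))), "squeezed")
})

test_that("OREPA-augmented GELAN supports both forms with fewer deploy parameters", {
  set.seed(7)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  blk <- m_gelan(8, 16, c3 = 8, c4 = 4, use_orepa = TRUE, orepa_expand = 2)
  y_tr <- orepancspelan4_forward(x, block = blk)
  expect_equal(dim(y_tr), c(8, 8, 16, 1))
  blk_sq <- germdetr:::gdm_squeeze_all(blk)
  y_sq <- orepancspelan4_forward(x, block = blk_sq)
  expect_lt(max(abs(y_tr - y_sq)), 1e-4)
  expect_lt(germdetr:::gdm_n_params(blk_sq), germdetr:::gdm_n_params(blk))
})
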