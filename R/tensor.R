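# Minimal define-by-run reverse-mode autodiff over plain R arrays.
# A gd_tensor is an environment holding a value, an accumulated gradient and
# the closure that maps the output gradient to parent gradients. Nodes are
# numbered at creation so backward() can process them in reverse topological
# order without an explicit graph sort.

.gd <- new.env(parent = emptyenv())
.gd$counter <- 0L
.gd$grad_enabled <- TRUE

gd_no_grad <- function(expr) {
  old <- .gd$grad_enabled
  .gd$grad_enabled <- FALSE
  on.exit(.gd$grad_enabled <- old)
  force(expr)
}

gd_tensor <- function(value, requires_grad = FALSE, parents = list(), backward = NULL) {
  if (is.null(dim(value))) value <- array(value, dim = length(value))
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  if (.gd$grad_enabled) {
    t$parents <- parents
    t$backward_fn <- backward
    t$requires_grad <- requires_grad || any(vapply(parents, function(p) p$requires_grad, logical(1)))
  } else {
    t$parents <- list()
    t$backward_fn <- NULL
    t$requires_grad <- FALSE
  }
  .gd$counter <- .gd$counter + 1L
  t$id <- .gd$counter
  class(t) <- "gd_tensor"
  t
}

gd_param <- function(value) gd_tensor(value, requires_grad = TRUE)

as_gd <- function(x) if (inherits(x, "gd_tensor")) x else gd_tensor(x)

gd_value <- function(x) if (inherits(x, "gd_tensor")) x$value else x

gd_detach <- function(x) gd_tensor(x$value)

#' @export
print.gd_tensor <- function(x, ...) {
  cat("<gd_tensor", paste(dim(x$value), collapse = "x"),
      if (x$requires_grad) "grad" else "", ">\n")
  invisible(x)
}

# Backpropagate from a scalar (or from `grad` matching root's shape).
gd_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    stopifnot(length(root$value) == 1L)
    grad <- array(1, dim = dim(root$value))
  }
  # collect reachable nodes that require grad
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]]) || !n$requires_grad) next
    nodes[[key]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  root$grad <- grad
  for (id in ids) {
    n <- nodes[[as.character(id)]]
    if (is.null(n$backward_fn) || is.null(n$grad)) next
    pg <- n$backward_fn(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!p$requires_grad || is.null(pg[[i]])) next
      if (is.null(p$grad)) p$grad <- pg[[i]] else p$grad <- p$grad + pg[[i]]
    }
    if (!identical(n, root)) n$grad <- NULL  # free intermediate gradients
  }
  invisible(root)
}

gd_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- elementwise ops (shapes must match exactly, or one side scalar) ----

bcast_back <- function(g, target_dim) {
  if (identical(dim(g), target_dim)) return(g)
  if (prod(target_dim) == 1L) return(array(sum(g), dim = target_dim))
  stop("internal: unexpected broadcast")
}

ew2 <- function(a, b, fwd, bwd_a, bwd_b) {
  a <- as_gd(a); b <- as_gd(b)
  va <- a$value; vb <- b$value
  out <- fwd(va, vb)
  gd_tensor(out, parents = list(a, b), backward = function(g) {
    list(bcast_back(bwd_a(g, va, vb, out), dim(va)),
         bcast_back(bwd_b(g, va, vb, out), dim(vb)))
  })
}

# elementwise ops accept same-shape arrays or a length-1 scalar on either side
gd_add <- function(a, b) ew2(a, b,
  function(x, y) if (length(y) == 1L) x + as.vector(y) else if (length(x) == 1L) as.vector(x) + y else x + y,
  function(g, x, y, o) g,
  function(g, x, y, o) g)

gd_sub <- function(a, b) ew2(a, b,
  function(x, y) if (length(y) == 1L) x - as.vector(y) else if (length(x) == 1L) as.vector(x) - y else x - y,
  function(g, x, y, o) g,
  function(g, x, y, o) -g)

gd_mul <- function(a, b) ew2(a, b,
  function(x, y) if (length(y) == 1L) x * as.vector(y) else if (length(x) == 1L) as.vector(x) * y else x * y,
  function(g, x, y, o) if (length(y) == 1L) g * as.vector(y) else g * y,
  function(g, x, y, o) if (length(x) == 1L) g * as.vector(x) else g * x)

gd_div <- function(a, b) ew2(a, b,
  function(x, y) if (length(y) == 1L) x / as.vector(y) else if (length(x) == 1L) as.vector(x) / y else x / y,
  function(g, x, y, o) if (length(y) == 1L) g / as.vector(y) else g / y,
  function(g, x, y, o) {
    xv <- if (length(x) == 1L) as.vector(x) else x
    yv <- if (length(y) == 1L) as.vector(y) else y
    -g * xv / (yv * yv)
  })

ew1 <- function(a, fwd, bwd) {
  a <- as_gd(a)
  va <- a$value
  out <- fwd(va)
  gd_tensor(out, parents = list(a), backward = function(g) list(bwd(g, va, out)))
}

gd_neg     <- function(a) ew1(a, function(x) -x, function(g, x, o) -g)
gd_exp     <- function(a) ew1(a, exp, function(g, x, o) g * o)
gd_log     <- function(a) ew1(a, log, function(g, x, o) g / x)
gd_sqrt    <- function(a) ew1(a, sqrt, function(g, x, o) g / (2 * o))
gd_square  <- function(a) ew1(a, function(x) x * x, function(g, x, o) 2 * g * x)
gd_abs     <- function(a) ew1(a, abs, function(g, x, o) g * sign(x))
gd_sigmoid <- function(a) ew1(a, stats::plogis, function(g, x, o) g * o * (1 - o))
gd_relu    <- function(a) ew1(a, function(x) pmax(x, 0), function(g, x, o) g * (x > 0))
gd_silu    <- function(a) ew1(a, function(x) x * stats::plogis(x),
                              function(g, x, o) {
                                s <- stats::plogis(x)
                                g * (s + x * s * (1 - s))
                              })

gd_pmax <- function(a, b) ew2(a, b,
  function(x, y) pmax(x, if (length(y) == 1L) as.vector(y) else y),
  function(g, x, y, o) g * (x >= if (length(y) == 1L) as.vector(y) else y),
  function(g, x, y, o) g * ((if (length(y) == 1L) as.vector(y) else y) > x))

gd_pmin <- function(a, b) ew2(a, b,
  function(x, y) pmin(x, if (length(y) == 1L) as.vector(y) else y),
  function(g, x, y, o) g * (x <= if (length(y) == 1L) as.vector(y) else y),
  function(g, x, y, o) g * ((if (length(y) == 1L) as.vector(y) else y) < x))

gd_clamp <- function(a, lo, hi) ew1(a, function(x) pmin(pmax(x, lo), hi),
                                    function(g, x, o) g * (x >= lo & x <= hi))

# ---- reductions ----

gd_sum <- function(a) {
  a <- as_gd(a)
  d <- dim(a$value)
  gd_tensor(array(sum(a$value), dim = 1L), parents = list(a),
            backward = function(g) list(array(as.vector(g), dim = d)))
}

gd_mean <- function(a) {
  a <- as_gd(a)
  d <- dim(a$value); n <- length(a$value)
  gd_tensor(array(mean(a$value), dim = 1L), parents = list(a),
            backward = function(g) list(array(as.vector(g) / n, dim = d)))
}

# ---- shape ops ----

gd_reshape <- function(a, new_dim) {
  a <- as_gd(a)
  old <- dim(a$value)
  v <- a$value; dim(v) <- new_dim
  gd_tensor(v, parents = list(a), backward = function(g) { dim(g) <- old; list(g) })
}

gd_concat <- function(tensors, axis) {
  tensors <- lapply(tensors, as_gd)
  vals <- lapply(tensors, function(t) t$value)
  d0 <- dim(vals[[1]])
  sizes <- vapply(vals, function(v) dim(v)[axis], integer(1))
  nd <- d0; nd[axis] <- sum(sizes)
  out <- array(0, dim = nd)
  idx_all <- lapply(nd, seq_len)
  off <- 0L
  for (i in seq_along(vals)) {
    idx <- idx_all; idx[[axis]] <- off + seq_len(sizes[i])
    out <- do.call(`[<-`, c(list(out), idx, list(vals[[i]])))
    off <- off + sizes[i]
  }
  gd_tensor(out, parents = tensors, backward = function(g) {
    res <- vector("list", length(sizes))
    off <- 0L
    for (i in seq_along(sizes)) {
      idx <- idx_all; idx[[axis]] <- off + seq_len(sizes[i])
      res[[i]] <- do.call(`[`, c(list(g), idx, list(drop = FALSE)))
      off <- off + sizes[i]
    }
    res
  })
}

gd_slice <- function(a, axis, idx) {
  a <- as_gd(a)
  d <- dim(a$value)
  sel <- lapply(d, seq_len); sel[[axis]] <- idx
  v <- do.call(`[`, c(list(a$value), sel, list(drop = FALSE)))
  gd_tensor(v, parents = list(a), backward = function(g) {
    dx <- array(0, dim = d)
    dx <- do.call(`[<-`, c(list(dx), sel, list(g)))
    list(dx)
  })
}

# rows of a matrix (duplicated indices accumulate in backward)
gd_take_rows <- function(a, idx) {
  a <- as_gd(a)
  d <- dim(a$value)
  v <- a$value[idx, , drop = FALSE]
  gd_tensor(v, parents = list(a), backward = function(g) {
    dx <- matrix(0, d[1], d[2])
    for (i in seq_along(idx)) dx[idx[i], ] <- dx[idx[i], ] + g[i, ]
    list(dx)
  })
}

# ---- linear algebra ----

gd_matmul <- function(a, b) {
  a <- as_gd(a); b <- as_gd(b)
  va <- a$value; vb <- b$value
  gd_tensor(va %*% vb, parents = list(a, b), backward = function(g) {
    list(g %*% t(vb), t(va) %*% g)
  })
}

# x: (n, din); W: (din, dout); b: length dout or NULL
gd_linear <- function(x, W, b = NULL) {
  x <- as_gd(x)
  out <- gd_matmul(x, W)
  if (!is.null(b)) {
    n <- nrow(out$value)
    vb <- b$value
    out <- gd_tensor(out$value + matrix(vb, n, length(vb), byrow = TRUE),
                     parents = list(out, b),
                     backward = function(g) list(g, colSums(g)))
  }
  out
}

gd_softmax_rows <- function(a) {
  a <- as_gd(a)
  v <- a$value
  m <- apply(v, 1, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  gd_tensor(s, parents = list(a), backward = function(g) {
    gs <- rowSums(g * s)
    list(s * (g - gs))
  })
}

# layer norm over rows of a matrix (tokens x dim)
gd_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_gd(x)
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  varr <- rowMeans(xc * xc)
  inv <- 1 / sqrt(varr + eps)
  xhat <- xc * inv
  gw <- gamma$value; bw <- beta$value
  out <- sweep(xhat, 2, gw, `*`)
  out <- sweep(out, 2, bw, `+`)
  D <- ncol(v)
  gd_tensor(out, parents = list(x, gamma, beta), backward = function(g) {
    gxhat <- sweep(g, 2, gw, `*`)
    t1 <- rowSums(gxhat)
    t2 <- rowSums(gxhat * xhat)
    dx <- inv * (gxhat - t1 / D - xhat * t2 / D)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# ---- conv / pool / norm on (H, W, C, N) arrays ----

gd_conv2d <- function(x, W, b = NULL, stride = 1L, pad = NULL) {
  x <- as_gd(x)
  K <- dim(W$value)[1]
  if (is.null(pad)) pad <- (K - 1L) %/% 2L
  vb <- if (is.null(b)) NULL else as.vector(b$value)
  out <- cpp_conv2d_forward(x$value, W$value, vb, as.integer(stride), as.integer(pad))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  vx <- x$value; vw <- W$value
  gd_tensor(out, parents = parents, backward = function(g) {
    bw <- cpp_conv2d_backward(vx, vw, g, as.integer(stride), as.integer(pad), !is.null(b))
    if (is.null(b)) list(bw$dx, bw$dw) else list(bw$dx, bw$dw, bw$db)
  })
}

gd_maxpool <- function(x, K, stride, pad = 0L) {
  x <- as_gd(x)
  r <- cpp_maxpool_forward(x$value, as.integer(K), as.integer(stride), as.integer(pad))
  in_dim <- dim(x$value)
  gd_tensor(r$out, parents = list(x), backward = function(g) {
    list(cpp_maxpool_backward(r$argmax, g, as.integer(in_dim)))
  })
}

gd_avgpool <- function(x, K, stride, pad = 0L) {
  x <- as_gd(x)
  in_dim <- dim(x$value)
  out <- cpp_avgpool_forward(x$value, as.integer(K), as.integer(stride), as.integer(pad))
  gd_tensor(out, parents = list(x), backward = function(g) {
    list(cpp_avgpool_backward(g, as.integer(in_dim), as.integer(K), as.integer(stride), as.integer(pad)))
  })
}

# nearest-neighbour 2x upsampling
gd_upsample2x <- function(x) {
  x <- as_gd(x)
  v <- x$value
  d <- dim(v)
  idx_h <- rep(seq_len(d[1]), each = 2)
  idx_w <- rep(seq_len(d[2]), each = 2)
  out <- v[idx_h, idx_w, , , drop = FALSE]
  gd_tensor(out, parents = list(x), backward = function(g) {
    dh <- dim(g)[1] / 2; dw <- dim(g)[2] / 2
    gi <- g
    dim(gi) <- c(2, dh, 2, dw, d[3], d[4])
    list(array(colSums(aperm(gi, c(1, 3, 2, 4, 5, 6)), dims = 2), dim = d))
  })
}

# batch normalization over (H, W, C, N): statistics per channel
gd_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  x <- as_gd(x)
  v <- x$value
  d <- dim(v)
  C <- d[3]
  m <- prod(d[c(1, 2, 4)])
  xm <- aperm(v, c(1, 2, 4, 3))
  dim(xm) <- c(m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    varr <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var  <- (1 - momentum) * state$running_var  + momentum * varr * m / max(1, m - 1)
  } else {
    mu <- state$running_mean
    varr <- state$running_var
    xc <- sweep(xm, 2, mu)
  }
  inv <- 1 / sqrt(varr + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  dim(out) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(out, c(1, 2, 4, 3))
  gd_tensor(out, parents = list(x, gamma, beta), backward = function(g) {
    gm <- aperm(g, c(1, 2, 4, 3))
    dim(gm) <- c(m, C)
    gxhat <- sweep(gm, 2, gamma$value, `*`)
    if (training) {
      t1 <- colMeans(gxhat)
      t2 <- colMeans(gxhat * xhat)
      dxm <- sweep(gxhat - matrix(t1, m, C, byrow = TRUE) -
                     sweep(xhat, 2, t2, `*`), 2, inv, `*`)
    } else {
      dxm <- sweep(gxhat, 2, inv, `*`)
    }
    dim(dxm) <- c(d[1], d[2], d[4], d[3])
    list(aperm(dxm, c(1, 2, 4, 3)), colSums(gm * xhat), colSums(gm))
  })
}
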