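# Backbone building blocks. Modules are nested lists (class "gdm") holding
# gd_tensor parameters; gdm_forward() runs them on (H, W, C, N) feature
# arrays, gdm_acct() produces the per-layer accounting rows used for the
# params/FLOPs ladder (conv FLOPs = 2*H*W*(Cin*K^2+1)*Cout at the output
# resolution; linear/attention elsewhere as 2 x multiply-accumulates).

new_gdm <- function(kind, params = list(), children = list(), cfg = list()) {
  structure(list(kind = kind, params = params, children = children, cfg = cfg),
            class = "gdm")
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Conv + batch-norm + SiLU block
#'
#' The elementary "CBS" unit; `act`/`bn` can be disabled for plain convs.
#'
#' @param cin,cout Channel counts.
#' @param k Kernel size.
#' @param stride Stride.
#' @param pad Padding (defaults to same-padding).
#' @param act,bn,bias Toggles for activation, batch norm, bias.
#' @return A module of kind `"cbs"`.
#' @export
m_cbs <- function(cin, cout, k = 1, stride = 1, pad = NULL, act = TRUE,
                  bn = TRUE, bias = FALSE) {
  params <- list(W = gd_param(he_init(k, cin, cout)))
  if (bias) params$b <- gd_param(numeric(cout))
  if (bn) {
    params$gamma <- gd_param(rep(1, cout))
    params$beta <- gd_param(numeric(cout))
  }
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(cout)
  state$running_var <- rep(1, cout)
  m <- new_gdm("cbs", params,
               cfg = list(cin = cin, cout = cout, k = k, stride = stride,
                          pad = if (is.null(pad)) (k - 1) %/% 2 else pad,
                          act = act, bn = bn, bias = bias))
  m$state <- state
  m
}

fwd_cbs <- function(m, x, ctx) {
  out <- gd_conv2d(x, m$params$W, m$params$b, stride = m$cfg$stride,
                   pad = m$cfg$pad)
  if (m$cfg$bn) {
    out <- gd_batchnorm(out, m$params$gamma, m$params$beta, m$state,
                        training = isTRUE(ctx$training))
  }
  if (m$cfg$act) out <- gd_silu(out)
  out
}

m_sequential <- function(...) {
  ch <- list(...)
  if (length(ch) == 1 && is.list(ch[[1]]) && !inherits(ch[[1]], "gdm")) ch <- ch[[1]]
  names(ch) <- paste0("l", seq_along(ch))
  new_gdm("seq", children = ch)
}

# residual basic block (two 3x3 convs); optional strided entry with a
# pool-then-project shortcut
m_basic_block <- function(cin, cout, stride = 1) {
  children <- list(
    conv1 = m_cbs(cin, cout, 3, stride),
    conv2 = m_cbs(cout, cout, 3, 1, act = FALSE)
  )
  if (stride != 1 || cin != cout) {
    children$shortcut <- m_cbs(cin, cout, 1, 1, act = FALSE)
  }
  new_gdm("basic", children = children,
          cfg = list(stride = stride, cin = cin, cout = cout))
}

fwd_basic <- function(m, x, ctx) {
  y <- gdm_forward(m$children$conv2, gdm_forward(m$children$conv1, x, ctx), ctx)
  if (!is.null(m$children$shortcut)) {
    s <- x
    if (m$cfg$stride != 1) s <- gd_avgpool(as_gd(s), 2, m$cfg$stride)
    s <- gdm_forward(m$children$shortcut, s, ctx)
  } else {
    s <- x
  }
  gd_silu(gd_add(y, s))
}

#' ADown downsampling block
#'
#' Average pool (2x2, stride 1), channel chunk into two halves, then a
#' 3x3 stride-2 CBS branch and a max-pool (3x3, stride 2) + 1x1 CBS branch,
#' concatenated.
#'
#' @param cin Input channels (even).
#' @param cout Output channels.
#' @return A module of kind `"adown"`.
#' @export
m_adown <- function(cin, cout) {
  if (cin %% 2 != 0) stop("ADown requires an even input channel count")
  half_in <- cin %/% 2
  half_out <- cout %/% 2
  new_gdm("adown",
          children = list(cv1 = m_cbs(half_in, half_out, 3, 2),
                          cv2 = m_cbs(half_in, cout - half_out, 1, 1)),
          cfg = list(cin = cin, cout = cout))
}

fwd_adown <- function(m, x, ctx) {
  x <- as_gd(x)
  x <- gd_avgpool(x, 2, 1, pad = 0)
  c <- dim(x$value)[3]
  x1 <- gd_slice(x, 3, seq_len(c %/% 2))
  x2 <- gd_slice(x, 3, (c %/% 2 + 1):c)
  y1 <- gdm_forward(m$children$cv1, x1, ctx)
  y2 <- gdm_forward(m$children$cv2, gd_maxpool(x2, 3, 2, pad = 1), ctx)
  gd_concat(list(y1, y2), 3)
}

# CSP block: split 1x1 projections, n bottlenecks (1x1 then 3x3, residual),
# merge 1x1
m_ncsp <- function(cin, cout, n = 1, hidden = NULL) {
  h <- if (is.null(hidden)) cout %/% 2 else hidden
  bots <- lapply(seq_len(n), function(i) {
    m_sequential(m_cbs(h, h, 1), m_cbs(h, h, 3))
  })
  new_gdm("ncsp",
          children = list(cv1 = m_cbs(cin, h, 1), cv2 = m_cbs(cin, h, 1),
                          m = m_sequential(bots), cv3 = m_cbs(2 * h, cout, 1)),
          cfg = list(cin = cin, cout = cout, n = n, h = h))
}

fwd_ncsp <- function(m, x, ctx) {
  a <- gdm_forward(m$children$cv1, x, ctx)
  for (bot in m$children$m$children) {
    a <- gd_add(a, gdm_forward(bot, a, ctx))
  }
  b <- gdm_forward(m$children$cv2, x, ctx)
  gdm_forward(m$children$cv3, gd_concat(list(a, b), 3), ctx)
}

#' GELAN module (RepNCSPELAN4 layout)
#'
#' 1x1 transition, channel split, two stacked computation blocks (CSP blocks
#' followed by a 3x3 conv) whose outputs concatenate forward, and a 1x1
#' merge. With `use_orepa` the 3x3 conv after each CSP block is an OREPA
#' block.
#'
#' @param cin,cout Channel counts.
#' @param c3 Transition width (split into two halves).
#' @param c4 Computation-block width.
#' @param n CSP bottleneck count.
#' @param use_orepa Replace the two 3x3 convs with [m_orepa()] blocks.
#' @param orepa_expand Expansion of the OREPA sequential branch.
#' @return A module of kind `"gelan"`.
#' @export
m_gelan <- function(cin, cout, c3, c4, n = 1, use_orepa = FALSE,
                    orepa_expand = 1) {
  conv_after <- function() {
    if (use_orepa) m_orepa(c4, c4, 3, expand = orepa_expand) else m_cbs(c4, c4, 3)
  }
  new_gdm("gelan",
          children = list(
            cv1 = m_cbs(cin, c3, 1),
            b1 = m_sequential(m_ncsp(c3 %/% 2, c4, n), conv_after()),
            b2 = m_sequential(m_ncsp(c4, c4, n), conv_after()),
            cv4 = m_cbs(c3 + 2 * c4, cout, 1)
          ),
          cfg = list(cin = cin, cout = cout, c3 = c3, c4 = c4, n = n,
                     use_orepa = use_orepa))
}

fwd_gelan <- function(m, x, ctx) {
  y <- gdm_forward(m$children$cv1, x, ctx)
  c3 <- m$cfg$c3
  y1 <- gd_slice(y, 3, seq_len(c3 %/% 2))
  y2 <- gd_slice(y, 3, (c3 %/% 2 + 1):c3)
  y3 <- gdm_forward(m$children$b1, y2, ctx)
  y4 <- gdm_forward(m$children$b2, y3, ctx)
  gdm_forward(m$children$cv4, gd_concat(list(y1, y2, y3, y4), 3), ctx)
}

# RepConv: parallel 3x3 + 1x1 convolutions (each with BN), summed; fusable
# into a single 3x3 conv at deployment
m_repconv <- function(cin, cout) {
  new_gdm("repconv",
          children = list(dense = m_cbs(cin, cout, 3, act = FALSE),
                          pw = m_cbs(cin, cout, 1, act = FALSE)),
          cfg = list(cin = cin, cout = cout))
}

fwd_repconv <- function(m, x, ctx) {
  x <- as_gd(x)
  gd_silu(gd_add(gdm_forward(m$children$dense, x, ctx),
                 gdm_forward(m$children$pw, x, ctx)))
}

# RepC3: the CSP fusion block of the baseline neck
m_repc3 <- function(cin, cout, n = 3, hidden = NULL) {
  h <- if (is.null(hidden)) cout else hidden
  blocks <- lapply(seq_len(n), function(i) m_repconv(h, h))
  children <- list(cv1 = m_cbs(cin, h, 1), cv2 = m_cbs(cin, h, 1),
                   m = m_sequential(blocks))
  if (h != cout) children$cv3 <- m_cbs(h, cout, 1, act = FALSE)
  new_gdm("repc3", children = children,
          cfg = list(cin = cin, cout = cout, n = n, h = h))
}

fwd_repc3 <- function(m, x, ctx) {
  a <- gdm_forward(m$children$cv1, x, ctx)
  for (blk in m$children$m$children) a <- gdm_forward(blk, a, ctx)
  out <- gd_add(a, gdm_forward(m$children$cv2, x, ctx))
  if (!is.null(m$children$cv3)) out <- gdm_forward(m$children$cv3, out, ctx)
  out
}

# ---- OREPA ----

#' Online re-parameterizable convolution block
#'
#' Training form: four parallel linear branches -- the origin k x k conv, a
#' 1 x 1 conv, a sequential 1 x 1 -> k x k expansion (internal width
#' `expand * cin`), and a 1 x 1 conv followed by k x k average pooling --
#' each scaled by a per-output-channel vector, summed, then batch-normalized
#' and activated. Deployment form ([orepa_squeeze()]): the branches fold into
#' a single conv by linear composition.
#'
#' @param cin,cout Channel counts.
#' @param k Kernel size (odd).
#' @param expand Internal width multiplier of the sequential branch.
#' @param branches Character subset of
#'   `c("origin", "conv1", "seq", "avg")` to include.
#' @return A module of kind `"orepa"`.
#' @export
m_orepa <- function(cin, cout, k = 3, expand = 1,
                    branches = c("origin", "conv1", "seq", "avg")) {
  branches <- match.arg(branches, several.ok = TRUE)
  ce <- max(1L, as.integer(round(expand * cin)))
  params <- list()
  if ("origin" %in% branches) {
    params$W_origin <- gd_param(he_init(k, cin, cout))
    params$s_origin <- gd_param(rep(1, cout))
  }
  if ("conv1" %in% branches) {
    params$W_1x1 <- gd_param(he_init(1, cin, cout))
    params$s_1x1 <- gd_param(rep(0.5, cout))
  }
  if ("seq" %in% branches) {
    params$W_seq_a <- gd_param(he_init(1, cin, ce))
    params$W_seq_b <- gd_param(he_init(k, ce, cout))
    params$s_seq <- gd_param(rep(0.5, cout))
  }
  if ("avg" %in% branches) {
    params$W_avg <- gd_param(he_init(1, cin, cout))
    params$s_avg <- gd_param(rep(0.5, cout))
  }
  params$gamma <- gd_param(rep(1, cout))
  params$beta <- gd_param(numeric(cout))
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(cout)
  state$running_var <- rep(1, cout)
  m <- new_gdm("orepa", params,
               cfg = list(cin = cin, cout = cout, k = k, ce = ce,
                          branches = branches, squeezed = FALSE))
  m$state <- state
  m
}

# per-channel scaling with correct gradients for both operands
gd_scale_channels <- function(y, s) {
  d <- dim(y$value)
  sv <- array(rep(rep(s$value, each = d[1] * d[2]), d[4]), dim = d)
  yv <- y$value
  gd_tensor(yv * sv, parents = list(y, s), backward = function(g) {
    gm <- g * yv
    gm <- aperm(gm, c(1, 2, 4, 3))
    dim(gm) <- c(d[1] * d[2] * d[4], d[3])
    list(g * sv, colSums(gm))
  })
}

#' Forward pass of an OREPA block in training form
#'
#' Output is the scaled sum of all branch outputs, batch-normalized and
#' activated. Fails if the block has been squeezed.
#'
#' @param m An [m_orepa()] block.
#' @param x Feature array (H, W, C, N) or gd_tensor.
#' @param ctx List; `ctx$training` toggles batch-statistics mode.
#' @return gd_tensor feature map with `cout` channels.
#' @export
orepa_forward_train <- function(m, x, ctx = list(training = FALSE)) {
  if (isTRUE(m$cfg$squeezed)) stop("OREPA block is already squeezed")
  x <- as_gd(x)
  k <- m$cfg$k
  pad <- (k - 1) %/% 2
  parts <- list()
  p <- m$params
  if (!is.null(p$W_origin)) {
    parts$origin <- gd_scale_channels(gd_conv2d(x, p$W_origin, stride = 1, pad = pad),
                                      p$s_origin)
  }
  if (!is.null(p$W_1x1)) {
    parts$conv1 <- gd_scale_channels(gd_conv2d(x, p$W_1x1, stride = 1, pad = 0),
                                     p$s_1x1)
  }
  if (!is.null(p$W_seq_a)) {
    h <- gd_conv2d(x, p$W_seq_a, stride = 1, pad = 0)
    parts$seq <- gd_scale_channels(gd_conv2d(h, p$W_seq_b, stride = 1, pad = pad),
                                   p$s_seq)
  }
  if (!is.null(p$W_avg)) {
    h <- gd_conv2d(x, p$W_avg, stride = 1, pad = 0)
    parts$avg <- gd_scale_channels(gd_avgpool(h, k, 1, pad = pad), p$s_avg)
  }
  out <- parts[[1]]
  if (length(parts) > 1) for (i in 2:length(parts)) out <- gd_add(out, parts[[i]])
  out <- gd_batchnorm(out, p$gamma, p$beta, m$state,
                      training = isTRUE(ctx$training))
  gd_silu(out)
}

# center-pad a 1x1 kernel array (1,1,cin,cout) to (k,k,cin,cout)
pad_kernel_center <- function(w1, k) {
  d <- dim(w1)
  out <- array(0, dim = c(k, k, d[3], d[4]))
  c0 <- (k + 1) %/% 2
  out[c0, c0, , ] <- w1[1, 1, , ]
  out
}

# compose 1x1 (cin->ce) followed by k x k (ce->cout) into one k x k kernel
compose_seq_kernel <- function(wa, wb) {
  k <- dim(wb)[1]; cin <- dim(wa)[3]; ce <- dim(wa)[4]; cout <- dim(wb)[4]
  a <- matrix(wa, cin, ce)           # wa[1,1,i,e]
  out <- array(0, dim = c(k, k, cin, cout))
  for (kh in seq_len(k)) {
    for (kw in seq_len(k)) {
      out[kh, kw, , ] <- a %*% matrix(wb[kh, kw, , ], ce, cout)
    }
  }
  out
}

scale_kernel <- function(w, s) {
  # multiply output channel o of (k,k,cin,cout) by s[o]
  sweep(w, 4, s, `*`)
}

#' Squeeze an OREPA block into a single convolution
#'
#' Folds all branches into one k x k kernel: sequential 1x1 -> kxk branches
#' compose by channel contraction, parallel 1x1 branches pad to the common
#' kernel size, the averaging branch becomes its equivalent uniform kernel,
#' per-branch scaling vectors fold multiplicatively, and the batch-norm
#' statistics fold into the final weight and bias. The squeezed block's
#' forward matches the training form within 1e-4 on any input, with strictly
#' fewer parameters.
#'
#' @param m An [m_orepa()] block (training form).
#' @return The squeezed block (kind `"orepa"`, `cfg$squeezed = TRUE`).
#' @export
orepa_squeeze <- function(m) {
  if (isTRUE(m$cfg$squeezed)) {
    warning("OREPA block already squeezed; returning unchanged")
    return(m)
  }
  k <- m$cfg$k; cin <- m$cfg$cin; cout <- m$cfg$cout
  p <- m$params
  W <- array(0, dim = c(k, k, cin, cout))
  if (!is.null(p$W_origin)) {
    W <- W + scale_kernel(p$W_origin$value, p$s_origin$value)
  }
  if (!is.null(p$W_1x1)) {
    W <- W + scale_kernel(pad_kernel_center(p$W_1x1$value, k), p$s_1x1$value)
  }
  if (!is.null(p$W_seq_a)) {
    W <- W + scale_kernel(compose_seq_kernel(p$W_seq_a$value, p$W_seq_b$value),
                          p$s_seq$value)
  }
  if (!is.null(p$W_avg)) {
    # 1x1 conv then kxk mean pool == kxk conv with the 1x1 weight / k^2
    wavg <- p$W_avg$value[1, 1, , ] / (k * k)
    Wk <- array(0, dim = c(k, k, cin, cout))
    for (kh in seq_len(k)) for (kw in seq_len(k)) Wk[kh, kw, , ] <- wavg
    W <- W + scale_kernel(Wk, p$s_avg$value)
  }
  # fold batch norm (running statistics)
  sd <- sqrt(m$state$running_var + 1e-5)
  gam <- p$gamma$value
  W <- scale_kernel(W, gam / sd)
  b <- p$beta$value - gam * m$state$running_mean / sd
  out <- new_gdm("orepa",
                 params = list(W = gd_param(W), b = gd_param(b)),
                 cfg = utils::modifyList(m$cfg, list(squeezed = TRUE)))
  out
}

fwd_orepa <- function(m, x, ctx) {
  if (isTRUE(m$cfg$squeezed)) {
    pad <- (m$cfg$k - 1) %/% 2
    gd_silu(gd_conv2d(as_gd(x), m$params$W, m$params$b, stride = 1, pad = pad))
  } else {
    orepa_forward_train(m, x, ctx)
  }
}

# ---- generic forward dispatch (registry so other files can add kinds) ----

.gdm_registry <- new.env(parent = emptyenv())

gdm_register <- function(kind, fn) assign(kind, fn, envir = .gdm_registry)

gdm_forward <- function(m, x, ctx = list(training = FALSE)) {
  fn <- get0(m$kind, envir = .gdm_registry)
  if (is.null(fn)) stop("unknown module kind: ", m$kind)
  fn(m, x, ctx)
}

gdm_register("cbs", function(m, x, ctx) fwd_cbs(m, as_gd(x), ctx))
gdm_register("seq", function(m, x, ctx) {
  out <- x
  for (ch in m$children) out <- gdm_forward(ch, out, ctx)
  out
})
gdm_register("basic", function(m, x, ctx) fwd_basic(m, as_gd(x), ctx))
gdm_register("adown", fwd_adown)
gdm_register("ncsp", function(m, x, ctx) fwd_ncsp(m, as_gd(x), ctx))
gdm_register("gelan", function(m, x, ctx) fwd_gelan(m, as_gd(x), ctx))
gdm_register("repconv", fwd_repconv)
gdm_register("repc3", function(m, x, ctx) fwd_repc3(m, as_gd(x), ctx))
gdm_register("orepa", fwd_orepa)

# collect all gd parameters of a module tree (named); children of
# sequential containers are named l1, l2, ... at construction
gdm_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  ch_names <- names(m$children)
  stopifnot(length(ch_names) == length(m$children))
  for (nm in ch_names) {
    out <- c(out, gdm_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

gdm_n_params <- function(m) {
  sum(vapply(gdm_params(m), function(p) length(p$value), numeric(1)))
}

# ---- spec-facing wrappers ----

#' Forward pass of a conv + batch-norm + SiLU block
#'
#' @param x Feature array (H, W, C, N).
#' @param block An [m_cbs()]-style module (or one is created from
#'   `cin`/`cout`/`k`/`stride`).
#' @param cin,cout,k,stride Used when `block` is missing.
#' @return Feature array of the output.
#' @export
cbs_forward <- function(x, block = NULL, cin = dim(x)[3], cout = cin, k = 3,
                        stride = 1) {
  if (is.null(block)) block <- m_cbs(cin, cout, k, stride)
  if (dim(x)[3] != block$cfg$cin) {
    stop("input has ", dim(x)[3], " channels, block expects ", block$cfg$cin)
  }
  gd_value(gdm_forward(block, x, list(training = FALSE)))
}

#' Forward pass of an ADown downsampling block
#'
#' Average pool (2x2, stride 1), split channels in half, then a 3x3 stride-2
#' conv branch and a max-pool + 1x1 conv branch, concatenated. Spatial size
#' halves exactly for even inputs.
#'
#' @param x Feature array (H, W, C, N); C must be even.
#' @param cout Output channels.
#' @param block Optionally a prebuilt [m_adown()] module.
#' @return Feature array (H/2, W/2, cout, N).
#' @export
adown_forward <- function(x, cout, block = NULL) {
  if (is.null(block)) block <- m_adown(dim(x)[3], cout)
  gd_value(gdm_forward(block, x, list(training = FALSE)))
}

#' Forward pass of a GELAN (RepNCSPELAN4) module
#'
#' @param x Feature array (H, W, C, N).
#' @param spec List with `cout`, `c3`, `c4`, optional `n`; or a prebuilt
#'   [m_gelan()] module via `block`.
#' @param block Optional prebuilt module.
#' @return Feature array with `cout` channels, same spatial size.
#' @export
gelan_forward <- function(x, spec = list(cout = dim(x)[3],
                                         c3 = dim(x)[3], c4 = dim(x)[3] %/% 2),
                          block = NULL) {
  if (is.null(block)) {
    block <- m_gelan(dim(x)[3], spec$cout, spec$c3, spec$c4,
                     n = if (is.null(spec$n)) 1 else spec$n)
  }
  gd_value(gdm_forward(block, x, list(training = FALSE)))
}

#' Forward pass of the OREPA-augmented GELAN module
#'
#' Same topology as [gelan_forward()] with the two internal 3x3 convolutions
#' replaced by OREPA blocks; supports both training form and squeezed form.
#'
#' @inheritParams gelan_forward
#' @param orepa_expand Internal expansion of the OREPA sequential branch.
#' @return Feature array with `cout` channels, same spatial size.
#' @export
orepancspelan4_forward <- function(x, spec = list(cout = dim(x)[3],
                                                  c3 = dim(x)[3],
                                                  c4 = dim(x)[3] %/% 2),
                                   orepa_expand = 1, block = NULL) {
  if (is.null(block)) {
    block <- m_gelan(dim(x)[3], spec$cout, spec$c3, spec$c4,
                     n = if (is.null(spec$n)) 1 else spec$n,
                     use_orepa = TRUE, orepa_expand = orepa_expand)
  }
  gd_value(gdm_forward(block, x, list(training = FALSE)))
}

# squeeze every OREPA block (and fuse conv+BN pairs is handled at the
# orepa level; CBS blocks keep BN, which is exact in eval mode)
gdm_squeeze_all <- function(m) {
  if (m$kind == "orepa" && !isTRUE(m$cfg$squeezed)) return(orepa_squeeze(m))
  if (length(m$children)) {
    for (nm in names(m$children)) m$children[[nm]] <- gdm_squeeze_all(m$children[[nm]])
  }
  m
}
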