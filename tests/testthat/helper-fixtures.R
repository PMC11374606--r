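# Shared fixtures and independent oracles.

det_tbl <- function(image_id, class_id, cx, cy, w, h, conf = NULL) {
  out <- tibble::tibble(image_id = as.character(image_id),
                        class_id = as.integer(class_id),
                        cx = cx, cy = cy, w = w, h = h)
  if (!is.null(conf)) out$conf <- conf
  out
}

# random ground truths + detections: perturbed copies of GTs plus clutter
random_eval_case <- function(n_gt = 5, n_extra = 3, n_images = 2, seed = 1) {
  set.seed(seed)
  gts <- det_tbl(
    image_id = sample(seq_len(n_images), n_gt, replace = TRUE),
    class_id = sample(0:1, n_gt, replace = TRUE),
    cx = runif(n_gt, 0.2, 0.8), cy = runif(n_gt, 0.2, 0.8),
    w = runif(n_gt, 0.05, 0.2), h = runif(n_gt, 0.05, 0.2)
  )
  keep <- runif(n_gt) < 0.8
  dets <- gts[keep, ]
  if (nrow(dets) > 0) {
    jitter <- function(x, s) x + rnorm(length(x), 0, s)
    dets$cx <- jitter(dets$cx, 0.01); dets$cy <- jitter(dets$cy, 0.01)
    dets$w <- pmax(0.01, jitter(dets$w, 0.01))
    dets$h <- pmax(0.01, jitter(dets$h, 0.01))
    # some detections carry the wrong class
    flip <- runif(nrow(dets)) < 0.15
    dets$class_id[flip] <- 1L - dets$class_id[flip]
  }
  extra <- det_tbl(
    image_id = sample(seq_len(n_images), n_extra, replace = TRUE),
    class_id = sample(0:1, n_extra, replace = TRUE),
    cx = runif(n_extra, 0.1, 0.9), cy = runif(n_extra, 0.1, 0.9),
    w = runif(n_extra, 0.03, 0.15), h = runif(n_extra, 0.03, 0.15)
  )
  dets <- dplyr::bind_rows(dets, extra)
  dets$conf <- runif(nrow(dets), 0.1, 1)
  list(dets = dets, gts = gts)
}

# ---- independent average-precision oracle ----
# Re-derives everything with plain loops: greedy confidence-ordered matching,
# the exhaustive precision envelope, and the 101-point mean. Shares no code
# with the package implementation.
oracle_iou <- function(a, b) {
  ax1 <- a[1] - a[3] / 2; ax2 <- a[1] + a[3] / 2
  ay1 <- a[2] - a[4] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; bx2 <- b[1] + b[3] / 2
  by1 <- b[2] - b[4] / 2; by2 <- b[2] + b[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

oracle_ap <- function(dets, gts, thr) {
  if (nrow(gts) == 0) return(NA_real_)
  ord <- order(-dets$conf)
  tp <- logical(length(ord))
  taken <- list()
  for (k in seq_along(ord)) {
    i <- ord[k]
    img <- dets$image_id[i]
    if (is.null(taken[[img]])) taken[[img]] <- integer(0)
    cand <- which(gts$image_id == img & gts$class_id == dets$class_id[i])
    best <- 0; bj <- 0
    for (j in cand) {
      v <- oracle_iou(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
                      as.numeric(gts[j, c("cx", "cy", "w", "h")]))
      if (v >= thr && v > best && !(j %in% taken[[img]])) { best <- v; bj <- j }
    }
    if (bj > 0) { tp[k] <- TRUE; taken[[img]] <- c(taken[[img]], bj) }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(gts)
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    pmax_r <- 0
    for (k in seq_along(rec)) {
      if (rec[k] >= r && prec[k] > pmax_r) pmax_r <- prec[k]
    }
    ap <- ap + pmax_r
  }
  ap / 101
}

tiny_model <- function(variant = "soilcuc", rng_seed = 1, n_queries = 12,
                       dec_layers = 1) {
  build_model(model_spec(variant = variant, image_size = 64,
                         n_queries = n_queries, dec_layers = dec_layers,
                         scale = 0.125, rng_seed = rng_seed))
}
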