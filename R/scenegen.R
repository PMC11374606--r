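# Synthetic soil seed-dish scenes with exact ground truth.
#
# A scene emulates the acquisition setting this model family targets: a dark
# substrate-soil background with band-limited texture, a rows x cols grid of
# elliptical seeds (jittered off their cell centers), thin curved radicles
# for germinated seeds that may dive under the soil and re-emerge, and
# distractors -- stones colored like seeds and wood-like fibers colored like
# radicles. Images are 8-bit RGB arrays (H, W, 3).

#' Parameters of the synthetic scene generator
#'
#' Defaults reflect the acquisition conditions the detector is built for:
#' 640 x 640 training resolution, a 7 x 7 dish of 49 seeds, and radicles that
#' are sometimes partially buried in the substrate.
#'
#' @param image_size `c(height, width)` in pixels (scalar recycled).
#' @param grid `c(rows, cols)` of seed positions.
#' @param germination_fraction Probability a seed has germinated.
#' @param root_length_ratio_range Range of radicle length as a multiple of
#'   seed length; values below 1 yield SROOT, above 1 LROOT.
#' @param n_stones,n_fibers Distractor counts.
#' @param burial_probability Probability that a germinated seed's radicle is
#'   partially hidden by soil.
#' @param jitter Maximum offset (px) of a seed from its grid-cell center.
#' @param seed_length_range Seed major-axis length range in px; the default
#'   scales with the cell size so any image size stays drawable.
#' @param box_extent `"seed_plus_root"` (annotation box covers seed body plus
#'   visible radicle; default) or `"root_only"`.
#' @param rng_seed Integer seed; the same seed gives a bit-identical scene.
#' @return List of class `scene_params`.
#' @export
scene_params <- function(image_size = c(640, 640), grid = c(7, 7),
                         germination_fraction = 0.5,
                         root_length_ratio_range = c(0.25, 2.5),
                         n_stones = 6, n_fibers = 4,
                         burial_probability = 0.3, jitter = 6,
                         seed_length_range = NULL,
                         box_extent = c("seed_plus_root", "root_only"),
                         rng_seed = 0L) {
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  if (length(grid) == 1) grid <- rep(grid, 2)
  probs <- c(germination_fraction, burial_probability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(root_length_ratio_range <= 0)) stop("root length ratios must be positive")
  cell <- min(image_size[1] / grid[1], image_size[2] / grid[2])
  if (is.null(seed_length_range)) {
    seed_length_range <- c(0.28, 0.36) * cell
  }
  if (max(seed_length_range) + 2 * jitter > 0.95 * cell) {
    stop("grid too dense: ", grid[1], "x", grid[2], " seeds of up to ",
         round(max(seed_length_range)), " px (+jitter) do not fit ",
         image_size[1], "x", image_size[2], " with margin")
  }
  structure(list(image_size = as.integer(image_size), grid = as.integer(grid),
                 germination_fraction = germination_fraction,
                 root_length_ratio_range = root_length_ratio_range,
                 n_stones = n_stones, n_fibers = n_fibers,
                 burial_probability = burial_probability, jitter = jitter,
                 seed_length_range = seed_length_range,
                 box_extent = match.arg(box_extent),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_params")
}

#' Classify a radicle as SROOT or LROOT
#'
#' A root shorter than the seed body is SROOT (class 0), longer is LROOT
#' (class 1). Equal lengths break toward SROOT.
#'
#' @param root_length,seed_length Positive lengths (same unit); vectorized.
#' @return Integer class ids (0 = SROOT, 1 = LROOT).
#' @examples
#' label_root_class(10, 40) # SROOT
#' label_root_class(80, 40) # LROOT
#' @export
label_root_class <- function(root_length, seed_length) {
  if (any(root_length <= 0) || any(seed_length <= 0)) {
    stop("root and seed lengths must be positive")
  }
  ifelse(root_length > seed_length, LROOT, SROOT)
}

# ---- drawing helpers on a (H, W, 3) double array in [0, 1] ----

upsample_bilinear <- function(m, H, W) {
  ri <- seq(1, nrow(m), length.out = H)
  ci <- seq(1, ncol(m), length.out = W)
  r0 <- pmin(floor(ri), nrow(m) - 1); rf <- ri - r0
  c0 <- pmin(floor(ci), ncol(m) - 1); cf <- ci - c0
  a <- m[r0, c0] * outer(1 - rf, 1 - cf) + m[r0 + 1, c0] * outer(rf, 1 - cf) +
    m[r0, c0 + 1] * outer(1 - rf, cf) + m[r0 + 1, c0 + 1] * outer(rf, cf)
  a
}

soil_background <- function(H, W) {
  base <- c(0.23, 0.175, 0.135)  # dark substrate brown
  coarse <- upsample_bilinear(matrix(stats::rnorm(ceiling(H / 16 + 2) * ceiling(W / 16 + 2),
                                                  0, 0.05),
                                     ceiling(H / 16 + 2)), H, W)
  mid <- upsample_bilinear(matrix(stats::rnorm(ceiling(H / 4 + 2) * ceiling(W / 4 + 2),
                                               0, 0.03),
                                  ceiling(H / 4 + 2)), H, W)
  fine <- matrix(stats::rnorm(H * W, 0, 0.02), H, W)
  lum <- coarse + mid + fine
  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3) img[, , k] <- pmin(pmax(base[k] * (1 + 1.6 * lum), 0), 1)
  img
}

blend_patch <- function(img, rows, cols, alpha, color) {
  for (k in 1:3) {
    patch <- img[rows, cols, k]
    img[rows, cols, k] <- patch * (1 - alpha) + color[k] * alpha
  }
  img
}

draw_ellipse <- function(img, cx, cy, a, b, theta, color, alpha = 1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(a, b) + 2
  if (cy + r < 1 || cy - r > H || cx + r < 1 || cx - r > W) return(img)
  rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  y <- rows - cy; x <- cols - cx
  xu <- outer(rep(1, length(rows)), x); yu <- outer(y, rep(1, length(cols)))
  u <- xu * cos(theta) + yu * sin(theta)
  v <- -xu * sin(theta) + yu * cos(theta)
  d <- (u / a)^2 + (v / b)^2
  am <- alpha * pmin(1, pmax(0, (1 - d) * 3))
  blend_patch(img, rows, cols, am, color)
}

draw_discs <- function(img, pts, radius, color, alphas) {
  H <- dim(img)[1]; W <- dim(img)[2]
  for (i in seq_len(nrow(pts))) {
    if (alphas[i] <= 0.01) next
    cx <- pts[i, 1]; cy <- pts[i, 2]
    r <- radius + 1.5
    if (cy + r < 1 || cy - r > H || cx + r < 1 || cx - r > W) next
    rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    d2 <- outer((rows - cy)^2, rep(1, length(cols))) +
      outer(rep(1, length(rows)), (cols - cx)^2)
    am <- alphas[i] * pmin(1, pmax(0, (radius + 0.5 - sqrt(d2))))
    img <- blend_patch(img, rows, cols, am, color)
  }
  img
}

# curved path of `n` points starting at (x0, y0) heading `theta`
wiggle_path <- function(x0, y0, theta, length, step = 2, wiggle = 0.14) {
  n <- max(2, ceiling(length / step))
  ang <- theta + cumsum(stats::rnorm(n, 0, wiggle))
  dx <- cumsum(step * cos(ang)); dy <- cumsum(step * sin(ang))
  cbind(x0 + dx, y0 + dy)
}

#' Generate a synthetic soil seed scene
#'
#' Draws the soil background, distractors, seeds and radicles, and derives
#' annotations: one box per germinated seed (covering the seed body plus the
#' visible part of its radicle), with the class set by [label_root_class()]
#' applied to the *true* root length -- mirroring an annotator who knows the
#' seed, even when part of the root is buried.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `seed_scene`: `image` (8-bit integer array
#'   H x W x 3), `seeds` (per-seed truth tibble), `annotations`
#'   (normalized cxcywh tibble as in [read_annotations()]), `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$rng_seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  H <- p$image_size[1]; W <- p$image_size[2]
  rows <- p$grid[1]; cols <- p$grid[2]
  img <- soil_background(H, W)

  cell_h <- H / rows; cell_w <- W / cols
  centers <- cbind(
    x = rep((seq_len(cols) - 0.5) * cell_w, each = rows),
    y = rep((seq_len(rows) - 0.5) * cell_h, times = cols)
  )
  n_seed <- rows * cols

  seed_color_base <- c(0.86, 0.78, 0.58)
  root_color <- c(0.93, 0.91, 0.82)

  # distractors first (under seeds); rejection-placed away from cell centers
  place_away <- function() {
    for (i in 1:50) {
      x <- stats::runif(1, 4, W - 4); y <- stats::runif(1, 4, H - 4)
      if (min((centers[, 1] - x)^2 + (centers[, 2] - y)^2) >
          (0.33 * min(cell_w, cell_h))^2) return(c(x, y))
    }
    c(x, y)
  }
  for (i in seq_len(p$n_stones)) {
    xy <- place_away()
    a <- stats::runif(1, 3, 0.18 * min(cell_w, cell_h) + 3)
    col <- pmin(pmax(seed_color_base * stats::runif(1, 0.55, 0.8) +
                       stats::rnorm(3, 0, 0.03), 0), 1)
    img <- draw_ellipse(img, xy[1], xy[2], a, a * stats::runif(1, 0.6, 0.9),
                        stats::runif(1, 0, pi), col, alpha = 0.95)
  }
  for (i in seq_len(p$n_fibers)) {
    xy <- place_away()
    pts <- wiggle_path(xy[1], xy[2], stats::runif(1, 0, 2 * pi),
                       stats::runif(1, 0.3, 0.9) * min(cell_w, cell_h))
    col <- pmin(pmax(root_color * stats::runif(1, 0.6, 0.85) +
                       stats::rnorm(3, 0, 0.02), 0), 1)
    img <- draw_discs(img, pts, 1.1, col, rep(0.85, nrow(pts)))
  }

  germ <- stats::runif(n_seed) < p$germination_fraction
  seed_len <- stats::runif(n_seed, p$seed_length_range[1], p$seed_length_range[2])
  ratio <- stats::runif(n_seed, p$root_length_ratio_range[1],
                        p$root_length_ratio_range[2])
  buried <- germ & (stats::runif(n_seed) < p$burial_probability)
  theta <- stats::runif(n_seed, 0, 2 * pi)
  jx <- stats::runif(n_seed, -p$jitter, p$jitter)
  jy <- stats::runif(n_seed, -p$jitter, p$jitter)

  seeds <- tibble::tibble(
    seed = seq_len(n_seed),
    cx = centers[, 1] + jx, cy = centers[, 2] + jy,
    seed_length = seed_len, angle = theta,
    germinated = germ,
    root_length = ifelse(germ, ratio * seed_len, 0),
    buried = buried
  )

  ann <- list()
  for (i in seq_len(n_seed)) {
    s <- seeds[i, ]
    a <- s$seed_length / 2; b <- a * stats::runif(1, 0.5, 0.62)
    col <- pmin(pmax(seed_color_base + stats::rnorm(3, 0, 0.035), 0), 1)
    img <- draw_ellipse(img, s$cx, s$cy, a, b, s$angle, col)
    if (!s$germinated) next

    tip <- c(s$cx + a * cos(s$angle), s$cy + a * sin(s$angle))
    pts <- wiggle_path(tip[1], tip[2], s$angle, s$root_length)
    np <- nrow(pts)
    alphas <- rep(0.95, np)
    if (s$buried) {
      # the radicle dives under the soil partway along, maybe re-emerging
      frac <- seq(0, 1, length.out = np)
      s0 <- stats::runif(1, 0.2, 0.5)
      s1 <- min(1, s0 + stats::runif(1, 0.3, 0.8))
      alphas[frac >= s0 & frac < s1] <- 0.1
    }
    img <- draw_discs(img, pts, 1.4, root_color, alphas)

    vis <- pts[alphas > 0.5, , drop = FALSE]
    if (p$box_extent == "seed_plus_root") {
      ex <- max(a, b)
      x1 <- min(s$cx - ex, vis[, 1]); x2 <- max(s$cx + ex, vis[, 1])
      y1 <- min(s$cy - ex, vis[, 2]); y2 <- max(s$cy + ex, vis[, 2])
    } else {
      x1 <- min(vis[, 1]); x2 <- max(vis[, 1])
      y1 <- min(vis[, 2]); y2 <- max(vis[, 2])
    }
    pad <- 1.5
    x1 <- max(0, x1 - pad); y1 <- max(0, y1 - pad)
    x2 <- min(W, x2 + pad); y2 <- min(H, y2 + pad)
    ann[[length(ann) + 1L]] <- tibble::tibble(
      seed = i,
      class_id = label_root_class(s$root_length, s$seed_length),
      cx = (x1 + x2) / 2 / W, cy = (y1 + y2) / 2 / H,
      w = (x2 - x1) / W, h = (y2 - y1) / H
    )
  }
  annotations <- if (length(ann)) dplyr::bind_rows(ann) else
    tibble::tibble(seed = integer(0), class_id = integer(0), cx = double(0),
                   cy = double(0), w = double(0), h = double(0))

  img8 <- array(as.integer(round(pmin(pmax(img, 0), 1) * 255)), dim = dim(img))
  structure(list(image = img8, seeds = seeds, annotations = annotations,
                 params = p),
            class = "seed_scene")
}

#' @export
print.seed_scene <- function(x, ...) {
  cat(sprintf("Synthetic seed scene %dx%d: %d seeds, %d germinated, %d annotations\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$seeds),
              sum(x$seeds$germinated), nrow(x$annotations)))
  invisible(x)
}

#' @export
autoplot.seed_scene <- function(object, ...) {
  H <- dim(object$image)[1]; W <- dim(object$image)[2]
  ann <- object$annotations
  df <- tibble::tibble(
    xmin = (ann$cx - ann$w / 2) * W, xmax = (ann$cx + ann$w / 2) * W,
    ymin = (ann$cy - ann$h / 2) * H, ymax = (ann$cy + ann$h / 2) * H,
    class = factor(root_class_names()[ann$class_id + 1L],
                   levels = root_class_names())
  )
  ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(object$image / 255),
                               xmin = 0, xmax = W, ymin = -H, ymax = 0) +
    ggplot2::geom_rect(data = df,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -.data$ymax, ymax = -.data$ymin,
                                    colour = .data$class),
                       fill = NA, linewidth = 0.4) +
    ggplot2::coord_fixed(xlim = c(0, W), ylim = c(-H, 0), expand = FALSE) +
    ggplot2::labs(colour = "class", x = NULL, y = NULL)
}

#' Write an 8-bit RGB array as PNG
#' @param image Integer array (H, W, 3) with values 0..255.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a PNG into an 8-bit RGB array
#' @param path PNG file.
#' @return Integer array (H, W, 3), values 0..255.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes PNG images, YOLO-txt labels, a dataset YAML config, and a JSON
#' manifest recording the per-image RNG seeds so any image (or the whole
#' dataset) can be regenerated bit-identically.
#'
#' @param n_images Number of scenes (>= 1).
#' @param params [scene_params()] template; image `i` uses
#'   `rng_seed = params$rng_seed + i - 1`.
#' @param out_dir Output directory (created).
#' @param split Ratios for a 7:2:1-style train/test/val split, or `NULL` for
#'   a flat directory.
#' @return Invisibly, the manifest (list) with per-image seeds and paths.
#' @export
generate_dataset <- function(n_images, params = scene_params(), out_dir,
                             split = c(7, 2, 1)) {
  stopifnot(n_images >= 1)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  ids <- sprintf("scene_%04d", seq_len(n_images))
  assignment <- if (is.null(split)) {
    rep("all", n_images)
  } else {
    sp <- split_dataset(seq_len(n_images), ratios = split,
                        rng_seed = params$rng_seed)
    out <- character(n_images)
    out[sp$train] <- "train"; out[sp$test] <- "test"; out[sp$val] <- "val"
    out
  }
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    pi <- params
    pi$rng_seed <- params$rng_seed + i - 1L
    scene <- generate_scene(pi)
    img_dir <- file.path(out_dir, "images", assignment[i])
    lab_dir <- file.path(out_dir, "labels", assignment[i])
    dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(lab_dir, showWarnings = FALSE, recursive = TRUE)
    img_path <- file.path(img_dir, paste0(ids[i], ".png"))
    lab_path <- file.path(lab_dir, paste0(ids[i], ".txt"))
    write_image(scene$image, img_path)
    write_annotations(scene$annotations[, c("class_id", "cx", "cy", "w", "h")],
                      lab_path, "yolo_txt")
    records[[i]] <- list(id = ids[i], rng_seed = pi$rng_seed,
                         split = assignment[i],
                         image = img_path, labels = lab_path)
  }
  cfg <- dataset_config(
    train = file.path("images", "train"), test = file.path("images", "test"),
    val = file.path("images", "val"),
    ratios = if (is.null(split)) c(7, 2, 1) else split
  )
  write_dataset_config(cfg, file.path(out_dir, "dataset.yaml"))
  manifest <- list(n_images = n_images, base_seed = params$rng_seed,
                   images = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
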