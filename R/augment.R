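# Online training-time augmentation: four mild, geometry-preserving
# transforms (box blur, median blur, CLAHE, grayscale), each fired
# independently with a small probability per batch so every batch sees a
# different random variation. Bounding boxes pass through unchanged.

#' Configuration of the online augmentation pipeline
#'
#' Defaults follow the mild recipe appropriate for partly buried, very small
#' targets: every transform fires with probability 1% and kernel sizes stay
#' small, so no augmentation can destroy a radicle only a few pixels wide.
#'
#' @param p_blur,p_medianblur,p_clahe,p_togray Firing probabilities in
#'   \[0, 1\] (default 0.01 each).
#' @param blur_limit Maximum box-blur kernel size (odd, >= 3, default 5).
#' @param median_limit Maximum median-filter kernel size (odd, >= 3, default 5).
#' @param clahe_clip CLAHE clip limit (default 4).
#' @param clahe_grid CLAHE tile count per side (default 8).
#' @return List of class `augment_config`.
#' @export
augment_config <- function(p_blur = 0.01, p_medianblur = 0.01,
                           p_clahe = 0.01, p_togray = 0.01,
                           blur_limit = 5, median_limit = 5,
                           clahe_clip = 4, clahe_grid = 8) {
  probs <- c(p_blur, p_medianblur, p_clahe, p_togray)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (k in c(blur_limit, median_limit)) {
    if (k < 3 || k %% 2 == 0) stop("kernel sizes must be odd and >= 3")
  }
  structure(list(p_blur = p_blur, p_medianblur = p_medianblur,
                 p_clahe = p_clahe, p_togray = p_togray,
                 blur_limit = blur_limit, median_limit = median_limit,
                 clahe_clip = clahe_clip, clahe_grid = clahe_grid),
            class = "augment_config")
}

check_image8 <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an (H, W, 3) array")
  }
  if (!is.integer(image) || any(image < 0L) || any(image > 255L)) {
    stop("image must be 8-bit: integer values in 0..255")
  }
  image
}

to_unit <- function(image) image / 255
to_byte <- function(x) array(as.integer(round(pmin(pmax(x, 0), 1) * 255)), dim = dim(x))

apply_box_blur <- function(x, k) {
  kern <- matrix(1 / (k * k), k, k)
  for (c in 1:3) x[, , c] <- EBImage::filter2(x[, , c], kern)
  x
}

apply_median_blur <- function(x, k) {
  for (c in 1:3) x[, , c] <- EBImage::medianFilter(x[, , c], size = (k - 1) / 2)
  x
}

apply_clahe <- function(x, clip, grid) {
  H <- dim(x)[1]; W <- dim(x)[2]
  nx <- max(2, min(grid, floor(W / 16)))
  ny <- max(2, min(grid, floor(H / 16)))
  img <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::clahe(img, nx = nx, ny = ny, limit = clip)
  pmin(pmax(aperm(EBImage::imageData(out), c(2, 1, 3)), 0), 1)
}

apply_togray <- function(x) {
  g <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  array(rep(g, 3), dim = dim(x))  # luminance replicated on 3 channels
}

#' Build the online augmentation pipeline
#'
#' The pipeline applies, in order: box blur, median blur, CLAHE and
#' grayscale conversion, each independently with its configured probability.
#' All four transforms preserve geometry, so annotations never change.
#'
#' @param cfg An [augment_config()].
#' @return A function-carrying list of class `augment_pipeline`; use
#'   [apply_augment()] to run it.
#' @export
build_augment_pipeline <- function(cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  structure(list(config = cfg), class = "augment_pipeline")
}

#' Apply the augmentation pipeline to an image
#'
#' Draws which transforms fire from the current RNG state (or from `seed`):
#' the same state reproduces the same output, while successive calls on the
#' same image generally differ -- the "online" property that gives every
#' training batch a fresh variation.
#'
#' @param pipeline From [build_augment_pipeline()].
#' @param image 8-bit RGB array (H, W, 3), integer 0..255.
#' @param annotations Optional annotation tibble; returned unchanged.
#' @param seed Optional integer seed for a reproducible draw.
#' @return List with `image` (same type/size), `annotations`, and `fired`
#'   (named logical vector of which transforms applied).
#' @export
apply_augment <- function(pipeline, image, annotations = NULL, seed = NULL) {
  stopifnot(inherits(pipeline, "augment_pipeline"))
  check_image8(image)
  cfg <- pipeline$config
  run <- function() {
    fired <- c(blur = stats::runif(1) < cfg$p_blur,
               medianblur = stats::runif(1) < cfg$p_medianblur,
               clahe = stats::runif(1) < cfg$p_clahe,
               togray = stats::runif(1) < cfg$p_togray)
    x <- to_unit(image)
    if (fired["blur"]) {
      k <- sample(seq(3, cfg$blur_limit, by = 2), 1)
      x <- apply_box_blur(x, k)
    }
    if (fired["medianblur"]) {
      k <- sample(seq(3, cfg$median_limit, by = 2), 1)
      x <- apply_median_blur(x, k)
    }
    if (fired["clahe"]) x <- apply_clahe(x, cfg$clahe_clip, cfg$clahe_grid)
    if (fired["togray"]) x <- apply_togray(x)
    list(image = to_byte(x), annotations = annotations, fired = fired)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
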