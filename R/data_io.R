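# Annotation I/O (YOLO-txt and LabelImg Pascal-VOC XML), dataset splitting and
# the dataset YAML config. Boxes cross file boundaries in normalized
# (cx, cy, w, h); geometry elsewhere in the package uses continuous pixel
# (x1, y1, x2, y2) with a single conversion point here.

validate_annotations <- function(ann) {
  if (nrow(ann) == 0) return(ann)
  if (any(!ann$class_id %in% c(0L, 1L))) stop("class_id must be 0 (SROOT) or 1 (LROOT)")
  if (any(ann$cx < 0 | ann$cx > 1 | ann$cy < 0 | ann$cy > 1)) {
    stop("box centers must be normalized to [0, 1]")
  }
  if (any(ann$w <= 0 | ann$h <= 0 | ann$w > 1 | ann$h > 1)) {
    stop("box sizes must lie in (0, 1]")
  }
  ann
}

empty_annotations <- function() {
  tibble::tibble(class_id = integer(0), cx = double(0), cy = double(0),
                 w = double(0), h = double(0))
}

#' Read box annotations from a label file
#'
#' Supports YOLO-txt (`class cx cy w h`, normalized) and LabelImg Pascal-VOC
#' XML (pixel `xmin/ymin/xmax/ymax`, converted here to normalized center
#' form). Class names in VOC files must be `SROOT` or `LROOT`.
#'
#' @param path Label file.
#' @param format `"yolo_txt"` or `"voc_xml"`.
#' @param image_size Image size as `c(width, height)` in pixels; required for
#'   `voc_xml` when the file lacks a `<size>` element, ignored for YOLO.
#' @return Tibble with columns `class_id`, `cx`, `cy`, `w`, `h` (normalized).
#' @export
read_annotations <- function(path, format = c("yolo_txt", "voc_xml"),
                             image_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("label file not found: ", path)
  if (format == "yolo_txt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_annotations())
    parsed <- lapply(seq_along(lines), function(i) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(parts) != 5 || anyNA(suppressWarnings(as.numeric(parts)))) {
        stop("malformed YOLO label line ", i, " in ", path, ": '", lines[i], "'")
      }
      as.numeric(parts)
    })
    m <- do.call(rbind, parsed)
    ann <- tibble::tibble(class_id = as.integer(m[, 1]), cx = m[, 2],
                          cy = m[, 3], w = m[, 4], h = m[, 5])
  } else {
    doc <- xml2::read_xml(path)
    size <- xml2::xml_find_first(doc, ".//size")
    if (!inherits(size, "xml_missing")) {
      image_size <- c(as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width"))),
                      as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height"))))
    }
    if (is.null(image_size) || anyNA(image_size)) {
      stop("voc_xml needs image_size = c(width, height) when the file has no <size>")
    }
    objs <- xml2::xml_find_all(doc, ".//object")
    if (length(objs) == 0) return(empty_annotations())
    rows <- lapply(seq_along(objs), function(i) {
      o <- objs[[i]]
      name <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
      cls <- match(name, root_class_names()) - 1L
      if (is.na(cls)) stop("unknown class '", name, "' in object ", i, " of ", path)
      num <- function(tag) {
        v <- suppressWarnings(as.numeric(
          xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag)))))
        if (is.na(v)) stop("missing/invalid <", tag, "> in object ", i, " of ", path)
        v
      }
      c(cls, num("xmin"), num("ymin"), num("xmax"), num("ymax"))
    })
    m <- do.call(rbind, rows)
    W <- image_size[1]; H <- image_size[2]
    ann <- tibble::tibble(class_id = as.integer(m[, 1]),
                          cx = (m[, 2] + m[, 4]) / 2 / W,
                          cy = (m[, 3] + m[, 5]) / 2 / H,
                          w = (m[, 4] - m[, 2]) / W,
                          h = (m[, 5] - m[, 3]) / H)
  }
  validate_annotations(ann)
}

#' Write box annotations to a label file
#'
#' Inverse of [read_annotations()]; round-trips to 6 decimal places.
#'
#' @param annotations Tibble with `class_id`, `cx`, `cy`, `w`, `h` (normalized).
#' @param path Output file.
#' @param format `"yolo_txt"` or `"voc_xml"`.
#' @param image_size `c(width, height)` in pixels; required for `voc_xml`.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path,
                              format = c("yolo_txt", "voc_xml"),
                              image_size = NULL) {
  format <- match.arg(format)
  ann <- validate_annotations(tibble::as_tibble(annotations))
  if (format == "yolo_txt") {
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     ann$class_id, ann$cx, ann$cy, ann$w, ann$h)
    writeLines(lines, path)
  } else {
    if (is.null(image_size)) stop("voc_xml needs image_size = c(width, height)")
    W <- image_size[1]; H <- image_size[2]
    doc <- xml2::xml_new_root("annotation")
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(W))
    xml2::xml_add_child(sz, "height", as.character(H))
    xml2::xml_add_child(sz, "depth", "3")
    for (i in seq_len(nrow(ann))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", root_class_names()[ann$class_id[i] + 1L])
      bb <- xml2::xml_add_child(o, "bndbox")
      xml2::xml_add_child(bb, "xmin", sprintf("%.4f", (ann$cx[i] - ann$w[i] / 2) * W))
      xml2::xml_add_child(bb, "ymin", sprintf("%.4f", (ann$cy[i] - ann$h[i] / 2) * H))
      xml2::xml_add_child(bb, "xmax", sprintf("%.4f", (ann$cx[i] + ann$w[i] / 2) * W))
      xml2::xml_add_child(bb, "ymax", sprintf("%.4f", (ann$cy[i] + ann$h[i] / 2) * H))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Split items into train/test/val partitions
#'
#' Random, seed-reproducible partition with sizes given by largest-remainder
#' apportionment of the ratios (so 1000 items at 7:2:1 give exactly
#' 700/200/100). The split is at item (image) level: no item ever appears in
#' two splits.
#'
#' @param items Vector or list of items (e.g. image paths).
#' @param ratios Positive weights for train/test/val, default `c(7, 2, 1)`;
#'   normalized internally.
#' @param rng_seed Integer seed for the shuffle.
#' @return Named list `train`, `test`, `val` of disjoint subsets covering
#'   `items`.
#' @export
split_dataset <- function(items, ratios = c(7, 2, 1), rng_seed = 0L) {
  if (length(ratios) != 3 || any(ratios <= 0)) {
    stop("ratios must be three positive numbers (train, test, val)")
  }
  n <- length(items)
  p <- ratios / sum(ratios)
  quota <- n * p
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  idx <- with_seed(rng_seed, sample.int(n))
  bounds <- cumsum(c(0, sizes))
  pick <- function(k) items[idx[seq2(bounds[k] + 1, bounds[k + 1])]]
  list(train = pick(1), test = pick(2), val = pick(3))
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

# evaluate expr under a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Dataset configuration
#'
#' @param train,test,val Paths of the three split image directories (or list
#'   files), relative to the config location.
#' @param names Class names; must stay `c("SROOT", "LROOT")` for this model
#'   family.
#' @param ratios Split ratios used to produce the splits.
#' @return List of class `dataset_config`.
#' @export
dataset_config <- function(train = "images/train", test = "images/test",
                           val = "images/val",
                           names = root_class_names(), ratios = c(7, 2, 1)) {
  if (any(ratios <= 0)) stop("split ratios must be positive")
  structure(list(train = train, test = test, val = val, names = names,
                 ratios = as.numeric(ratios / sum(ratios))),
            class = "dataset_config")
}

#' Write a dataset config YAML
#' @param config A [dataset_config()].
#' @param path Output YAML file.
#' @return Invisibly, `path`.
#' @export
write_dataset_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a dataset config YAML
#' @param path YAML file written by [write_dataset_config()].
#' @return A [dataset_config()].
#' @export
read_dataset_config <- function(path) {
  x <- yaml::read_yaml(path)
  dataset_config(train = x$train, test = x$test, val = x$val,
                 names = unlist(x$names), ratios = unlist(x$ratios))
}
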