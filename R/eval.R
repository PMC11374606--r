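# Detection evaluation: greedy confidence-ordered matching, precision/recall,
# 101-point interpolated average precision, the missed/false-alarm/repeated
# error taxonomy, and a confusion matrix.
#
# Detections and ground truths are tibbles with columns
#   image_id, class_id, cx, cy, w, h  (+ conf for detections),
# boxes in any consistent unit (normalized or pixels).

check_iou_threshold <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1) {
    stop("iou_threshold must lie strictly inside (0, 1)")
  }
  x
}

empty_det <- function() {
  tibble::tibble(image_id = character(0), class_id = integer(0),
                 cx = double(0), cy = double(0), w = double(0), h = double(0),
                 conf = double(0))
}

# Match detections of one image to ground truths. Greedy in confidence order:
# each detection takes the highest-IoU unconsumed GT of its class with
# IoU >= threshold. Returns per-detection flags.
match_image <- function(dets, gts, iou_threshold) {
  nd <- nrow(dets); ng <- nrow(gts)
  matched_gt <- integer(0)
  flag <- character(nd)          # "tp", "repeated", "false_alarm"
  gt_of_det <- rep(NA_integer_, nd)
  if (nd > 0) {
    ord <- order(-dets$conf)
    gt_taken <- rep(FALSE, ng)
    db <- as_box_matrix(dets)
    gb <- if (ng > 0) as_box_matrix(gts) else matrix(0, 0, 4)
    for (i in ord) {
      if (ng == 0) { flag[i] <- "false_alarm"; next }
      same <- which(gts$class_id == dets$class_id[i])
      if (length(same) == 0) { flag[i] <- "false_alarm"; next }
      ious <- iou(matrix(db[i, ], length(same), 4, byrow = TRUE),
                  gb[same, , drop = FALSE])
      ok <- ious >= iou_threshold
      if (!any(ok)) { flag[i] <- "false_alarm"; next }
      cand <- same[ok][order(-ious[ok])]
      free <- cand[!gt_taken[cand]]
      if (length(free) > 0) {
        gt_taken[free[1]] <- TRUE
        flag[i] <- "tp"
        gt_of_det[i] <- free[1]
      } else {
        flag[i] <- "repeated"   # overlaps only already-consumed GTs
      }
    }
    matched_gt <- which(gt_taken)
  }
  list(flag = flag, gt_of_det = gt_of_det, matched_gt = matched_gt,
       unmatched_gt = setdiff(seq_len(ng), matched_gt))
}

#' Match detections to ground truths at an IoU threshold
#'
#' Greedy one-to-one, class-aware matching in descending confidence order.
#' Each ground truth can be matched at most once; an extra detection whose
#' only qualifying overlap is with an already-consumed ground truth is a
#' false positive of the "repeated" kind.
#'
#' @param dets Tibble of detections (`image_id`, `class_id`, `cx`, `cy`, `w`,
#'   `h`, `conf`).
#' @param gts Tibble of ground truths (same columns, no `conf`).
#' @param iou_threshold IoU threshold in (0, 1); default 0.5.
#' @return List with counts `tp`, `fp`, `fn` and a per-detection tibble
#'   `flags` (columns `image_id`, `conf`, `flag`).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  check_iou_threshold(iou_threshold)
  if (nrow(dets) == 0) dets <- empty_det()
  images <- union(unique(dets$image_id), unique(gts$image_id))
  tp <- 0L; fp <- 0L; fn <- 0L
  flags <- list()
  for (img in images) {
    d <- dets[dets$image_id == img, , drop = FALSE]
    g <- gts[gts$image_id == img, , drop = FALSE]
    m <- match_image(d, g, iou_threshold)
    tp <- tp + sum(m$flag == "tp")
    fp <- fp + sum(m$flag != "tp")
    fn <- fn + length(m$unmatched_gt)
    if (nrow(d) > 0) {
      flags[[length(flags) + 1L]] <-
        tibble::tibble(image_id = d$image_id, conf = d$conf, flag = m$flag)
    }
  }
  list(tp = tp, fp = fp, fn = fn,
       flags = if (length(flags)) dplyr::bind_rows(flags) else
         tibble::tibble(image_id = character(0), conf = double(0), flag = character(0)))
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`. With no predictions at all
#' precision is defined as 1 (nothing asserted, nothing wrong); with no
#' ground truth objects recall is defined as 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector with elements `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r)
}

# cumulative PR points for one class across all images
pr_points <- function(dets, gts, iou_threshold) {
  n_gt <- nrow(gts)
  m <- match_detections(dets, gts, iou_threshold)
  fl <- m$flags[order(-m$flags$conf), , drop = FALSE]
  tp_cum <- cumsum(fl$flag == "tp")
  fp_cum <- cumsum(fl$flag != "tp")
  tibble::tibble(precision = tp_cum / (tp_cum + fp_cum),
                 recall = if (n_gt > 0) tp_cum / n_gt else rep(0, nrow(fl)))
}

#' Average precision for one class at one IoU threshold
#'
#' Area under the interpolated precision-recall curve, evaluated on the
#' 101-point recall grid 0, 0.01, ..., 1 with the precision envelope
#' `p(r) = max{precision at recall >= r}`.
#'
#' @inheritParams match_detections
#' @return AP in \[0, 1\], or `NA` (with a warning) if `gts` is empty.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  check_iou_threshold(iou_threshold)
  if (nrow(gts) == 0) {
    warning("no ground-truth objects: AP undefined")
    return(NA_real_)
  }
  pr <- pr_points(dets, gts, iou_threshold)
  if (nrow(pr) == 0) return(0)
  grid <- seq(0, 1, by = 0.01)
  env <- vapply(grid, function(r) {
    ok <- pr$recall >= r
    if (any(ok)) max(pr$precision[ok]) else 0
  }, numeric(1))
  mean(env)
}

#' Mean average precision over classes and IoU thresholds
#'
#' Computes per-class AP at IoU 0.5 and averaged over the threshold grid
#' 0.50, 0.55, ..., 0.95; means are over the classes present in `gts`.
#'
#' @inheritParams match_detections
#' @param thresholds IoU grid for the second value (default `seq(.5, .95, .05)`).
#' @return An object of class `eval_result`: list with `map50`, `map5095`,
#'   `per_class` (tibble of per-class AP at each threshold), and the counts
#'   `tp`, `fp`, `fn`, `precision`, `recall` at IoU 0.5.
#' @export
mean_ap <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(gts$class_id))
  if (length(classes) == 0) stop("gts must contain at least one class")
  if (nrow(dets) == 0) dets <- empty_det()
  per <- tidyr::expand_grid(class_id = classes, iou = thresholds)
  per$ap <- purrr::map2_dbl(per$class_id, per$iou, function(cl, t) {
    average_precision(dets[dets$class_id == cl, , drop = FALSE],
                      gts[gts$class_id == cl, , drop = FALSE], t)
  })
  ap50 <- per$ap[per$iou == 0.5]
  m <- match_detections(dets, gts, 0.5)
  pr <- precision_recall(m$tp, m$fp, m$fn)
  structure(list(map50 = mean(ap50),
                 map5095 = mean(per$ap),
                 per_class = per,
                 tp = m$tp, fp = m$fp, fn = m$fn,
                 precision = unname(pr["precision"]),
                 recall = unname(pr["recall"])),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Detection evaluation: mAP@0.5 = %.4f, mAP@0.5:0.95 = %.4f\n",
              x$map50, x$map5095))
  cat(sprintf("  TP %d / FP %d / FN %d  (P = %.4f, R = %.4f at IoU 0.5)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

#' @export
tidy.eval_result <- function(x, ...) x$per_class

#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map5095 = x$map5095,
                 precision = x$precision, recall = x$recall,
                 tp = x$tp, fp = x$fp, fn = x$fn)
}

#' @export
autoplot.eval_result <- function(object, ...) {
  df <- object$per_class
  df$class <- factor(root_class_names()[df$class_id + 1L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iou, y = .data$ap,
                                   colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "IoU threshold", y = "average precision",
                  title = "AP across IoU thresholds") +
    ggplot2::ylim(0, 1)
}

#' Tally detection errors into the missed / false-alarm / repeated taxonomy
#'
#' `missed` counts unmatched ground truths, `false_alarm` unmatched detections
#' that do not qualify against any consumed ground truth, and `repeated`
#' extra detections on an already-consumed ground truth. The error rate is
#' `(missed + false_alarm + repeated) / (n_images * seeds_per_image)`.
#'
#' @inheritParams match_detections
#' @param n_images Number of dish images the detections came from.
#' @param seeds_per_image Seeds sown per dish (49 for a 7 x 7 grid).
#' @return A tibble with one row: `missed`, `false_alarm`, `repeated`,
#'   `n_images`, `seeds_per_image`, `error_rate`.
#' @export
error_taxonomy <- function(dets, gts, n_images, seeds_per_image,
                           iou_threshold = 0.5) {
  if (seeds_per_image <= 0) stop("seeds_per_image must be positive")
  if (n_images <= 0) stop("n_images must be positive")
  m <- match_detections(dets, gts, iou_threshold)
  missed <- m$fn
  false_alarm <- sum(m$flags$flag == "false_alarm")
  repeated <- sum(m$flags$flag == "repeated")
  tibble::tibble(missed = missed, false_alarm = false_alarm,
                 repeated = repeated, n_images = n_images,
                 seeds_per_image = seeds_per_image,
                 error_rate = (missed + false_alarm + repeated) /
                   (n_images * seeds_per_image))
}

#' Confusion matrix between predicted and true root classes
#'
#' Detections are matched to ground truths class-agnostically by IoU; matched
#' pairs contribute (predicted class, true class), unmatched detections count
#' against the background column, and unmatched ground truths against the
#' background row.
#'
#' @inheritParams match_detections
#' @return An integer matrix with rows `SROOT`, `LROOT`, `background`
#'   (predicted) and columns `SROOT`, `LROOT`, `background` (true).
#' @export
confusion_matrix <- function(dets, gts, iou_threshold = 0.5) {
  check_iou_threshold(iou_threshold)
  cls <- root_class_names()
  nm <- c(cls, "background")
  cm <- matrix(0L, 3, 3, dimnames = list(predicted = nm, true = nm))
  if (nrow(dets) == 0) dets <- empty_det()
  images <- union(unique(dets$image_id), unique(gts$image_id))
  for (img in images) {
    d <- dets[dets$image_id == img, , drop = FALSE]
    g <- gts[gts$image_id == img, , drop = FALSE]
    gt_taken <- rep(FALSE, nrow(g))
    if (nrow(d) > 0) {
      db <- as_box_matrix(d)
      gb <- if (nrow(g) > 0) as_box_matrix(g) else matrix(0, 0, 4)
      for (i in order(-d$conf)) {
        matched <- FALSE
        if (nrow(g) > 0) {
          ious <- iou(matrix(db[i, ], nrow(g), 4, byrow = TRUE), gb)
          ious[gt_taken] <- -1
          j <- which.max(ious)
          if (ious[j] >= iou_threshold) {
            gt_taken[j] <- TRUE
            cm[d$class_id[i] + 1L, g$class_id[j] + 1L] <-
              cm[d$class_id[i] + 1L, g$class_id[j] + 1L] + 1L
            matched <- TRUE
          }
        }
        if (!matched) cm[d$class_id[i] + 1L, 3L] <- cm[d$class_id[i] + 1L, 3L] + 1L
      }
    }
    if (nrow(g) > 0) {
      for (j in which(!gt_taken)) {
        cm[3L, g$class_id[j] + 1L] <- cm[3L, g$class_id[j] + 1L] + 1L
      }
    }
  }
  cm
}
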