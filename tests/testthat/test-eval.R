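# Detection matching, precision/recall, average precision against the
# independent envelope oracle, error taxonomy, confusion matrix.

test_that("match_detections handles perfect, empty and repeated cases", {
  gts <- det_tbl("a", c(0L, 1L), c(0.3, 0.7), c(0.3, 0.7), 0.1, 0.1)
  dets <- gts; dets$conf <- c(0.9, 0.8)
  m <- match_detections(dets, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  m0 <- match_detections(dets[0, ], gts)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 2L))

  # two detections on one GT: one TP, one repeated FP
  dets2 <- det_tbl("a", 0L, c(0.3, 0.31), c(0.3, 0.3), 0.1, 0.1,
                   conf = c(0.9, 0.8))
  m2 <- match_detections(dets2, gts[1, ])
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  expect_equal(sort(m2$flags$flag), c("repeated", "tp"))
  expect_error(match_detections(dets, gts, iou_threshold = 1.2), "inside")
})

test_that("precision and recall follow the defining ratios and conventions", {
  expect_equal(unname(precision_recall(49, 1, 0)), c(0.98, 1))
  expect_equal(unname(precision_recall(0, 0, 5)), c(1, 0))
  expect_equal(unname(precision_recall(9, 1, 1)), c(0.9, 0.9))
  expect_equal(unname(precision_recall(0, 0, 0)), c(1, 0))
})

test_that("average precision reproduces the hand-computed 3-detection case", {
  gts <- det_tbl("a", 0L, c(0.2, 0.8), c(0.2, 0.8), 0.1, 0.1)
  dets <- det_tbl("a", 0L,
                  cx = c(0.2, 0.5, 0.8), cy = c(0.2, 0.5, 0.8),
                  w = 0.1, h = 0.1, conf = c(0.9, 0.8, 0.7))
  # conf .9 TP, .8 FP (no GT there), .7 TP:
  # envelope: p=1 for r<=0.5, p=2/3 above -> (51 + 50*2/3)/101
  expect_equal(average_precision(dets, gts), (51 + 50 * 2 / 3) / 101,
               tolerance = 1e-12)
  expect_equal(average_precision(dets[1, ], gts[1, ]), 1)
  wrong <- dets[1, ]; wrong$class_id <- 1L
  expect_equal(average_precision(wrong, gts[1, ]), 0)
  expect_warning(ap <- average_precision(dets, gts[0, ]), "undefined")
  expect_true(is.na(ap))
})

test_that("average precision equals the brute-force envelope oracle", {
  for (seed in 1:100) {
    case <- random_eval_case(n_gt = sample(2:8, 1), n_extra = sample(0:6, 1),
                             n_images = sample(1:3, 1), seed = seed)
    for (cl in unique(case$gts$class_id)) {
      d <- case$dets[case$dets$class_id == cl, ]
      g <- case$gts[case$gts$class_id == cl, ]
      thr <- sample(c(0.3, 0.5, 0.75), 1)
      expect_equal(average_precision(d, g, thr), oracle_ap(d, g, thr),
                   tolerance = 1e-9)
    }
  }
})

test_that("adding a correct detection never lowers AP; higher IoU never raises it", {
  set.seed(11)
  for (trial in 1:10) {
    case <- random_eval_case(n_gt = 5, n_extra = 3, seed = trial + 100)
    d <- case$dets[case$dets$class_id == 0, ]
    g <- case$gts[case$gts$class_id == 0, ]
    if (nrow(g) == 0) next
    ap1 <- average_precision(d, g, 0.5)
    # append an exact copy of an unmatched GT at top confidence
    extra <- g[1, ]; extra$conf <- 1
    ap2 <- average_precision(dplyr::bind_rows(extra, d), g, 0.5)
    expect_gte(ap2 + 1e-12, ap1)
    expect_lte(average_precision(d, g, 0.75), ap1 + 1e-12)
  }
})

test_that("mean AP is perfect for perfect detections and 0 for wrong classes", {
  gts <- det_tbl("a", c(0L, 1L, 0L), c(0.2, 0.5, 0.8), 0.5, 0.1, 0.1)
  dets <- gts; dets$conf <- 0.9
  r <- mean_ap(dets, gts)
  expect_equal(r$map50, 1)
  expect_equal(r$map5095, 1)
  flipped <- dets; flipped$class_id <- 1L - flipped$class_id
  r2 <- mean_ap(flipped, gts)
  expect_equal(r2$map50, 0)
  # threshold monotonicity
  case <- random_eval_case(n_gt = 6, n_extra = 4, seed = 42)
  r3 <- mean_ap(case$dets, case$gts)
  expect_lte(r3$map5095, r3$map50 + 1e-12)
  # tidy/glance accessors
  expect_s3_class(tidy(r3), "tbl_df")
  expect_equal(nrow(glance(r3)), 1L)
})

test_that("error taxonomy counts missed, false alarms and repeats", {
  gts <- det_tbl("a", 0L, c(0.2, 0.5, 0.8), 0.5, 0.1, 0.1)
  dets <- det_tbl("a", 0L,
                  cx = c(0.2, 0.21, 0.9), cy = c(0.5, 0.5, 0.1),
                  w = 0.1, h = 0.1, conf = c(0.9, 0.8, 0.7))
  # det1 TP on gt1, det2 repeated on gt1, det3 false alarm; gt2, gt3 missed
  tal <- error_taxonomy(dets, gts, n_images = 1, seeds_per_image = 49)
  expect_equal(tal$missed, 2L)
  expect_equal(tal$false_alarm, 1L)
  expect_equal(tal$repeated, 1L)
  expect_equal(tal$error_rate, 4 / 49)
  # error components always sum to matcher FP + FN
  m <- match_detections(dets, gts)
  expect_equal(tal$missed + tal$false_alarm + tal$repeated, m$fp + m$fn)
  # the reported dish experiment arithmetic: 11 errors over 30 dishes of 49
  expect_equal(error_taxonomy(det_tbl("z", 0L, .5, .5, .1, .1, 1)[0, ],
                              det_tbl("z", 0L, .5, .5, .1, .1)[0, ],
                              30, 49)$error_rate, 0)
  expect_equal((1 + 7 + 3) / (30 * 49), 11 / 1470)
  expect_error(error_taxonomy(dets, gts, 1, 0), "positive")
})

test_that("confusion matrix separates classes and background", {
  gts <- det_tbl("a", c(0L, 1L), c(0.3, 0.7), 0.5, 0.1, 0.1)
  dets <- gts; dets$conf <- 0.9
  cm <- confusion_matrix(dets, gts)
  expect_equal(unname(diag(cm)[1:2]), c(1L, 1L))
  expect_equal(sum(cm), 2L)
  # a detection on empty soil lands in the background column
  ghost <- det_tbl("a", 0L, 0.05, 0.05, 0.05, 0.05, conf = 0.8)
  cm2 <- confusion_matrix(dplyr::bind_rows(dets, ghost), gts)
  expect_equal(unname(cm2["SROOT", "background"]), 1L)
  # a missed LROOT lands in the background row
  cm3 <- confusion_matrix(dets[1, ], gts)
  expect_equal(unname(cm3["background", "LROOT"]), 1L)
  # every detection and every ground truth is tallied exactly once
  for (seed in 1:5) {
    case <- random_eval_case(seed = seed + 300)
    cm4 <- confusion_matrix(case$dets, case$gts)
    expect_equal(sum(cm4[1:2, ]), nrow(case$dets))
    expect_equal(sum(cm4[, 1:2]), nrow(case$gts))
  }
})
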