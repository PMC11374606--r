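# Annotation format I/O, dataset splitting, config round-trips.

test_that("YOLO lines parse to normalized annotations", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.2", "1 0.25 0.75 0.05 0.05"), f)
  ann <- read_annotations(f, "yolo_txt")
  expect_equal(ann$class_id, c(0L, 1L))
  expect_equal(ann$cx, c(0.5, 0.25))
  expect_equal(ann$h, c(0.2, 0.05))
  # empty file -> empty tibble
  writeLines(character(0), f)
  expect_equal(nrow(read_annotations(f, "yolo_txt")), 0L)
  # malformed line is reported with its number
  writeLines(c("0 0.5 0.5 0.1 0.2", "oops"), f)
  expect_error(read_annotations(f, "yolo_txt"), "line 2")
  # out-of-range coordinates rejected
  writeLines("0 1.5 0.5 0.1 0.2", f)
  expect_error(read_annotations(f, "yolo_txt"), "normalized")
})

test_that("VOC pixel boxes convert to normalized center form", {
  f <- withr::local_tempfile(fileext = ".xml")
  ann <- det_tbl("x", 0L, 0.05, 0.05, 0.1, 0.1)[, -1]
  write_annotations(ann, f, "voc_xml", image_size = c(640, 640))
  # the file holds xmin=0, ymin=0, xmax=64, ymax=64
  txt <- readLines(f)
  expect_true(any(grepl("64.0000", txt)))
  back <- read_annotations(f, "voc_xml")
  expect_equal(back$cx, 0.05, tolerance = 1e-6)
  expect_equal(back$w, 0.1, tolerance = 1e-6)
  expect_equal(back$class_id, 0L)
})

test_that("both formats round-trip to 6 decimals", {
  set.seed(7)
  ann <- tibble::tibble(class_id = sample(0:1, 5, TRUE),
                        cx = round(runif(5, .2, .8), 6),
                        cy = round(runif(5, .2, .8), 6),
                        w = round(runif(5, .05, .2), 6),
                        h = round(runif(5, .05, .2), 6))
  fy <- withr::local_tempfile(fileext = ".txt")
  write_annotations(ann, fy, "yolo_txt")
  expect_equal(as.data.frame(read_annotations(fy, "yolo_txt")),
               as.data.frame(ann), tolerance = 1e-6)
  fx <- withr::local_tempfile(fileext = ".xml")
  write_annotations(ann, fx, "voc_xml", image_size = c(1840, 1800))
  expect_equal(as.data.frame(read_annotations(fx, "voc_xml")),
               as.data.frame(ann), tolerance = 1e-5)
  # empty list -> empty file -> empty read
  write_annotations(ann[0, ], fy, "yolo_txt")
  expect_equal(nrow(read_annotations(fy, "yolo_txt")), 0L)
  # invalid box rejected before write
  bad <- ann; bad$w[1] <- 0
  expect_error(write_annotations(bad, fy, "yolo_txt"), "sizes")
})

test_that("dataset splits use largest-remainder sizes and are deterministic partitions", {
  sp <- split_dataset(seq_len(1000), c(7, 2, 1), rng_seed = 3)
  expect_equal(lengths(sp), c(train = 700L, test = 200L, val = 100L))
  sp10 <- split_dataset(seq_len(10), c(7, 2, 1), rng_seed = 3)
  expect_equal(lengths(sp10), c(train = 7L, test = 2L, val = 1L))
  # disjoint cover
  expect_setequal(unlist(sp10), seq_len(10))
  expect_equal(anyDuplicated(unlist(sp10)), 0L)
  # determinism
  expect_identical(split_dataset(letters, c(7, 2, 1), rng_seed = 9),
                   split_dataset(letters, c(7, 2, 1), rng_seed = 9))
  # empty input -> empty splits, no error
  sp0 <- split_dataset(character(0))
  expect_equal(lengths(sp0), c(train = 0L, test = 0L, val = 0L))
  expect_error(split_dataset(1:5, c(1, -1, 1)), "positive")
})

test_that("dataset config YAML round-trips", {
  cfg <- dataset_config(ratios = c(7, 2, 1))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_dataset_config(cfg, f)
  back <- read_dataset_config(f)
  expect_equal(back$names, c("SROOT", "LROOT"))
  expect_equal(back$ratios, c(0.7, 0.2, 0.1))
  expect_equal(back$train, cfg$train)
})
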