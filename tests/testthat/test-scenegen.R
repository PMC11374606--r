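# Synthetic scene generation: labeling rule, annotation soundness,
# determinism, burial behaviour.

test_that("root class rule: shorter than seed is SROOT, longer LROOT, tie SROOT", {
  expect_equal(label_root_class(10, 40), 0L)
  expect_equal(label_root_class(80, 40), 1L)
  expect_equal(label_root_class(40, 40), 0L)
  expect_equal(label_root_class(c(10, 80, 40), c(40, 40, 40)), c(0L, 1L, 0L))
  expect_error(label_root_class(0, 40), "positive")
  expect_error(label_root_class(10, -1), "positive")
})

test_that("germination fraction drives the annotation count", {
  s1 <- generate_scene(scene_params(germination_fraction = 1,
                                    burial_probability = 0, rng_seed = 1))
  expect_equal(nrow(s1$annotations), 49L)
  s0 <- generate_scene(scene_params(germination_fraction = 0, rng_seed = 1))
  expect_equal(nrow(s0$annotations), 0L)
  expect_equal(sum(s0$seeds$germinated), 0L)
})

test_that("scenes are bit-identical for the same seed and differ across seeds", {
  a <- generate_scene(scene_params(rng_seed = 11))
  b <- generate_scene(scene_params(rng_seed = 11))
  expect_identical(a$image, b$image)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
  c <- generate_scene(scene_params(rng_seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("annotation classes equal the labeling rule applied to stored truth", {
  for (seed in c(3, 4)) {
    s <- generate_scene(scene_params(germination_fraction = 0.7, rng_seed = seed))
    germ <- s$seeds[s$seeds$germinated, ]
    expect_equal(nrow(s$annotations), nrow(germ))
    expect_equal(s$annotations$class_id,
                 label_root_class(germ$root_length, germ$seed_length))
    # every box inside the unit square
    ann <- s$annotations
    expect_true(all(ann$cx - ann$w / 2 >= -1e-9))
    expect_true(all(ann$cy + ann$h / 2 <= 1 + 1e-9))
  }
})

test_that("fully buried scenes still annotate, with class from true length", {
  p <- scene_params(germination_fraction = 1, burial_probability = 1,
                    root_length_ratio_range = c(1.5, 2.5), rng_seed = 5)
  s <- generate_scene(p)
  expect_equal(nrow(s$annotations), 49L)
  expect_true(all(s$seeds$buried[s$seeds$germinated]))
  # class comes from the true (partly hidden) root length: all roots are
  # longer than the seed here, so all labels are LROOT even though only a
  # fraction of each root is visible
  expect_true(all(s$annotations$class_id == 1L))
  # boxes cover the seed plus visible root only: never wider than seed+root
  germ <- s$seeds[s$seeds$germinated, ]
  W <- p$image_size[2]
  max_extent <- (germ$seed_length + germ$root_length + 6) / W
  expect_true(all(s$annotations$w <= max_extent + 1e-9))
})

test_that("a grid too dense for the image errors out", {
  expect_error(scene_params(image_size = 64, grid = 7, jitter = 6,
                            seed_length_range = c(20, 26)), "dense")
})

test_that("generate_dataset writes images, labels, config and a reproducible manifest", {
  out1 <- withr::local_tempdir()
  p <- scene_params(image_size = 96, grid = 3, jitter = 2, rng_seed = 2)
  man <- generate_dataset(6, p, out1, split = c(7, 2, 1))
  expect_equal(man$n_images, 6)
  imgs <- list.files(file.path(out1, "images"), recursive = TRUE)
  labs <- list.files(file.path(out1, "labels"), recursive = TRUE)
  expect_equal(length(imgs), 6L)
  expect_equal(length(labs), 6L)
  expect_true(file.exists(file.path(out1, "dataset.yaml")))
  # regenerate: identical images and labels
  out2 <- withr::local_tempdir()
  generate_dataset(6, p, out2, split = c(7, 2, 1))
  for (f in imgs) {
    expect_identical(readBin(file.path(out1, "images", f), "raw", 1e6),
                     readBin(file.path(out2, "images", f), "raw", 1e6))
  }
  # per-image seed in the manifest regenerates that exact scene
  rec <- man$images[[3]]
  p3 <- p; p3$rng_seed <- rec$rng_seed
  s3 <- generate_scene(p3)
  disk <- read_image(rec$image)
  expect_identical(s3$image, disk)
})
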