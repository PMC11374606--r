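# Model assembly: forward contract, postprocessing, accounting conventions,
# reparameterization, checkpointing. Full-size variant accounting lives in
# the acceptance suite; these tests run width-reduced models.

test_that("forward emits per-query class scores and unit-square boxes", {
  model <- tiny_model(rng_seed = 1)
  set.seed(1)
  img <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  out <- model_forward(model, img)
  expect_length(out, 2)
  expect_equal(dim(out[[1]]$logits), c(12, 2))
  expect_equal(dim(out[[1]]$boxes), c(12, 4))
  expect_true(all(out[[1]]$boxes >= 0 & out[[1]]$boxes <= 1))
  # duplicated image in the batch gives identical outputs (eval mode)
  img[, , , 2] <- img[, , , 1]
  out2 <- model_forward(model, img)
  expect_equal(out2[[1]]$logits, out2[[2]]$logits)
  expect_equal(out2[[1]]$boxes, out2[[2]]$boxes)
  expect_error(model_forward(model, array(0, c(64, 64, 4, 1))), "3 channels")
  expect_error(model_forward(model, array(0, c(60, 60, 3, 1))), "divisible")
})

test_that("postprocess filters by score without ever adding detections", {
  model <- tiny_model(rng_seed = 2)
  set.seed(2)
  out <- model_forward(model, array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
  d_all <- postprocess(out, 0)
  expect_equal(nrow(d_all), 12L)
  d_top <- postprocess(out, 1.0)
  expect_equal(nrow(d_top), 0L)
  thresholds <- seq(0, 1, by = 0.1)
  counts <- vapply(thresholds, function(t) nrow(postprocess(out, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(postprocess(out, -0.1), "\\[0, 1\\]")
})

test_that("parameter and FLOP accounting follow the stated conventions", {
  # a bare conv: Cin * K^2 * Cout kernel entries
  blk <- m_cbs(3, 16, 3, bn = FALSE)
  expect_equal(germdetr:::gdm_n_params(blk), 432)
  # unit conv: 2 * 1 * 1 * (1 * 1 + 1) * 1 = 4 FLOPs
  unit <- m_cbs(1, 1, 1, bn = FALSE)
  acct <- germdetr:::gdm_acct(unit, 1, 1)
  expect_equal(acct$rows$flops, 4)
  # layer table totals equal the walked model totals
  model <- tiny_model(rng_seed = 3)
  lc <- layer_counts(model, 64)
  expect_equal(sum(lc$params), count_params(model))
  expect_equal(sum(lc$flops), count_flops(model, 64))
  # FLOPs scale with input size, params do not
  expect_gt(count_flops(model, 128), count_flops(model, 64))
  expect_equal(sum(layer_counts(model, 128)$params), count_params(model))
})

test_that("reparameterization preserves outputs, drops parameters, idempotent", {
  model <- tiny_model(rng_seed = 4)
  set.seed(4)
  imgs <- lapply(1:3, function(i) array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
  outs <- lapply(imgs, function(im) model_forward(model, im))
  dep <- reparameterize_model(model)
  expect_lt(count_params(dep), count_params(model))
  drift <- 0
  for (i in 1:3) {
    o <- model_forward(dep, imgs[[i]])
    drift <- max(drift, max(abs(o[[1]]$logits - outs[[i]][[1]]$logits)),
                 max(abs(o[[1]]$boxes - outs[[i]][[1]]$boxes)))
  }
  expect_lt(drift, 1e-3)
  expect_warning(dep2 <- reparameterize_model(dep), "already")
  expect_equal(count_params(dep2), count_params(dep))
})

test_that("train-form OREPA variants carry more parameters than squeezed/GIoU-free ones", {
  spec_tr <- model_spec(variant = "soilcuc", image_size = 64, n_queries = 12,
                        dec_layers = 1, scale = 0.125, rng_seed = 5)
  m_tr <- build_model(spec_tr)
  m_dep <- reparameterize_model(build_model(spec_tr))
  expect_gt(count_params(m_tr), count_params(m_dep))
  # the plain-GELAN variant is lighter than the train-form OREPA variant
  spec_g <- model_spec(variant = "adown_gelan", image_size = 64, n_queries = 12,
                       dec_layers = 1, scale = 0.125, rng_seed = 5)
  expect_lt(count_params(build_model(spec_g)), count_params(m_tr))
})

test_that("checkpoints restore bit-identical weights and outputs", {
  model <- tiny_model(rng_seed = 6)
  set.seed(6)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  # perturb a BN running stat so state round-trip is exercised too
  model$backbone$stem$children$l1$state$running_mean[] <- 0.123
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  p1 <- model_parameters(model); p2 <- model_parameters(back)
  expect_identical(names(p1), names(p2))
  for (nm in names(p1)) expect_identical(p1[[nm]]$value, p2[[nm]]$value)
  expect_identical(back$backbone$stem$children$l1$state$running_mean[1], 0.123)
  o1 <- model_forward(model, img); o2 <- model_forward(back, img)
  expect_identical(o1[[1]]$logits, o2[[1]]$logits)
})

test_that("unknown variants and bad sizes are rejected", {
  expect_error(model_spec(variant = "resnet50"), "arg")
  expect_error(model_spec(image_size = 100), "divisible")
})
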