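# Training: AdamW on the autodiff graph, Hungarian-matched set-prediction
# loss with deep supervision (every decoder layer plus the encoder
# proposals), online augmentation on the training split, and a desk-scale
# smoke mode on easy synthetic scenes.

#' Training configuration
#'
#' Defaults mirror the reference training recipe: 100 epochs, batch size 4,
#' 640 x 640 inputs, box-loss gain 0.5, 4 workers, no caching. The R
#' implementation runs single-process regardless of `workers` (kept for
#' config compatibility and logging).
#'
#' @param epochs,batch_size,image_size,workers,cache As in the recipe above.
#' @param box_gain Box-loss gain (the `lambda_box` of [nwd_params()]).
#' @param lr,weight_decay AdamW settings.
#' @param rng_seed Seed controlling shuffling, augmentation and init.
#' @param smoke If `TRUE`, presets for a tiny synthetic run.
#' @param augment An [augment_config()] or `NULL` to disable.
#' @param objective An [nwd_params()]; \code{r = 0} recovers the GIoU-only
#'   baseline objective.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 4, image_size = 640,
                         box_gain = 0.5, workers = 4, cache = FALSE,
                         lr = 1e-4, weight_decay = 1e-4, rng_seed = 0L,
                         smoke = FALSE, augment = augment_config(),
                         objective = NULL) {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be positive")
  if (image_size %% 32 != 0) stop("image_size must be divisible by 32")
  if (is.null(objective)) {
    objective <- nwd_params(C = 12.8 * image_size / 640, lambda_box = box_gain)
  }
  structure(list(epochs = epochs, batch_size = batch_size,
                 image_size = image_size, box_gain = box_gain,
                 workers = workers, cache = cache, lr = lr,
                 weight_decay = weight_decay, rng_seed = as.integer(rng_seed),
                 smoke = smoke, augment = augment, objective = objective),
            class = "train_config")
}

# ---- AdamW ----

adamw_state <- function(params) {
  list(step = 0,
       m = lapply(params, function(p) array(0, dim = dim(p$value))),
       v = lapply(params, function(p) array(0, dim = dim(p$value))))
}

adamw_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$step <- state$step + 1
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    upd <- (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    p$value <- p$value - lr * (upd + weight_decay * p$value)
  }
  state
}

# ---- tensor-graph loss ----

gd_bce_logits <- function(z, y) {
  # numerically stable binary cross-entropy with logits, mean over entries
  t <- gd_sub(gd_pmax(z, 0), gd_mul(z, gd_tensor(y)))
  t <- gd_add(t, gd_log(gd_add(gd_exp(gd_neg(gd_abs(z))), 1)))
  gd_mean(t)
}

# loss for one prediction set (logits, boxes gd tensors) against targets
loss_prediction_set <- function(logits, boxes, targets, params) {
  nq <- nrow(logits$value)
  nc <- ncol(logits$value)
  y <- matrix(0, nq, nc)
  nt <- nrow(targets)
  terms <- list()
  if (nt > 0) {
    preds <- list(boxes = boxes$value, probs = stats::plogis(logits$value))
    matches <- hungarian_match(preds, targets, params)
    # IoU-aware classification target: a matched query's positive target is
    # its current IoU with the assigned object, so the confidence learns to
    # rank localization quality
    tgt_iou <- pmax(0.05, iou(preds$boxes[matches$query, , drop = FALSE],
                              as_box_matrix(targets)[matches$target, , drop = FALSE]))
    y[cbind(matches$query, as.integer(targets$class_id[matches$target]) + 1L)] <- tgt_iou
    pb <- gd_take_rows(boxes, matches$query)
    tb <- gd_tensor(as_box_matrix(targets)[matches$target, , drop = FALSE])
    l1 <- gd_mul(gd_mean(gd_abs(gd_sub(pb, tb))), 4)  # mean per-box L1
    w <- gd_nwd(pb, tb, C = params$C, squared_exponent = params$squared_exponent)
    g <- gd_giou(pb, tb)
    box <- gd_add(gd_mul(gd_mean(gd_sub(1, w)), params$r),
                  gd_mul(gd_mean(gd_sub(1, g)), 1 - params$r))
    terms$l1 <- gd_mul(l1, params$lambda_l1)
    terms$box <- gd_mul(box, params$lambda_box)
  }
  terms$cls <- gd_mul(gd_bce_logits(logits, y), params$lambda_cls * nc)
  terms
}

# dense auxiliary loss on the encoder proposals: every query whose predicted
# box overlaps a target at IoU >= 0.3 is a positive for that target (target
# value = its IoU), all others are background; box terms on the positives.
# The proposal head sees many positives per image, which makes query
# selection usable after very few updates; the decoder itself stays purely
# set-predictive (Hungarian one-to-one).
loss_dense_enc <- function(logits, boxes, targets, params) {
  nq <- nrow(logits$value)
  nc <- ncol(logits$value)
  y <- matrix(0, nq, nc)
  terms <- list()
  nt <- nrow(targets)
  if (nt > 0) {
    tb_all <- as_box_matrix(targets)
    iou_m <- vapply(seq_len(nt), function(j) {
      iou(boxes$value, matrix(tb_all[j, ], nq, 4, byrow = TRUE))
    }, numeric(nq))
    best_gt <- max.col(iou_m, ties.method = "first")
    best_iou <- iou_m[cbind(seq_len(nq), best_gt)]
    pos <- which(best_iou >= 0.3)
    if (length(pos) > 0) {
      y[cbind(pos, as.integer(targets$class_id[best_gt[pos]]) + 1L)] <-
        best_iou[pos]
      pb <- gd_take_rows(boxes, pos)
      tb <- gd_tensor(tb_all[best_gt[pos], , drop = FALSE])
      w <- gd_nwd(pb, tb, C = params$C, squared_exponent = params$squared_exponent)
      g <- gd_giou(pb, tb)
      box <- gd_add(gd_mul(gd_mean(gd_sub(1, w)), params$r),
                    gd_mul(gd_mean(gd_sub(1, g)), 1 - params$r))
      terms$l1 <- gd_mul(gd_mul(gd_mean(gd_abs(gd_sub(pb, tb))), 4),
                         params$lambda_l1)
      terms$box <- gd_mul(box, params$lambda_box)
    }
  }
  terms$cls <- gd_mul(gd_bce_logits(logits, y), params$lambda_cls * nc)
  terms
}

batch_loss <- function(raw_outputs, target_list, params) {
  total <- NULL
  parts <- c(cls = 0, l1 = 0, box = 0)
  add_terms <- function(terms) {
    for (nm in names(terms)) {
      total <<- if (is.null(total)) terms[[nm]] else gd_add(total, terms[[nm]])
      parts[nm] <<- parts[nm] + as.vector(terms[[nm]]$value)
    }
  }
  for (n in seq_along(raw_outputs)) {
    img <- raw_outputs[[n]]
    for (s in img$layers) {
      add_terms(loss_prediction_set(s$logits, s$boxes, target_list[[n]], params))
    }
    add_terms(loss_dense_enc(img$enc$logits, img$enc$boxes,
                             target_list[[n]], params))
  }
  scale <- 1 / length(raw_outputs)
  list(total = gd_mul(total, scale), parts = parts * scale)
}

# stack a list of (H, W, 3) images into (H, W, 3, N) in [0, 1]
stack_images <- function(images) {
  arr <- array(0, dim = c(dim(images[[1]])[1:2], 3, length(images)))
  for (i in seq_along(images)) arr[, , , i] <- images[[i]] / 255
  arr
}

#' Train a detector
#'
#' From-scratch training (no pretrained weights) on in-memory samples.
#' Deterministic for a fixed `cfg$rng_seed`. Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model A `germ_model` (train form).
#' @param samples List of samples, each a list with `image` (8-bit (H, W, 3)
#'   array) and `annotations` (normalized cxcywh tibble); e.g. from
#'   [generate_scene()] or [load_split()].
#' @param cfg A [train_config()].
#' @param log_csv Optional path for a per-epoch metrics CSV.
#' @return List: the trained `model`, `history` tibble (per-epoch mean loss
#'   and components), `config`.
#' @export
train <- function(model, samples, cfg = train_config(), log_csv = NULL) {
  stopifnot(length(samples) >= 1)
  params <- model_parameters(model)
  opt <- adamw_state(params)
  history <- list()
  set.seed(cfg$rng_seed)
  pipeline <- if (!is.null(cfg$augment)) build_augment_pipeline(cfg$augment)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(samples))
    ep_parts <- c(cls = 0, l1 = 0, box = 0)
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      imgs <- lapply(samples[idx], function(s) {
        if (is.null(pipeline)) s$image else {
          apply_augment(pipeline, s$image)$image
        }
      })
      tgts <- lapply(samples[idx], function(s) s$annotations)
      raw <- model_forward(model, stack_images(imgs), training = TRUE)
      loss <- batch_loss(raw, tgts, cfg$objective)
      lv <- as.vector(loss$total$value)
      if (!is.finite(lv)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (components: ", paste(sprintf("%s=%.3g", names(loss$parts),
                                             loss$parts), collapse = ", "), ")")
      }
      gd_zero_grad(params)
      gd_backward(loss$total)
      opt <- adamw_step(params, opt, lr = cfg$lr,
                        weight_decay = cfg$weight_decay)
      ep_loss <- ep_loss + lv
      ep_parts <- ep_parts + loss$parts
      nb <- nb + 1
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss / nb,
                                       cls = ep_parts["cls"] / nb,
                                       l1 = ep_parts["l1"] / nb,
                                       box = ep_parts["box"] / nb)
  }
  history <- dplyr::bind_rows(history)
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  list(model = model, history = history, config = cfg)
}

#' Evaluate a model on a labelled split
#'
#' Runs the forward pass and [postprocess()] on every sample and scores the
#' detections with [mean_ap()].
#'
#' @param model A `germ_model`.
#' @param samples As in [train()].
#' @param conf_threshold Detection confidence floor fed to the evaluator
#'   (low by default so the PR curve is fully resolved).
#' @return An `eval_result` (see [mean_ap()]).
#' @export
validate <- function(model, samples, conf_threshold = 0.05) {
  if (length(samples) == 0) stop("empty validation split")
  dets <- list(); gts <- list()
  for (i in seq_along(samples)) {
    out <- model_forward(model, samples[[i]]$image / 255)
    dets[[i]] <- postprocess(out, conf_threshold, image_ids = as.character(i))
    g <- samples[[i]]$annotations
    g$image_id <- as.character(i)
    gts[[i]] <- g[, c("image_id", "class_id", "cx", "cy", "w", "h")]
  }
  mean_ap(dplyr::bind_rows(dets), dplyr::bind_rows(gts))
}

#' Load an image/label split from a generated dataset directory
#'
#' @param dataset_dir Directory written by [generate_dataset()].
#' @param split One of `"train"`, `"test"`, `"val"` (or `"all"`).
#' @return List of samples (each `image` + `annotations`).
#' @export
load_split <- function(dataset_dir, split = "train") {
  img_dir <- file.path(dataset_dir, "images", split)
  lab_dir <- file.path(dataset_dir, "labels", split)
  imgs <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  lapply(imgs, function(p) {
    lab <- file.path(lab_dir, sub("\\.png$", ".txt", basename(p)))
    list(image = read_image(p),
         annotations = read_annotations(lab, "yolo_txt"))
  })
}

#' Scene parameters for easy smoke-test scenes
#'
#' Small early-germination dishes (3 x 3 grid at 96 x 96 px): full
#' germination, radicles still shorter than the seed body (as in
#' early-stage imaging), no burial, no distractors, minimal jitter. These
#' are the easiest conditions under which a freshly initialized detector can
#' be expected to learn within a few epochs on CPU.
#'
#' @param image_size,grid,rng_seed Overridable basics.
#' @return A [scene_params()] object.
#' @export
smoke_scene_params <- function(image_size = 96, grid = 3, rng_seed = 0L) {
  scene_params(image_size = image_size, grid = grid,
               germination_fraction = 1,
               root_length_ratio_range = c(0.5, 0.9),
               n_stones = 0, n_fibers = 0, burial_probability = 0,
               jitter = 1, seed_length_range = c(11, 13.5),
               rng_seed = rng_seed)
}

#' Desk-scale smoke training run
#'
#' Generates easy synthetic scenes, trains a width-reduced model for a few
#' epochs on CPU, and evaluates on a held-out synthetic split. Intended as a
#' fast end-to-end check that the objective decreases and detections become
#' usable, not as a substitute for full-scale training.
#'
#' @param n_train,n_val Scene counts (default 50 / 12).
#' @param epochs Training epochs (default 3).
#' @param rng_seed Seed for scenes, init and shuffling.
#' @param variant Model variant to exercise.
#' @return List: `history` (per-epoch loss tibble), `eval` (an
#'   `eval_result`), `model`.
#' @export
smoke_train <- function(n_train = 50, n_val = 12, epochs = 3, rng_seed = 0L,
                        variant = "soilcuc") {
  scenes <- lapply(seq_len(n_train + n_val), function(i) {
    generate_scene(smoke_scene_params(rng_seed = rng_seed + i - 1))
  })
  samples <- lapply(scenes, function(s) {
    list(image = s$image, annotations = s$annotations)
  })
  spec <- model_spec(variant = variant, image_size = 96, n_queries = 15,
                     dec_layers = 1, scale = 0.125, rng_seed = rng_seed)
  model <- build_model(spec)
  cfg <- train_config(epochs = epochs, batch_size = 1, image_size = 96,
                      lr = 1e-2, weight_decay = 0, rng_seed = rng_seed,
                      smoke = TRUE, augment = NULL)
  fit <- train(model, samples[seq_len(n_train)], cfg)
  ev <- validate(fit$model, samples[(n_train + 1):(n_train + n_val)])
  list(history = fit$history, eval = ev, model = fit$model)
}
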