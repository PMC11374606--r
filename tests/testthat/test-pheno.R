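# Germination-vigor statistics and the detections-to-series aggregation.

test_that("germination rate follows 100 * N_t / N with validation", {
  expect_equal(germination_rate(0, 49), 0)
  expect_equal(germination_rate(49, 49), 100)
  expect_equal(germination_rate(24, 49), 2400 / 49)
  expect_equal(round(germination_rate(24, 49), 2), 48.98)
  expect_error(germination_rate(5, 0), "positive")
  expect_error(germination_rate(50, 49), "\\[0, N\\]")
})

test_that("germination index is the day-weighted sum of new germinations", {
  expect_equal(germination_index(data.frame(day = 1, newly_germinated = 1)), 1)
  expect_equal(germination_index(data.frame(day = c(1, 2),
                                            newly_germinated = c(2, 3))), 3.5)
  expect_equal(germination_index(data.frame(day = numeric(0),
                                            newly_germinated = numeric(0))), 0)
  expect_error(germination_index(data.frame(day = 0, newly_germinated = 1)),
               "positive")
  # additive over disjoint seed subsets
  s1 <- data.frame(day = c(1, 3), newly_germinated = c(2, 1))
  s2 <- data.frame(day = c(1, 3), newly_germinated = c(1, 4))
  joint <- data.frame(day = c(1, 3), newly_germinated = c(3, 5))
  expect_equal(germination_index(joint),
               germination_index(s1) + germination_index(s2))
})

test_that("series constructor enforces monotone counts and derives G_t", {
  obs <- tibble::tibble(day = c(1, 2, 4), cumulative_germinated = c(3, 5, 5))
  s <- germination_series("d1", obs, n_seeds = 49, treatment = 30)
  expect_equal(s$observations$newly_germinated, c(3, 2, 0))
  expect_equal(germination_index(s), 3 / 1 + 2 / 2)
  expect_error(germination_series("d", tibble::tibble(
    day = c(1, 2), cumulative_germinated = c(5, 3))), "non-decreasing")
  expect_error(germination_series("d", tibble::tibble(
    day = c(2, 2), cumulative_germinated = c(1, 2))), "increasing")
  expect_error(germination_series("d", tibble::tibble(
    day = 1, cumulative_germinated = 50), n_seeds = 49), "exceeds")
  g <- glance(s)
  expect_equal(g$final_rate, 500 / 49)
  expect_equal(g$index, 4)
})

test_that("detections collapse to seeds with latching and deduplication", {
  # two detections in the same cell on day 2 count once
  det <- det_tbl("img", c(0L, 1L), cx = c(0.5, 0.52), cy = c(0.5, 0.5),
                 w = 0.1, h = 0.1, conf = c(0.9, 0.8))[, -1]
  det$day <- 2
  s <- detections_to_series(det, rows = 3, cols = 3, days = 1:3)
  expect_equal(s$observations$cumulative_germinated, c(0, 1, 1))
  # no detections at all
  s0 <- detections_to_series(det[0, ], rows = 3, cols = 3, days = 1:3)
  expect_equal(s0$observations$cumulative_germinated, c(0, 0, 0))
  # latching: a seed seen on day 1 stays germinated even with no later hits
  det1 <- det; det1$day <- 1
  s1 <- detections_to_series(det1, rows = 3, cols = 3, days = 1:3)
  expect_equal(s1$observations$cumulative_germinated, c(1, 1, 1))
  # detections outside the dish are dropped with a message
  bad <- det; bad$cx <- 1.4
  expect_message(sb <- detections_to_series(bad, rows = 3, cols = 3, days = 1:2),
                 "dropped")
  expect_equal(sum(sb$observations$cumulative_germinated), 0)
  # sub-threshold confidence is ignored
  weak <- det; weak$conf <- 0.2
  sw <- detections_to_series(weak, rows = 3, cols = 3, days = 1:2,
                             confidence_threshold = 0.5)
  expect_equal(max(sw$observations$cumulative_germinated), 0)
})

test_that("series recovery is invariant to detection order within a day", {
  set.seed(8)
  det <- det_tbl("img", sample(0:1, 6, TRUE),
                 cx = runif(6), cy = runif(6), w = 0.05, h = 0.05,
                 conf = runif(6, 0.6, 1))[, -1]
  det$day <- sample(1:3, 6, replace = TRUE)
  s1 <- detections_to_series(det, days = 1:3)
  s2 <- detections_to_series(det[sample(6), ], days = 1:3)
  expect_equal(s1$observations, s2$observations)
})

test_that("closed loop: scene truth -> perfect detections -> exact counts", {
  days <- 1:4
  params <- lapply(days, function(d) {
    scene_params(germination_fraction = 0.2 * d, burial_probability = 0,
                 jitter = 4, rng_seed = 77)
  })
  # same seed: later days re-draw the same layout with more seeds germinated
  # (germination_fraction grows); simulate perfect detections from truth
  scenes <- lapply(params, generate_scene)
  germinated_sets <- lapply(scenes, function(s) which(s$seeds$germinated))
  # enforce monotone germination across days (a seed stays germinated)
  for (d in 2:4) {
    germinated_sets[[d]] <- union(germinated_sets[[d - 1]], germinated_sets[[d]])
  }
  dets <- dplyr::bind_rows(lapply(seq_along(days), function(d) {
    s <- scenes[[1]]$seeds[germinated_sets[[d]], ]
    tibble::tibble(day = days[d], class_id = 0L,
                   cx = s$cx / 640, cy = s$cy / 640,
                   w = 0.05, h = 0.05, conf = 1)
  }))
  series <- detections_to_series(dets, rows = 7, cols = 7, days = days)
  expect_equal(series$observations$cumulative_germinated,
               vapply(germinated_sets, length, numeric(1)))
})

test_that("stress report aggregates and orders constructed treatments", {
  mk <- function(id, trt, counts) {
    germination_series(id, tibble::tibble(day = seq_along(counts),
                                          cumulative_germinated = counts),
                       n_seeds = 49, treatment = trt)
  }
  # deliberately monotone-improving fabricated treatments
  rep1 <- stress_report(list(mk("a", 150, c(1, 3, 5)),
                             mk("b", 60, c(10, 20, 30)),
                             mk("c", 0, c(20, 35, 45))))
  sm <- rep1$summary[order(rep1$summary$treatment), ]
  expect_true(all(diff(sm$final_rate) < 0))
  expect_true(all(diff(sm$index) < 0))
  # identical series aggregate identically
  rep2 <- stress_report(list(mk("a", 30, c(5, 10)), mk("b", 30, c(5, 10))))
  expect_equal(rep2$summary$final_rate[1], rep2$summary$final_rate[2])
  expect_equal(rep2$summary$index[1], rep2$summary$index[2])
  expect_warning(stress_report(list(mk("a", 0, c(1, 2)),
                                    germination_series("z", tibble::tibble(
                                      day = 1, cumulative_germinated = 1),
                                      n_seeds = 25))), "different seed totals")
  expect_error(stress_report(list()), "at least one")
})
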