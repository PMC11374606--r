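# germdetr

Detection-transformer phenotyping of seed germination in substrate-soil
images.

Scoring germination trials by hand is slow and error-prone, and it gets
worse in soil: the emerging radicle is a thin, low-contrast target a few
pixels wide that can burrow under the substrate and re-emerge elsewhere,
among stones colored like seed coats and fibers shaped like roots.
`germdetr` is for researchers running dish-based germination assays (e.g.
salt-stress screening of cucumber varieties) who want an automated,
reproducible readout: detect every germinated seed in top-down dish images,
classify its radicle stage, and turn time-stamped detections into
germination-vigor statistics.

## What is inside

* **A lightweight real-time detection transformer** (pure R + Rcpp,
  including its own reverse-mode autodiff): ResNet-18-derived baseline and
  lightweight variants built from ADown downsampling, GELAN
  (`RepNCSPELAN4`) stages, and OREPA — online re-parameterizable
  convolutions whose multi-branch training form squeezes exactly into a
  single conv for deployment (`orepa_squeeze()`,
  `reparameterize_model()`). Set prediction end to end: no non-maximum
  suppression anywhere.
* **The NWD + GIoU objective.** Boxes are embedded as 2-D Gaussians; the
  normalized Wasserstein similarity `NWD = exp(-W2/C)` stays informative
  for tiny boxes where IoU collapses. The box loss is
  `r·(1 − NWD) + (1 − r)·(1 − GIoU)` inside Hungarian matching and the
  loss (`nwd()`, `giou()`, `hungarian_match()`, `total_loss()`).
* **Annotation classes.** A radicle shorter than its seed body is `SROOT`,
  longer is `LROOT` (`label_root_class()`).
* **A deterministic synthetic scene generator** standing in for the
  unpublished acquisition data: dark soil texture, 7 × 7 seed grids,
  partially buried radicles, stone/fiber distractors, exact ground truth
  (`generate_scene()`, `generate_dataset()`).
* **Evaluation and phenotyping**: COCO-style AP/mAP with a
  missed/false-alarm/repeated error taxonomy (`mean_ap()`,
  `error_taxonomy()`), germination rate `100·N_t/N` and germination index
  `Σ G_t/D_t` from deduplicated per-seed detections
  (`germination_rate()`, `germination_index()`,
  `detections_to_series()`, `stress_report()`).

## Worked example

```r
library(germdetr)

# a synthetic dish: 49 seeds, some germinated, exact truth
scene <- generate_scene(scene_params(germination_fraction = 0.6, rng_seed = 42))
scene
#> Synthetic seed scene 640x640: 49 seeds, 23 germinated, 23 annotations
head(scene$annotations, 3)
#> # A tibble: 3 × 6
#>    seed class_id     cx     cy      w      h
#>   <int>    <int>  <dbl>  <dbl>  <dbl>  <dbl>
#> 1     1        1 0.115  0.1000 0.135  0.100
#> 2     5        0 0.0803 0.642  0.0679 0.0517
#> 3     6        1 0.0793 0.741  0.0485 0.120
```

23 of 49 seeds germinated, so the scene carries 23 boxes (normalized
center/size), class 0 = SROOT, 1 = LROOT. `autoplot(scene)` draws the dish
with its boxes.

```r
# the full detector and its cost accounting
m <- build_model(model_spec(variant = "soilcuc"))
m
#> Germination detector, variant 'soilcuc' (train form)
#>   14,105,780 parameters (14.1 M); d_model 256, 3 decoder layers, 300 queries
count_flops(m, in_g = TRUE)
#> [1] 34.9
```

The train-form final model counts 14.1 M parameters and 34.9 GFLOPs at
640 × 640; the `baseline_r18`, `adown` and `adown_gelan` variants give
19.8 M / 56.9 G, 19.2 M and 9.1 M respectively (`layer_counts()` returns
the per-layer table behind these totals).

```r
# germination vigor from a counting series
germination_rate(17, 49)
#> [1] 34.69388
germination_index(data.frame(day = 1:3, newly_germinated = c(5, 9, 3)))
#> [1] 10.5
```

By day 3, 17 of 49 seeds germinated (34.7%); the index 5/1 + 9/2 + 3/3 =
10.5 rewards the early germinations. `detections_to_series()` produces
these series from raw detections (snapping each detection to its dish-grid
cell so a root re-emerging from the soil is never counted twice), and
`stress_report()` aggregates dishes across treatments.

A command-line interface wrapping the same functions ships at
`inst/cli/germdetr` (verbs: `generate-data`, `train`, `validate`,
`predict`, `phenotype`, `account`).

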