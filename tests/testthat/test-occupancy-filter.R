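# Shared fixtures: modest parents, half empty, in the easy regime.
filter_parents <- function(seeds, n_birds, size = 720) {
  out <- lapply(seeds, function(s)
    generate_scene(scene_spec(size, size, 0.5, n_birds[[as.character(s)]],
                              sea_state = 0.2, seed = s)))
  names(out) <- as.character(seeds)
  out
}

shared_filter_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      seeds <- 1:8
      nb <- stats::setNames(ifelse(seeds %% 2 == 0, 0, 4), seeds)
      scns <- filter_parents(seeds, nb)
      cfg <- load_config()
      fts <- skyfilter:::.filter_training_set(
        lapply(scns, `[[`, "image"), lapply(scns, `[[`, "gt_boxes"),
        cfg, n_aug = 3, seed = 11)
      model <<- train_filter(fts$patches, fts$labels, backend = "small_cnn")
    }
    model
  }
})

test_that("augmentation crops, rescales, flips and labels by box centers", {
  patch <- matrix(runif(200 * 200), 200, 200)
  # degenerate range: pure resize
  aug <- augment_patch(patch, augment_spec(crop_area_range = c(1, 1),
                                           hflip_prob = 0), seed = 1)
  expect_equal(dim(aug$patch), c(480, 480))
  expect_equal(unlist(aug$crop[c("x0", "y0", "x1", "y1")]),
               c(x0 = 0, y0 = 0, x1 = 200, y1 = 200))
  expect_false(aug$flipped)

  # output always 480x480; same seed reproduces the same crop
  for (s in 1:5) {
    a1 <- augment_patch(patch, seed = s)
    a2 <- augment_patch(patch, seed = s)
    expect_equal(dim(a1$patch), c(480, 480))
    expect_identical(a1$patch, a2$patch)
    expect_equal(a1$crop, a2$crop)
  }

  # center rule: label tracks whether a box center is inside the crop
  gt <- boxes(10, 10, 30, 30)
  lab <- augment_patch(patch, augment_spec(crop_area_range = c(1, 1)),
                       seed = 2, gt_boxes = gt)$label
  expect_equal(lab, 1L)
  far <- boxes(150, 150, 170, 170)
  a3 <- augment_patch(patch, augment_spec(crop_area_range = c(0.08, 0.12)),
                      seed = 3, gt_boxes = far)
  cx <- 160; cy <- 160
  inside <- cx >= a3$crop$x0 && cx < a3$crop$x1 &&
            cy >= a3$crop$y0 && cy < a3$crop$y1
  expect_equal(a3$label, as.integer(inside))

  expect_error(augment_spec(crop_area_range = c(0, 1.5)),
               class = "skyfilter_invalid_argument")
  expect_error(augment_patch(matrix(0, 16, 16)),
               class = "skyfilter_invalid_argument")
})

test_that("heuristic backend needs no training and scores by proposals", {
  hm <- train_filter(NULL, backend = "proposal_heuristic")
  expect_s3_class(hm, "filter_model")
  water <- generate_scene(scene_spec(512, 512, 0.5, 0, sea_state = 0.2,
                                     seed = 21))
  expect_equal(predict_patch(hm, water$image), 0)
  occ <- generate_scene(scene_spec(512, 512, 0.5, 3, sea_state = 0.2,
                                   seed = 22))
  expect_gte(predict_patch(hm, occ$image), 0.5)
})

test_that("the small_cnn filter separates occupied from empty patches", {
  model <- shared_filter_model()
  # held-out patches
  seeds <- 101:110
  nb <- stats::setNames(ifelse(seeds %% 2 == 0, 0, 3), seeds)
  held <- filter_parents(seeds, nb)
  probs <- vapply(held, function(s) predict_patch(model, s$image),
                  numeric(1))
  truth <- vapply(held, function(s) nrow(s$gt_boxes) > 0, logical(1))
  acc <- mean((probs > 0.5) == truth)
  expect_gte(acc, 0.95)
  expect_true(all(probs >= 0 & probs <= 1))

  # training is deterministic: same data -> identical predictions
  cfg <- load_config()
  scns <- filter_parents(31:34, stats::setNames(c(2, 0, 2, 0), 31:34))
  fts <- skyfilter:::.filter_training_set(
    lapply(scns, `[[`, "image"), lapply(scns, `[[`, "gt_boxes"),
    cfg, n_aug = 2, seed = 5)
  # tiny fixture on purpose; glmnet warns about the small class counts
  m1 <- suppressWarnings(train_filter(fts$patches, fts$labels))
  m2 <- suppressWarnings(train_filter(fts$patches, fts$labels))
  expect_identical(
    vapply(held[1:3], function(s) predict_patch(m1, s$image), numeric(1)),
    vapply(held[1:3], function(s) predict_patch(m2, s$image), numeric(1)))

  expect_error(train_filter(fts$patches, rep(1, length(fts$patches))),
               class = "skyfilter_single_class_error")
})

test_that("filter_images partitions parents and respects the threshold", {
  model <- shared_filter_model()
  seeds <- 201:210
  nb <- stats::setNames(ifelse(seeds %% 2 == 0, 0, 3), seeds)
  parents <- filter_parents(seeds, nb)
  imgs <- lapply(parents, `[[`, "image")
  res <- filter_images(model, imgs, threshold = 0.5)
  # partition contract
  expect_setequal(c(res$kept, res$dropped), names(imgs))
  expect_length(intersect(res$kept, res$dropped), 0)
  expect_equal(nrow(res$probs), length(imgs))
  # oracle-easy regime: exactly the occupied parents kept
  truth <- names(imgs)[vapply(parents, function(s) nrow(s$gt_boxes) > 0,
                              logical(1))]
  expect_setequal(res$kept, truth)

  # near-zero threshold keeps everything with nonzero probability
  res0 <- filter_images(model, imgs, threshold = 1e-6)
  expect_setequal(res0$kept,
                  res$probs$image_id[res$probs$p_occurrence > 1e-6])
})

test_that("max-probability thresholding equals the any-patch OR rule", {
  model <- shared_filter_model()
  scn <- generate_scene(scene_spec(1600, 1600, 0.5, 4, sea_state = 0.2,
                                   seed = 61))
  cfg <- load_config()
  tl <- cfg$tiling$eval
  grid <- plan_tiles(ncol(scn$image), nrow(scn$image), tl$window, tl$stride)
  patch_probs <- vapply(seq_len(nrow(grid$tiles)), function(i)
    predict_patch(model, extract_patch(scn$image, grid$tiles[i, ],
                                       rescale_to = rep(tl$rescale, 2))),
    numeric(1))
  thr <- 0.5
  any_patch <- aggregate_occupancy(as.integer(patch_probs > thr))
  res <- filter_images(model, list(p = scn$image), tiling = tl,
                       threshold = thr)
  expect_equal(as.integer(res$probs$decision), any_patch)
  expect_equal(res$probs$p_occurrence, max(patch_probs))
})

test_that("the heuristic backend is at least as fast as the cnn backend", {
  model <- shared_filter_model()
  hm <- train_filter(NULL, backend = "proposal_heuristic")
  scn <- generate_scene(scene_spec(512, 512, 0.5, 2, sea_state = 0.2,
                                   seed = 71))
  t_cnn <- system.time(for (i in 1:3) predict_patch(model, scn$image))[3]
  t_heur <- system.time(for (i in 1:3) predict_patch(hm, scn$image))[3]
  expect_lte(t_heur, t_cnn * 1.5 + 0.5)
})
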