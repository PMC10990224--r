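test_that("binarize separates dark birds from bright water", {
  # constant bright image: nothing below the threshold
  expect_false(any(binarize(matrix(1, 32, 32))))

  # >= 95% of bird pixels are foreground at contrast 0.4
  sp <- scene_spec(512, 512, 0.5, 5, bird_contrast = 0.4, sea_state = 0.2,
                   glare_fraction = 0, seed = 6)
  bg <- generate_background(sp)
  scn <- place_birds(bg, sp)
  bird_mask <- scn$image != bg
  fg <- binarize(scn$image, blob_params(contrast_enhance = "stretch"))
  expect_gte(sum(fg & bird_mask) / sum(bird_mask), 0.95)
  # and the water stays clean
  expect_lt(mean(fg & !bird_mask), 1e-3)

  # polarity symmetry (with no enhancement, mirrored threshold)
  img <- matrix(runif(400), 20, 20)
  dark <- binarize(img, blob_params(intensity_threshold = 0.3,
                                    polarity = "dark_fg",
                                    contrast_enhance = "none"))
  bright <- binarize(1 - img, blob_params(intensity_threshold = 0.7,
                                          polarity = "bright_fg",
                                          contrast_enhance = "none"))
  expect_identical(dark, bright)

  expect_error(binarize(img, structure(list(intensity_threshold = 1.2,
                                            polarity = "dark_fg",
                                            contrast_enhance = "none"),
                                       class = "blob_params")),
               class = "skyfilter_invalid_argument")
})

test_that("dilation uses a square element and is extensive", {
  m <- matrix(FALSE, 40, 40)
  expect_identical(dilate_mask(m, 12), m)
  m[20, 20] <- TRUE
  expect_identical(dilate_mask(m, 0), m)
  d <- dilate_mask(m, 12)
  expect_equal(sum(d), 144)
  idx <- which(d, arr.ind = TRUE)
  expect_equal(diff(range(idx[, 1])) + 1, 12)
  expect_equal(diff(range(idx[, 2])) + 1, 12)
  # clipped at borders
  mb <- matrix(FALSE, 10, 10); mb[1, 1] <- TRUE
  expect_lt(sum(dilate_mask(mb, 12)), 144)
  # monotone: mask subset of its dilation
  set.seed(4)
  r <- matrix(runif(900) < 0.2, 30, 30)
  expect_true(all(r <= dilate_mask(r, 5)))
  expect_error(dilate_mask(m, -1), class = "skyfilter_invalid_argument")
})

test_that("connected components match a flood-fill oracle", {
  # empty mask
  expect_equal(connected_components(matrix(FALSE, 5, 5))$n, 0)

  # diagonal touch: 1 component at 8-connectivity, 2 at 4
  m <- matrix(FALSE, 8, 8); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(connected_components(m, 8)$n, 1)
  expect_equal(connected_components(m, 4)$n, 2)

  # randomized masks against the oracle
  set.seed(99)
  for (trial in 1:200) {
    mask <- matrix(runif(32 * 32) < runif(1, 0.1, 0.6), 32, 32)
    conn <- if (trial %% 2) 8 else 4
    got <- connected_components(mask, conn)
    want <- flood_fill_components(mask, conn)
    expect_equal(got$n, want$n)
    # same partition: labels agree up to renaming
    if (want$n > 0) {
      pairs <- table(got$labels[mask], want$labels[mask])
      expect_equal(sum(pairs > 0), want$n)
    }
  }
})

test_that("proposals are tight component boxes in scan order", {
  m <- matrix(FALSE, 40, 60)
  m[11:13, 21:25] <- TRUE           # 5x3 blob at x=20..24, y=10..12
  cc <- connected_components(m)
  pr <- proposals_from_components(cc$labels)
  expect_equal(unlist(pr[1, c("x0", "y0", "x1", "y1")]),
               c(x0 = 20, y0 = 10, x1 = 25, y1 = 13))
  expect_equal(pr$area, 15)

  # min_blob_px filter
  m[30, 50] <- TRUE
  cc2 <- connected_components(m)
  expect_equal(nrow(proposals_from_components(cc2$labels, 1)), 2)
  expect_equal(nrow(proposals_from_components(cc2$labels, 2)), 1)

  # deterministic (y0, x0) order
  m2 <- matrix(FALSE, 30, 30)
  m2[20:22, 2:4] <- TRUE; m2[2:4, 20:22] <- TRUE
  pr2 <- proposals_from_components(connected_components(m2)$labels)
  expect_equal(pr2$y0, c(1, 19))
})

test_that("dilation merges nearby fragments into one proposal", {
  m <- matrix(FALSE, 60, 60)
  m[30:34, 10:18] <- TRUE
  m[30:34, 24:30] <- TRUE    # 5-px gap, below the dilation factor
  d <- dilate_mask(m, 12)
  expect_equal(connected_components(d)$n, 1)
  expect_equal(connected_components(m)$n, 2)
})

test_that("HOG geometry, normalization and resize contract hold", {
  hp <- hog_params()
  expect_equal(hp$length, 7 * 7 * 4 * 9)

  scn <- easy_scene(3)
  f1 <- hog_features(scn$image, scn$gt_boxes[1, ], hp)
  expect_length(f1, 1764)
  expect_true(all(f1 >= 0 & f1 <= 1))

  # constant crop -> zero vector
  fz <- hog_features(matrix(0.7, 128, 128), boxes(10, 10, 90, 90), hp)
  expect_true(all(fz == 0))

  # feature length independent of box size
  f2 <- hog_features(scn$image, boxes(5, 5, 25, 15), hp)
  expect_length(f2, length(f1))

  expect_error(hog_params(window = c(60, 60), cell = c(8, 8)),
               class = "skyfilter_config_error")
})

test_that("SVM training, scoring and serialization behave", {
  set.seed(1)
  pos <- matrix(rnorm(60, mean = 2), 20, 3)
  neg <- matrix(rnorm(60, mean = -2), 20, 3)
  clf <- train_svm(pos, neg, cost = 1)
  sc <- svm_scores(clf, rbind(pos, neg))
  expect_true(all(sc[1:20] > 0.5) && all(sc[21:40] < 0.5))

  # round trip through serialization: identical decision values
  clf2 <- unserialize(serialize(clf, NULL))
  expect_identical(svm_scores(clf2, rbind(pos, neg)), sc)

  expect_error(train_svm(pos, NULL), class = "skyfilter_single_class_error")
})

test_that("the full detector finds birds and stays silent on open water", {
  clf <- shared_easy_classifier()

  # water-only scene: zero detections
  water <- generate_scene(scene_spec(512, 512, 0.5, 0, sea_state = 0.2,
                                     seed = 55))
  expect_equal(nrow(detect(water$image, classifier = clf)), 0)

  # easy scenes: nearly all birds recovered at IoU 0.5 (the residual miss
  # mode is two birds close enough that dilation merges their blobs)
  hits <- 0; total <- 0
  for (s in 201:204) {
    scn <- easy_scene(s, n_birds = 4, size = 640)
    d <- detect(scn$image, classifier = clf)
    M <- skyfilter:::iou_matrix(d, scn$gt_boxes)
    if (nrow(d)) hits <- hits + sum(apply(M, 2, max) >= 0.5)
    total <- total + nrow(scn$gt_boxes)
  }
  expect_gte(hits / total, 0.85)

  # determinism
  scn <- easy_scene(204)
  expect_identical(detect(scn$image, classifier = clf),
                   detect(scn$image, classifier = clf))
})

test_that("held-out proposal classification is accurate in the easy regime", {
  clf <- shared_easy_classifier()
  hp <- hog_params()
  correct <- 0; total <- 0
  for (s in 301:304) {
    scn <- hard_scene(s, n_birds = 4)
    props <- blob_proposals(scn$image)
    if (!nrow(props)) next
    feats <- t(vapply(seq_len(nrow(props)), function(i)
      hog_features(scn$image, props[i, ], hp), numeric(hp$length)))
    truth <- label_proposals(props, scn$gt_boxes)
    pred <- svm_scores(clf, feats) >= 0.5
    correct <- correct + sum(pred == truth)
    total <- total + length(truth)
  }
  expect_gte(correct / total, 0.9)
})

test_that("the SVM adds precision over keeping every proposal", {
  clf <- shared_easy_classifier()
  val <- lapply(401:404, function(s) hard_scene(s, n_birds = 4))
  gts <- lapply(val, `[[`, "gt_boxes")
  names(gts) <- as.character(seq_along(val))
  mk_dets <- function(use_classifier) {
    do.call(rbind, lapply(seq_along(val), function(i) {
      if (use_classifier) {
        d <- detect(val[[i]]$image, classifier = clf)
      } else {
        d <- blob_proposals(val[[i]]$image)[, c("x0", "y0", "x1", "y1")]
        d$score <- 0.5
      }
      if (!nrow(d)) return(NULL)
      cbind(data.frame(image_id = i), d)
    }))
  }
  with_svm <- evaluate(mk_dets(TRUE), gts)
  without <- evaluate(mk_dets(FALSE), gts)
  expect_gt(with_svm$map, without$map)
})
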