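test_that("iou matches direct area arithmetic, exhaustively on small boxes", {
  expect_equal(iou(boxes(0, 0, 10, 10), boxes(0, 0, 10, 10)), 1)
  expect_equal(iou(boxes(0, 0, 10, 10), boxes(20, 20, 30, 30)), 0)
  expect_equal(iou(boxes(0, 0, 10, 10), boxes(5, 0, 15, 10)), 50 / 150)
  expect_error(iou(boxes(0, 0, 10, 10), list(x0 = 5, y0 = 5, x1 = 5, y1 = 9)),
               class = "skyfilter_invalid_argument")

  # exhaustive small integer boxes vs the oracle
  grid <- expand.grid(ax0 = 0:2, ay0 = 0:2, aw = 1:3, ah = 1:3,
                      bx0 = 0:2, by0 = 0:2, bw = 1:3)
  for (i in seq(1, nrow(grid), by = 7)) {
    g <- grid[i, ]
    a <- boxes(g$ax0, g$ay0, g$ax0 + g$aw, g$ay0 + g$ah)
    b <- boxes(g$bx0, g$by0, g$bx0 + g$bw, g$by0 + 2)
    expect_equal(iou(a, b),
                 brute_iou(c(g$ax0, g$ay0, g$ax0 + g$aw, g$ay0 + g$ah),
                           c(g$bx0, g$by0, g$bx0 + g$bw, g$by0 + 2)))
    expect_equal(iou(a, b), iou(b, a))  # symmetry
  }
})

test_that("matching follows the one-match-per-gt greedy rule", {
  gt <- boxes(0, 0, 10, 10)
  d1 <- boxes(0, 0, 10, 10, score = 0.9)
  m <- match_detections(d1, gt, 0.5)
  expect_equal(sum(m$tp), 1)
  expect_true(all(m$gt_matched))

  # two detections on one gt: only the higher-scored is a TP
  d2 <- boxes(c(0, 1), c(0, 0), c(10, 11), c(10, 10), score = c(0.9, 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))

  # threshold semantics at IoU exactly 0.5
  half <- boxes(0, 0, 10, 5, score = 1)   # IoU vs gt = 50/100 = 0.5
  expect_equal(iou(half, gt), 0.5)
  expect_true(match_detections(half, gt, 0.5)$tp)
  expect_false(match_detections(half, gt, 0.75)$tp)
})

test_that("average precision handles the canonical rankings", {
  gt <- boxes(0, 0, 10, 10)
  tp1 <- match_detections(boxes(0, 0, 10, 10, score = 1), gt, 0.5)
  expect_equal(average_precision(tp1)$ap, 1)

  fp1 <- match_detections(boxes(50, 50, 60, 60, score = 1), gt, 0.5)
  expect_equal(average_precision(fp1)$ap, 0)

  # ranked [TP, FP]: interpolation carries precision 1 across the grid
  both <- boxes(c(0, 50), c(0, 50), c(10, 60), c(10, 60),
                score = c(0.9, 0.8))
  m <- match_detections(both, gt, 0.5)
  expect_equal(average_precision(m)$ap, 1)

  # no gt but detections -> flagged NA, never silent zero
  none <- average_precision(match_detections(both, empty_boxes(), 0.5))
  expect_true(is.na(none$ap))
  expect_false(none$defined)
})

test_that("evaluate reproduces perfect detections and the default grid", {
  gts <- list(`1` = boxes(c(0, 40), c(0, 40), c(10, 60), c(10, 60)),
              `2` = boxes(5, 5, 25, 20))
  dets <- rbind(
    data.frame(image_id = 1L, gts[["1"]], score = c(0.9, 0.8)),
    data.frame(image_id = 2L, gts[["2"]], score = 0.95))
  rep <- evaluate(dets, gts)
  expect_equal(rep$map, 1)
  expect_equal(rep$map50, 1)
  expect_equal(rep$map75, 1)
  expect_equal(rep$ar, 1)
  expect_length(rep$ap_by_iou, 10)
  expect_equal(as.numeric(names(rep$ap_by_iou))[c(1, 10)], c(0.5, 0.95))
})

test_that("AP equals independent brute-force and COCO-reference oracles", {
  set.seed(123)
  for (trial in 1:60) {
    n_img <- sample(1:3, 1)
    dets <- lapply(seq_len(n_img), function(i)
      random_box_df(sample(0:20, 1)))
    gts <- lapply(seq_len(n_img), function(i)
      random_box_df(sample(1:10, 1), scored = FALSE))
    names(dets) <- names(gts) <- as.character(seq_len(n_img))
    det_df <- do.call(rbind, lapply(names(dets), function(id)
      if (nrow(dets[[id]]))
        cbind(data.frame(image_id = id), dets[[id]]) else NULL))
    if (is.null(det_df))
      det_df <- cbind(data.frame(image_id = character()),
                      empty_boxes(score = TRUE))
    for (thr in sample(seq(0.5, 0.95, 0.05), 2)) {
      rep <- evaluate(det_df, gts, iou_grid = thr)
      oracle <- brute_ap_sweep(lapply(dets, box_df_to_mat),
                               lapply(gts, box_df_to_mat), thr)
      expect_equal(unname(rep$ap_by_iou[1]), oracle$ap, tolerance = 1e-9)
      coco <- coco_reference_ap(lapply(dets, box_df_to_mat),
                                lapply(gts, box_df_to_mat), thr)
      expect_lt(abs(unname(rep$ap_by_iou[1]) - coco), 0.01)
    }
  }
})

test_that("AP is non-increasing in the IoU threshold and mAP is their mean", {
  set.seed(9)
  for (trial in 1:10) {
    dets <- random_box_df(15)
    gts <- random_box_df(8, scored = FALSE)
    det_df <- cbind(data.frame(image_id = 1L), dets)
    rep <- evaluate(det_df, list(`1` = gts))
    expect_true(all(diff(rep$ap_by_iou) <= 1e-12))
    expect_equal(rep$map, mean(rep$ap_by_iou))
    # interpolated precision non-increasing along the recall grid
    m <- match_detections(dets, gts, 0.5)
    pc <- average_precision(m)
    expect_true(all(diff(pc$precision) <= 1e-12))
    expect_true(all(pc$precision >= 0 & pc$precision <= 1))
  }
})

test_that("image-level metrics follow the confusion-matrix formulas", {
  ids <- as.character(1:4)
  perfect <- image_level_metrics(stats::setNames(c(1, 1, 0, 0), ids),
                                 stats::setNames(c(1, 1, 0, 0), ids))
  expect_equal(unlist(perfect[c("recall", "precision", "accuracy")]),
               c(recall = 1, precision = 1, accuracy = 1))

  half <- image_level_metrics(stats::setNames(c(1, 0, 1, 0), ids),
                              stats::setNames(c(1, 1, 0, 0), ids))
  expect_equal(unlist(half[c("recall", "precision", "accuracy")]),
               c(recall = 0.5, precision = 0.5, accuracy = 0.5))

  # all-negative predictions: recall 0, precision undefined
  allneg <- image_level_metrics(stats::setNames(c(0, 0, 0, 0), ids),
                                stats::setNames(c(1, 1, 0, 0), ids))
  expect_equal(allneg$recall, 0)
  expect_true(is.na(allneg$precision))

  expect_error(
    image_level_metrics(stats::setNames(1, "a"), stats::setNames(1, "b")),
    class = "skyfilter_invalid_argument")
})

test_that("GSD stratification puts the bin edges in the middle stratum", {
  expect_equal(as.character(gsd_bin(c(0.3, 0.8, 1.5))),
               c("fine", "medium", "coarse"))
  expect_equal(as.character(gsd_bin(c(0.6, 1.2))), c("medium", "medium"))

  # membership matches a direct comparison oracle
  set.seed(31)
  g <- runif(100, 0.05, 2)
  got <- as.character(gsd_bin(g))
  want <- ifelse(g < 0.6, "fine", ifelse(g > 1.2, "coarse", "medium"))
  expect_equal(got, want)

  # one image per bin; empty bins report, not error
  gts <- list(`1` = boxes(0, 0, 10, 10), `2` = boxes(0, 0, 10, 10),
              `3` = boxes(0, 0, 10, 10))
  dets <- do.call(rbind, lapply(1:3, function(i)
    data.frame(image_id = i, gts[[i]], score = 0.9)))
  res <- stratify_by_gsd(dets, gts, c(`1` = 0.3, `2` = 0.8, `3` = 1.5))
  expect_named(res, c("fine", "medium", "coarse"))
  expect_equal(res$fine$map, 1)
  only_fine <- stratify_by_gsd(dets, gts,
                               c(`1` = 0.1, `2` = 0.2, `3` = 0.3))
  expect_false(only_fine$coarse$defined)
  expect_error(stratify_by_gsd(dets, gts, c(`1` = 0.3, `2` = 0.8)),
               class = "skyfilter_invalid_argument")
})
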