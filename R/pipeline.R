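# End-to-end orchestration of the three-stage workflow:
# filter -> detect -> (stub) classify, with evaluation against ground truth.

# Map parent-frame annotation boxes into a tile's coordinate frame,
# keeping boxes whose center falls inside the tile (training convention:
# birds appearing in several overlapping tiles are treated as independent
# instances).
.boxes_in_tile <- function(parent_boxes, tile) {
  if (!nrow(parent_boxes)) return(empty_boxes())
  cx <- (parent_boxes$x0 + parent_boxes$x1) / 2
  cy <- (parent_boxes$y0 + parent_boxes$y1) / 2
  keep <- cx >= tile$x_off & cx < tile$x_off + tile$window_w &
          cy >= tile$y_off & cy < tile$y_off + tile$window_h
  b <- parent_boxes[keep, , drop = FALSE]
  if (!nrow(b)) return(empty_boxes())
  b$x0 <- b$x0 - tile$x_off; b$x1 <- b$x1 - tile$x_off
  b$y0 <- b$y0 - tile$y_off; b$y1 <- b$y1 - tile$y_off
  clip_boxes(b, tile$window_w, tile$window_h)
}

#' Train the blob + HOG + SVM detector from parent images
#'
#' Tiles each training parent with the training grid (default 720-pixel
#' windows, 540-pixel stride), maps annotations into each tile, and fits
#' the proposal classifier on the pooled tile proposals. Duplicated birds
#' in overlapping tiles are kept as independent training instances.
#'
#' @param images Named list of parent intensity matrices.
#' @param ann_boxes Named list of parent-frame box data frames (same
#'   names).
#' @param config A `run_config` (see [load_config()]).
#' @return A `proposal_classifier`.
#' @export
train_detector_tiled <- function(images, ann_boxes, config = load_config()) {
  tl <- config$tiling$train
  tiles_imgs <- list(); tiles_boxes <- list()
  for (id in names(images)) {
    img <- images[[id]]
    grid <- plan_tiles(ncol(img), nrow(img), tl$window, tl$stride)
    for (i in seq_len(nrow(grid$tiles))) {
      tile <- grid$tiles[i, ]
      tiles_imgs[[length(tiles_imgs) + 1L]] <- extract_patch(img, tile)
      tiles_boxes[[length(tiles_boxes) + 1L]] <-
        .boxes_in_tile(ann_boxes[[id]] %||% empty_boxes(), tile)
    }
  }
  train_blob_detector(tiles_imgs, tiles_boxes,
                      blob = do.call(blob_params, config$blob),
                      hog = do.call(hog_params, config$hog),
                      cost = config$detect$svm_cost)
}

#' Detect birds on one parent frame via the evaluation tiling
#'
#' Tiles the parent with the evaluation grid (1440/1080 rescaled to 960 by
#' default), runs the detector per patch, maps detections back to parent
#' coordinates and removes cross-tile duplicates with NMS.
#'
#' @param image Parent intensity matrix.
#' @param classifier A `proposal_classifier`.
#' @param config A `run_config`.
#' @return Parent-frame detection data frame.
#' @export
detect_parent <- function(image, classifier, config = load_config()) {
  tl <- config$tiling$eval
  grid <- plan_tiles(ncol(image), nrow(image), tl$window, tl$stride)
  rescale <- rep_len(tl$rescale, 2)
  per_tile <- lapply(seq_len(nrow(grid$tiles)), function(i) {
    tile <- grid$tiles[i, ]
    patch <- extract_patch(image, tile, rescale_to = rescale)
    dets <- detect(patch, blob = do.call(blob_params, config$blob),
                   hog = do.call(hog_params, config$hog),
                   classifier = classifier,
                   score_threshold = config$detect$score_threshold)
    list(tile = tile, dets = dets)
  })
  merge_detections(per_tile, nms_iou = config$nms$iou,
                   rescale_from = rescale,
                   parent_size = c(ncol(image), nrow(image)))
}

# Build augmented filter-training patches from parent frames.
.filter_training_set <- function(images, ann_boxes, config, n_aug = 4L,
                                 seed = 1L) {
  tl <- config$tiling$train
  patches <- list(); labels <- integer()
  k <- 0L
  for (id in names(images)) {
    img <- images[[id]]
    grid <- plan_tiles(ncol(img), nrow(img), tl$window, tl$stride)
    for (i in seq_len(nrow(grid$tiles))) {
      tile <- grid$tiles[i, ]
      patch <- extract_patch(img, tile)
      tb <- .boxes_in_tile(ann_boxes[[id]] %||% empty_boxes(), tile)
      for (a in seq_len(n_aug)) {
        k <- k + 1L
        aug <- augment_patch(patch, augment_spec(),
                             seed = .derive_seed(seed, k), gt_boxes = tb)
        patches[[k]] <- aug$patch
        labels[k] <- aug$label
      }
    }
  }
  list(patches = patches, labels = labels)
}

#' Run the full three-stage workflow on a generated dataset
#'
#' Reads a dataset directory produced by [generate_dataset()], trains the
#' occupancy filter and the detector on the training split, then processes
#' every non-training parent: stage 1 filters by occupancy probability,
#' stage 2 detects birds on the kept parents only, and stage 3 attaches
#' the explicit stub label `"bird-unclassified"` to every detection (the
#' species-classification slot of the workflow is reserved but
#' intentionally unimplemented). Detections are evaluated against the
#' tight ground truth, image-level filter metrics are computed over all
#' evaluation parents, and every artifact is written under `out_dir`.
#' Parents dropped by the filter are retained in the probability table,
#' and those that contained ground truth are listed explicitly in the run
#' record, since such false-negative drops bias population estimates.
#'
#' @param config A `run_config`.
#' @param data_dir Dataset directory (manifest, images, annotation files).
#' @param out_dir Run directory to create.
#' @param annotations Which annotation file trains the models:
#'   `"tight"`, `"loose"`, or a path to a COCO JSON.
#' @param n_aug Augmented patches per training tile for the filter.
#' @return A `run_record` list with per-stage counts, seeds, paths and
#'   the evaluation reports.
#' @export
run_workflow <- function(config, data_dir, out_dir,
                         annotations = c("tight", "loose"), n_aug = 4L) {
  stage <- "setup"
  record <- list(config = unclass(config), seeds = config$seed,
                 stages = list(), paths = list())
  on_fail <- function(e, last_good) {
    stop(errorCondition(sprintf("workflow failed at stage '%s': %s (last good artifact: %s)",
                                stage, conditionMessage(e),
                                last_good %||% "none"),
                        class = c("skyfilter_stage_error", "error")))
  }
  tryCatch({
    man <- read_manifest(file.path(data_dir, "manifest.csv"))
    ann_path <- if (length(annotations) == 1 && file.exists(annotations))
      annotations
    else file.path(data_dir, sprintf("annotations_%s.json",
                                     match.arg(annotations)))
    aset <- read_coco(ann_path)
    gt <- read_coco(file.path(data_dir, "annotations_tight.json"))
    imgs <- lapply(man$file_name, function(f)
      read_image(file.path(data_dir, f)))
    names(imgs) <- as.character(man$image_id)
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    .assert(ok, "cannot create run directory", class = "skyfilter_io_error")
    dir.create(file.path(out_dir, "filter"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "detect"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "eval"), showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.lock.yaml"))
    record$paths$config <- file.path(out_dir, "config.lock.yaml")
    logf <- file.path(out_dir, "log.txt")
    logmsg <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
    cat("", file = logf)

    train_ids <- as.character(man$image_id[man$split == "train"])
    eval_ids <- as.character(man$image_id[man$split != "train"])
    .assert(length(train_ids) > 0 && length(eval_ids) > 0,
            "need both a train split and a non-train split")
    ann_of <- function(ids) {
      out <- lapply(ids, function(i)
        annotations_for_image(aset, as.integer(i)))
      names(out) <- ids
      out
    }
    gt_of <- function(ids) {
      out <- lapply(ids, function(i)
        annotations_for_image(gt, as.integer(i)))
      names(out) <- ids
      out
    }

    stage <- "train-filter"
    t0 <- proc.time()[["elapsed"]]
    fts <- .filter_training_set(imgs[train_ids], ann_of(train_ids), config,
                                n_aug = n_aug, seed = config$seed)
    fmodel <- train_filter(fts$patches, fts$labels,
                           backend = config$filter$backend)
    record$stages$train_filter <- list(n_patches = length(fts$patches),
                                       wall_s = proc.time()[["elapsed"]] - t0)
    logmsg("trained %s filter on %d patches", config$filter$backend,
           length(fts$patches))

    stage <- "train-detector"
    t0 <- proc.time()[["elapsed"]]
    classifier <- train_detector_tiled(imgs[train_ids], ann_of(train_ids),
                                       config)
    record$stages$train_detector <- list(
      wall_s = proc.time()[["elapsed"]] - t0)

    stage <- "filter"
    t0 <- proc.time()[["elapsed"]]
    flt <- filter_images(fmodel, imgs[eval_ids],
                         tiling = config$tiling$eval,
                         threshold = config$filter$threshold)
    utils::write.csv(flt$probs, file.path(out_dir, "filter", "probs.csv"),
                     row.names = FALSE, quote = FALSE)
    record$paths$filter_probs <- file.path(out_dir, "filter", "probs.csv")
    truth_occ <- stats::setNames(
      as.integer(man$n_birds[match(eval_ids, man$image_id)] > 0), eval_ids)
    fn_drops <- intersect(flt$dropped, eval_ids[truth_occ[eval_ids] == 1])
    record$stages$filter <- list(
      n_parents = length(eval_ids), n_kept = length(flt$kept),
      n_dropped = length(flt$dropped),
      false_negative_drops = fn_drops,
      wall_s = proc.time()[["elapsed"]] - t0)
    logmsg("filter kept %d / %d parents (%d occupied parents dropped)",
           length(flt$kept), length(eval_ids), length(fn_drops))

    stage <- "detect"
    t0 <- proc.time()[["elapsed"]]
    dets <- lapply(flt$kept, function(id)
      detect_parent(imgs[[id]], classifier, config))
    names(dets) <- flt$kept
    det_df <- do.call(rbind, c(list(
      cbind(data.frame(image_id = integer()), empty_boxes(score = TRUE))),
      lapply(flt$kept, function(id) {
        d <- dets[[id]]
        if (!nrow(d)) return(NULL)
        cbind(data.frame(image_id = as.integer(id)), d)
      })))
    stage <- "classify"
    det_df$label <- if (nrow(det_df)) "bird-unclassified" else character()
    write_detections(det_df, file.path(out_dir, "detect", "dets.json"))
    record$paths$detections <- file.path(out_dir, "detect", "dets.json")
    record$stages$detect <- list(
      n_parents = length(flt$kept), n_detections = nrow(det_df),
      wall_s = proc.time()[["elapsed"]] - t0)

    stage <- "evaluate"
    t0 <- proc.time()[["elapsed"]]
    rep <- evaluate(det_df, gt_of(eval_ids), iou_grid = config$eval$iou_grid)
    pred_occ <- stats::setNames(flt$probs$decision, flt$probs$image_id)
    img_metrics <- image_level_metrics(pred_occ, truth_occ)
    gsd <- stats::setNames(man$gsd_cm[match(eval_ids, man$image_id)],
                           eval_ids)
    by_gsd <- stratify_by_gsd(det_df, gt_of(eval_ids), gsd,
                              bin_edges = config$eval$gsd_bins,
                              iou_grid = config$eval$iou_grid)
    report <- list(
      instance = list(map = rep$map, map50 = rep$map50, map75 = rep$map75,
                      ar = rep$ar, ap_by_iou = as.list(rep$ap_by_iou),
                      defined = rep$defined),
      image_level = img_metrics[c("recall", "precision", "accuracy")],
      by_gsd = lapply(by_gsd, function(r)
        list(map = r$map, map50 = r$map50, map75 = r$map75, ar = r$ar,
             n_gt = r$n_gt, defined = r$defined)))
    jsonlite::write_json(report, file.path(out_dir, "eval", "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    record$paths$report <- file.path(out_dir, "eval", "report.json")
    record$stages$evaluate <- list(wall_s = proc.time()[["elapsed"]] - t0)
    record$eval <- rep
    record$image_level <- img_metrics
    record$by_gsd <- by_gsd
    record$filter <- flt
    logmsg("instance mAP %.3f mAP50 %.3f; image-level acc %.3f",
           rep$map, rep$map50, img_metrics$accuracy)
    structure(record, class = "run_record")
  }, error = function(e) on_fail(e, record$paths[[length(record$paths)]]))
}

#' @export
print.run_record <- function(x, ...) {
  cat("run_record:\n")
  cat(sprintf("  filter: %d kept / %d parents (%d occupied dropped)\n",
              x$stages$filter$n_kept, x$stages$filter$n_parents,
              length(x$stages$filter$false_negative_drops)))
  cat(sprintf("  detect: %d detections on %d parents\n",
              x$stages$detect$n_detections, x$stages$detect$n_parents))
  if (!is.null(x$eval) && x$eval$defined)
    cat(sprintf("  eval: mAP %.3f mAP50 %.3f mAP75 %.3f AR %.3f\n",
                x$eval$map, x$eval$map50, x$eval$map75, x$eval$ar))
  invisible(x)
}

#' Cross-regime validation of the detector
#'
#' Trains one detector per region (e.g. two survey areas with different
#' sea-state and glare regimes) and evaluates every trained model on every
#' region's validation images, quantifying how well a model transfers
#' across acquisition conditions.
#'
#' @param region_a,region_b Lists with named-list elements `train_images`,
#'   `train_boxes`, `val_images`, `val_boxes`.
#' @param config A `run_config`.
#' @return List with `table` (rows trained_on x eval_on, columns mAP,
#'   mAP50, mAP75, AR) and the underlying `eval_report`s.
#' @export
crossval_regions <- function(region_a, region_b, config = load_config()) {
  regions <- list(A = region_a, B = region_b)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    lab <- unlist(lapply(r$train_boxes, nrow))
    .assert(length(r$train_images) > 0 && length(r$val_images) > 0,
            sprintf("region %s needs train and val data", nm))
  }
  models <- lapply(regions, function(r)
    train_detector_tiled(r$train_images, r$train_boxes, config))
  rows <- list(); reports <- list()
  for (tr in names(regions)) for (ev in names(regions)) {
    dets <- do.call(rbind, c(list(cbind(data.frame(image_id = character()),
                                        empty_boxes(score = TRUE))),
      lapply(names(regions[[ev]]$val_images), function(id) {
        d <- detect_parent(regions[[ev]]$val_images[[id]], models[[tr]],
                           config)
        if (!nrow(d)) return(NULL)
        cbind(data.frame(image_id = id), d)
      })))
    rep <- evaluate(dets, regions[[ev]]$val_boxes,
                    iou_grid = config$eval$iou_grid)
    key <- sprintf("train_%s_eval_%s", tr, ev)
    reports[[key]] <- rep
    rows[[key]] <- data.frame(trained_on = tr, eval_on = ev,
                              mAP = rep$map, mAP50 = rep$map50,
                              mAP75 = rep$map75, AR = rep$ar)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}
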