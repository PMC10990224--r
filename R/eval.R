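#' Match detections to ground truth at one IoU threshold
#'
#' Detections are processed in descending score order (ties broken by
#' input order); each claims the not-yet-matched ground-truth box with the
#' highest IoU, provided that IoU reaches `iou_thresh` (a true positive),
#' and is otherwise a false positive. IoU ties between ground-truth boxes
#' break toward the lower index. Ground-truth boxes left unmatched are the
#' false negatives. Each ground truth is matched at most once.
#'
#' @param dets Detection box data frame with `score`.
#' @param gts Ground-truth box data frame.
#' @param iou_thresh True-positive gate in `(0, 1]`.
#' @return List with `det_order` (row indices of `dets` in rank order),
#'   `tp` (logical per ranked detection), `gt_matched` (logical per gt),
#'   `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_thresh) {
  .assert(.is_scalar_num(iou_thresh) && iou_thresh > 0 && iou_thresh <= 1,
          "iou_thresh must be in (0,1]", class = "skyfilter_invalid_argument")
  validate_boxes(dets); validate_boxes(gts)
  n_gt <- nrow(gts)
  if (!nrow(dets))
    return(list(det_order = integer(), tp = logical(),
                gt_matched = rep(FALSE, n_gt), n_gt = n_gt))
  ord <- order(-dets$score)
  tp <- logical(length(ord))
  matched <- rep(FALSE, n_gt)
  if (n_gt) {
    M <- iou_matrix(dets, gts)
    for (k in seq_along(ord)) {
      i <- ord[k]
      free <- which(!matched)
      if (!length(free)) break
      best <- free[which.max(M[i, free])]
      if (M[i, best] >= iou_thresh) {
        tp[k] <- TRUE
        matched[best] <- TRUE
      }
    }
  }
  list(det_order = ord, tp = tp, gt_matched = matched, n_gt = n_gt)
}

#' Average precision from ranked matches
#'
#' Sweeps the ranked detections, accumulating precision/recall points,
#' interpolates precision as `p(r) = max` precision at any recall `>= r`,
#' and averages `p(r)` over the 101-point recall grid `0, 0.01, ..., 1`.
#' With no ground truth, recall is undefined and the AP is returned as a
#' flagged `NA` rather than a silent zero.
#'
#' @param matches Result of [match_detections()] (or pooled equivalent):
#'   needs `tp` in rank order and `n_gt`.
#' @param n_gt Number of ground-truth boxes (defaults to `matches$n_gt`).
#' @return List with `ap`, `recall_grid`, `precision` (interpolated over
#'   the grid), `raw` (data frame of the ranked sweep), `final_recall`,
#'   and `defined` (FALSE when `n_gt == 0`).
#' @export
average_precision <- function(matches, n_gt = matches$n_gt) {
  tp <- matches$tp
  grid <- seq(0, 1, by = 0.01)
  if (n_gt == 0) {
    return(list(ap = NA_real_, recall_grid = grid,
                precision = rep(NA_real_, length(grid)),
                raw = data.frame(recall = numeric(), precision = numeric()),
                final_recall = NA_real_, defined = FALSE))
  }
  if (!length(tp)) {
    return(list(ap = 0, recall_grid = grid, precision = rep(0, length(grid)),
                raw = data.frame(recall = numeric(), precision = numeric()),
                final_recall = 0, defined = TRUE))
  }
  ctp <- cumsum(tp)
  rec <- ctp / n_gt
  prec <- ctp / seq_along(tp)
  # p(r) = max precision among sweep points with recall >= r
  interp <- vapply(grid, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  list(ap = mean(interp), recall_grid = grid, precision = interp,
       raw = data.frame(recall = rec, precision = prec),
       final_recall = rec[length(rec)], defined = TRUE)
}

# Pool matches across images at one threshold: per-image matching, then a
# single ranked list over all detections.
.pooled_matches <- function(dets_by_image, gts_by_image, iou_thresh) {
  scores <- numeric(); tps <- logical(); n_gt <- 0L
  for (id in names(dets_by_image)) {
    d <- dets_by_image[[id]]
    g <- gts_by_image[[id]] %||% empty_boxes()
    n_gt <- n_gt + nrow(g)
    m <- match_detections(d, g, iou_thresh)
    scores <- c(scores, d$score[m$det_order])
    tps <- c(tps, m$tp)
  }
  for (id in setdiff(names(gts_by_image), names(dets_by_image)))
    n_gt <- n_gt + nrow(gts_by_image[[id]])
  ord <- order(-scores)
  list(tp = tps[ord], n_gt = n_gt)
}

#' Evaluate detections against ground truth over an IoU grid
#'
#' Computes average precision at each IoU threshold of the grid (default
#' 0.50 to 0.95 in steps of 0.05) over the detections of all images pooled
#' into a single ranked list, and reports `mAP` (mean over the grid),
#' `mAP50`, `mAP75`, and `AR` (mean over the same grid of the recall
#' reached by the full ranked list). With no ground truth anywhere the
#' report is flagged undefined.
#'
#' @param dets Detection data frame with `image_id` and `score` columns.
#' @param gts An [annotation_set()], or a named list of ground-truth box
#'   data frames keyed by image id.
#' @param iou_grid Vector of IoU thresholds.
#' @return An `eval_report` list: `ap_by_iou`, `recall_by_iou`, `map`,
#'   `map50`, `map75`, `ar`, `n_images`, `n_gt`, `defined`.
#' @export
evaluate <- function(dets, gts, iou_grid = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(gts, "annotation_set")) {
    ids <- gts$images$id
    gl <- lapply(ids, function(i) annotations_for_image(gts, i))
    names(gl) <- as.character(ids)
    gts <- gl
  }
  .assert(is.list(gts), "gts must be an annotation_set or named list")
  if (is.null(dets$image_id) && nrow(dets) > 0)
    stop(errorCondition("detections need an image_id column",
                        class = c("skyfilter_invalid_argument", "error")))
  det_ids <- if (nrow(dets)) unique(dets$image_id) else integer()
  all_ids <- union(names(gts), as.character(det_ids))
  dl <- lapply(all_ids, function(id) {
    d <- dets[as.character(dets$image_id) == id, , drop = FALSE]
    d[order(-d$score), , drop = FALSE]
  })
  names(dl) <- all_ids
  n_gt <- sum(vapply(gts, nrow, integer(1)))
  ap <- rec <- stats::setNames(numeric(length(iou_grid)),
                               sprintf("%.2f", iou_grid))
  for (k in seq_along(iou_grid)) {
    pm <- .pooled_matches(dl, gts, iou_grid[k])
    res <- average_precision(pm, n_gt = pm$n_gt)
    ap[k] <- res$ap
    rec[k] <- if (pm$n_gt) sum(pm$tp) / pm$n_gt else NA_real_
  }
  structure(list(ap_by_iou = ap, recall_by_iou = rec,
                 map = mean(ap),
                 map50 = if ("0.50" %in% names(ap)) ap[["0.50"]] else NA_real_,
                 map75 = if ("0.75" %in% names(ap)) ap[["0.75"]] else NA_real_,
                 ar = mean(rec), n_images = length(all_ids), n_gt = n_gt,
                 defined = n_gt > 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (!x$defined) {
    cat("eval_report: undefined (no ground truth)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "eval_report (%d images, %d gt): mAP %.3f  mAP50 %.3f  mAP75 %.3f  AR %.3f\n",
    x$n_images, x$n_gt, x$map, x$map50, x$map75, x$ar))
  invisible(x)
}

#' Image-level recall, precision and accuracy
#'
#' Binary occupancy metrics for the stage-1 filter: `R = TP/(TP+FN)`,
#' `P = TP/(TP+FP)`, `Acc = (TP+TN)/N`. Ratios with zero denominators are
#' returned as `NA` rather than silently clamped.
#'
#' @param pred,truth Named 0/1 vectors over the same image ids.
#' @return List with `recall`, `precision`, `accuracy` and the confusion
#'   counts.
#' @export
image_level_metrics <- function(pred, truth) {
  .assert(!is.null(names(pred)) && !is.null(names(truth)),
          "pred and truth must be named by image id")
  diff <- c(setdiff(names(pred), names(truth)),
            setdiff(names(truth), names(pred)))
  .assert(length(diff) == 0,
          sprintf("image id mismatch: %s", paste(diff, collapse = ", ")),
          class = "skyfilter_invalid_argument")
  truth <- truth[names(pred)]
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       accuracy = (tp + tn) / length(pred),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' GSD bin membership
#'
#' Three resolution strata: fine (`< lo` cm), medium (`lo` to `hi`
#' inclusive at both ends) and coarse (`> hi` cm). The bin edges belong to
#' the middle stratum.
#'
#' @param gsd Numeric GSD values (cm/pixel).
#' @param bin_edges Two increasing edges, default `c(0.6, 1.2)`.
#' @return Factor with levels `fine`, `medium`, `coarse`.
#' @export
gsd_bin <- function(gsd, bin_edges = c(0.6, 1.2)) {
  .assert(all(is.finite(gsd)), "missing GSD value",
          class = "skyfilter_invalid_argument")
  out <- ifelse(gsd < bin_edges[1], "fine",
                ifelse(gsd > bin_edges[2], "coarse", "medium"))
  factor(out, levels = c("fine", "medium", "coarse"))
}

#' Evaluate detections stratified by ground sample distance
#'
#' Partitions images into the three GSD strata and runs [evaluate()]
#' within each; strata with no images yield empty (undefined) reports, not
#' errors.
#'
#' @param dets Detection data frame with `image_id`.
#' @param gts [annotation_set()] or named list of box data frames.
#' @param gsd Named numeric vector: image id -> GSD (cm). Every evaluated
#'   image must have one.
#' @param bin_edges Two increasing bin edges (cm), default `c(0.6, 1.2)`.
#' @param iou_grid IoU thresholds for [evaluate()].
#' @return Named list of `eval_report`s (`fine`, `medium`, `coarse`).
#' @export
stratify_by_gsd <- function(dets, gts, gsd, bin_edges = c(0.6, 1.2),
                            iou_grid = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(gts, "annotation_set")) {
    ids <- gts$images$id
    gl <- lapply(ids, function(i) annotations_for_image(gts, i))
    names(gl) <- as.character(ids)
    gts <- gl
  }
  ids <- union(names(gts), as.character(unique(dets$image_id)))
  missing <- setdiff(ids, names(gsd))
  .assert(length(missing) == 0,
          sprintf("images with no GSD: %s", paste(missing, collapse = ", ")),
          class = "skyfilter_invalid_argument")
  bins <- gsd_bin(as.numeric(gsd[ids]), bin_edges)
  out <- list()
  for (b in levels(bins)) {
    sub <- ids[bins == b]
    out[[b]] <- evaluate(dets[as.character(dets$image_id) %in% sub, ,
                              drop = FALSE],
                         gts[intersect(names(gts), sub)], iou_grid)
  }
  out
}

#' Summarize evaluation reports as a table
#'
#' One row per report, columns `mAP`, `mAP50`, `mAP75`, `AR` -- the layout
#' detection comparisons in this workflow are reported in.
#'
#' @param reports Named list of `eval_report`s.
#' @return Data frame.
#' @export
report_table <- function(reports) {
  data.frame(condition = names(reports),
             mAP = vapply(reports, function(r) r$map, numeric(1)),
             mAP50 = vapply(reports, function(r) r$map50, numeric(1)),
             mAP75 = vapply(reports, function(r) r$map75, numeric(1)),
             AR = vapply(reports, function(r) r$ar, numeric(1)),
             row.names = NULL)
}
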