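#' Plan a sliding-window tile grid over a parent frame
#'
#' Tile origins sit at multiples of the stride; the final origin on each
#' axis is clamped to `parent_dim - window` so the last tile abuts the
#' border and every parent pixel is covered (no padding, no dropped edges).
#' The number of tiles per axis is `ceiling((parent - window)/stride) + 1`.
#' A window larger than the parent collapses to a single clamped tile.
#'
#' @param parent_w,parent_h Parent frame size in pixels.
#' @param window Length-1 or -2 integer window size `(w, h)`.
#' @param stride Length-1 or -2 integer step size; `0 < stride <= window`.
#' @return A `tile_grid`: list with `parent_w`, `parent_h`, `window`,
#'   `stride` and `tiles`, a data frame of `x_off`, `y_off`, `window_w`,
#'   `window_h` ordered row-major (y outer, x inner).
#' @export
#' @examples
#' plan_tiles(2000, 2000, window = 1440, stride = 1080)  # 2 x 2 tiles
plan_tiles <- function(parent_w, parent_h, window, stride) {
  window <- rep_len(as.integer(window), 2)
  stride <- rep_len(as.integer(stride), 2)
  .assert(.is_count(parent_w) && .is_count(parent_h) &&
          parent_w > 0 && parent_h > 0, "parent dimensions must be positive",
          class = "skyfilter_invalid_argument")
  .assert(all(stride > 0), "stride must be positive",
          class = "skyfilter_invalid_argument")
  .assert(all(stride <= window), "stride must not exceed window",
          class = "skyfilter_invalid_argument")
  axis_origins <- function(parent, win, step) {
    if (win >= parent) return(list(orig = 0L, win = as.integer(parent)))
    k <- ceiling((parent - win) / step) + 1
    orig <- pmin((seq_len(k) - 1) * step, parent - win)
    list(orig = as.integer(orig), win = as.integer(win))
  }
  ax <- axis_origins(parent_w, window[1], stride[1])
  ay <- axis_origins(parent_h, window[2], stride[2])
  tiles <- expand.grid(x_off = ax$orig, y_off = ay$orig,
                       KEEP.OUT.ATTRS = FALSE)
  tiles <- tiles[order(tiles$y_off, tiles$x_off), , drop = FALSE]
  rownames(tiles) <- NULL
  tiles$window_w <- ax$win
  tiles$window_h <- ay$win
  structure(list(parent_w = as.integer(parent_w),
                 parent_h = as.integer(parent_h),
                 window = c(ax$win, ay$win), stride = stride,
                 tiles = tiles), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d tiles (%dx%d window, %dx%d stride) over %dx%d\n",
              nrow(x$tiles), x$window[1], x$window[2], x$stride[1],
              x$stride[2], x$parent_w, x$parent_h))
  invisible(x)
}

#' Extract (and optionally rescale) one tile from a parent image
#'
#' Pixel-exact crop of the tile rectangle; when `rescale_to` is given the
#' crop is bilinearly resized, e.g. the 1440-pixel evaluation window
#' rescaled to 960 to cut compute.
#'
#' @param image Parent intensity matrix `[y, x]`.
#' @param tile One row of a `tile_grid`'s `tiles` data frame (or any list
#'   with `x_off`, `y_off`, `window_w`, `window_h`).
#' @param rescale_to Optional `(width, height)` to resize the crop to.
#' @return Intensity matrix.
#' @export
extract_patch <- function(image, tile, rescale_to = NULL) {
  .assert(tile$x_off >= 0 && tile$y_off >= 0 &&
          tile$x_off + tile$window_w <= ncol(image) &&
          tile$y_off + tile$window_h <= nrow(image),
          "tile lies outside the image", class = "skyfilter_bounds_error")
  patch <- image[(tile$y_off + 1):(tile$y_off + tile$window_h),
                 (tile$x_off + 1):(tile$x_off + tile$window_w), drop = FALSE]
  if (!is.null(rescale_to))
    patch <- resize_image(patch, height = rescale_to[2], width = rescale_to[1])
  patch
}

#' Map a tile-frame box back to parent-frame coordinates
#'
#' Undoes any rescale (multiplying by `window / rescale_from` per axis) and
#' translates by the tile offset. Scores and labels are preserved; boxes
#' are clipped to the parent bounds and the result carries a `clipped`
#' attribute when clipping changed anything.
#'
#' @param box Box data frame in tile coordinates.
#' @param tile Tile descriptor (as in [extract_patch()]).
#' @param rescale_from Optional `(width, height)` the tile was rescaled to
#'   before the boxes were produced.
#' @param parent_size Optional `(width, height)` for clipping.
#' @return Box data frame in parent coordinates.
#' @export
patch_to_parent <- function(box, tile, rescale_from = NULL,
                            parent_size = NULL) {
  validate_boxes(box)
  sx <- sy <- 1
  if (!is.null(rescale_from)) {
    sx <- tile$window_w / rescale_from[1]
    sy <- tile$window_h / rescale_from[2]
  }
  out <- box
  out$x0 <- box$x0 * sx + tile$x_off; out$x1 <- box$x1 * sx + tile$x_off
  out$y0 <- box$y0 * sy + tile$y_off; out$y1 <- box$y1 * sy + tile$y_off
  if (!is.null(parent_size)) {
    clipped <- clip_boxes(out, parent_size[1], parent_size[2])
    attr(clipped, "clipped") <- !identical(clipped[names(out)], out)
    out <- clipped
  }
  out
}

#' Aggregate patch-level occupancy labels to a parent-image label
#'
#' A parent frame counts as occupied if any of its patches was predicted to
#' contain a bird: the logical OR of the patch labels.
#'
#' @param patch_labels Vector of 0/1 (or logical) patch predictions.
#' @return 0 or 1.
#' @export
aggregate_occupancy <- function(patch_labels) {
  .assert(length(patch_labels) > 0,
          "a parent image with no patches is malformed",
          class = "skyfilter_invalid_argument")
  .assert(all(patch_labels %in% c(0, 1)), "patch labels must be 0/1")
  as.integer(any(patch_labels == 1))
}

#' Greedy non-maximum suppression
#'
#' Sorts boxes by descending score (ties broken by ascending `x0`, then
#' `y0`, so the result is deterministic) and keeps a box iff its IoU with
#' every already-kept box is strictly below `nms_iou`.
#'
#' @param dets Box data frame with a `score` column.
#' @param nms_iou Suppression threshold in `(0, 1)`.
#' @return The kept subset, in the sorted order.
#' @export
nms <- function(dets, nms_iou = 0.5) {
  validate_boxes(dets)
  .assert(.is_scalar_num(nms_iou) && nms_iou > 0 && nms_iou < 1,
          "nms_iou must be in (0,1)", class = "skyfilter_invalid_argument")
  if (!nrow(dets)) return(dets)
  .assert(!is.null(dets$score), "nms requires scores")
  ord <- order(-dets$score, dets$x0, dets$y0)
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  kept_idx <- integer()
  for (i in seq_len(nrow(dets))) {
    if (length(kept_idx)) {
      ious <- iou_matrix(dets[i, , drop = FALSE],
                         dets[kept_idx, , drop = FALSE])
      if (max(ious) >= nms_iou) next
    }
    keep[i] <- TRUE
    kept_idx <- c(kept_idx, i)
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-tile detections into parent-frame detections
#'
#' Maps every tile's detections into parent coordinates (undoing any
#' rescale) and removes cross-tile duplicates -- the same bird detected in
#' two overlapping tiles -- with greedy NMS.
#'
#' @param per_tile_dets List of `list(tile = <tile row>, dets = <box df>)`,
#'   detections in tile coordinates.
#' @param nms_iou NMS threshold in `(0, 1)`.
#' @param rescale_from Optional `(width, height)` the tiles were rescaled
#'   to before detection.
#' @param parent_size Optional `(width, height)` for clipping.
#' @return A parent-frame detection data frame.
#' @export
merge_detections <- function(per_tile_dets, nms_iou = 0.5,
                             rescale_from = NULL, parent_size = NULL) {
  mapped <- lapply(per_tile_dets, function(td) {
    if (!nrow(td$dets)) return(NULL)
    patch_to_parent(td$dets, td$tile, rescale_from = rescale_from,
                    parent_size = parent_size)
  })
  mapped <- Filter(Negate(is.null), mapped)
  if (!length(mapped)) return(empty_boxes(score = TRUE))
  all_dets <- do.call(rbind, mapped)
  all_dets <- all_dets[box_area(all_dets) > 0, , drop = FALSE]
  if (!nrow(all_dets)) return(empty_boxes(score = TRUE))
  nms(all_dets, nms_iou)
}
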