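#' Activation map of a patch
#'
#' Weak-localization heat map used to initialize and drive the level-set
#' tightening of annotation boxes. Two backends:
#'
#' * `contrast` (default, needs no trained model): absolute deviation of
#'   each pixel from the patch's robust background level -- the median of
#'   its border pixels -- min-max normalized to `[0, 1]`. A constant patch
#'   maps to all zeros.
#' * `cam`: class-activation map from a patch classifier with a
#'   global-average-pooling head (see [train_filter()]): the classifier's
#'   spatial feature maps weighted by its class weights, bilinearly
#'   upsampled to the patch size and min-max normalized.
#'
#' @param patch Intensity matrix.
#' @param backend `"contrast"` or `"cam"`.
#' @param classifier A `filter_model` with the `small_cnn` backend;
#'   required for `backend = "cam"`.
#' @return Heat matrix in `[0, 1]`, same size as `patch`.
#' @export
activation_map <- function(patch, backend = c("contrast", "cam"),
                           classifier = NULL) {
  backend <- match.arg(backend)
  .assert(length(patch) > 0 && nrow(patch) >= 2 && ncol(patch) >= 2,
          "patch must be non-empty")
  if (backend == "cam") {
    .assert(!is.null(classifier),
            "cam backend requires a trained patch classifier",
            class = "skyfilter_config_error")
    return(cam_map(classifier, patch))
  }
  border <- c(patch[1, ], patch[nrow(patch), ],
              patch[, 1], patch[, ncol(patch)])
  bg <- stats::median(border)
  dev <- abs(patch - bg)
  mx <- max(dev)
  # deviations below the noise floor carry no localization signal; an
  # (almost) uniform water patch must map to zero heat, not amplified noise
  if (mx < 0.1) return(matrix(0, nrow(patch), ncol(patch)))
  dev / mx
}

# 3x3 binary majority smoothing (the curvature step of the morphological
# level set); pixels with >= 5 foreground neighbors (incl. self) turn on.
.majority3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(0L, h + 2, w + 2)
  m[2:(h + 1), 2:(w + 1)] <- mask
  s <- matrix(0L, h, w)
  for (dy in 0:2) for (dx in 0:2)
    s <- s + m[(1 + dy):(h + dy), (1 + dx):(w + dx)]
  s >= 5
}

.dilate3 <- function(mask) dilate_mask(mask, 3L)
.erode3 <- function(mask) !dilate_mask(!mask, 3L)

#' Two-phase morphological level-set segmentation
#'
#' Region-based (Chan-Vese-type) curve evolution implemented with
#' morphological operators, used to shrink a loose initial mask onto the
#' target supported by the heat map. Each iteration computes the mean heat
#' inside (`c1`) and outside (`c0`) the current mask, reassigns the pixels
#' of the narrow band around the front to whichever phase mean is closer
#' (the discrete descent step on the two-phase variance energy), and
#' applies one binary majority smoothing (the curvature term). Evolution
#' stops at `iters` iterations or as soon as the mask is unchanged for 3
#' consecutive iterations.
#'
#' @param heat Heat matrix in `[0, 1]`.
#' @param init_mask Logical matrix, same size, with at least one
#'   foreground pixel.
#' @param iters Maximum iterations (default 100).
#' @return Logical foreground mask with attribute `converged` (TRUE when
#'   the front stabilized before the iteration cap and both phases remain
#'   distinguishable).
#' @export
level_set_segment <- function(heat, init_mask, iters = 100L) {
  .assert(all(dim(heat) == dim(init_mask)),
          "heat and init_mask must have the same dimensions")
  .assert(any(init_mask), "init_mask has no foreground: nothing to evolve",
          class = "skyfilter_invalid_argument")
  mask <- init_mask
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(iters)) {
    inside <- heat[mask]
    outside <- heat[!mask]
    if (!length(outside)) { converged <- FALSE; break }
    c1 <- mean(inside); c0 <- mean(outside)
    if (abs(c1 - c0) < 1e-6) { converged <- FALSE; break }
    # curvature (majority smoothing) first, then the data-term descent on
    # the narrow band, so shapes fully supported by the heat map are exact
    # fixed points of one iteration
    prop <- .majority3(mask)
    if (!any(prop)) prop <- mask
    band <- .dilate3(prop) & !.erode3(prop)
    prop[band] <- (heat[band] - c1)^2 < (heat[band] - c0)^2
    if (!any(prop)) { mask <- prop; converged <- FALSE; break }
    if (identical(prop, mask)) {
      stable <- stable + 1L
      if (stable >= 3L) { converged <- TRUE; break }
    } else stable <- 0L
    mask <- prop
  }
  attr(mask, "converged") <- converged
  mask
}

# Largest 8-connected component of a mask, or NULL if empty.
.largest_component <- function(mask) {
  cc <- connected_components(mask, 8L)
  if (!cc$n) return(NULL)
  sizes <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n)
  cc$labels == which.max(sizes)
}

#' Refine one loose annotation box
#'
#' The bootstrap tightening step: crop the loose box expanded by
#' `margin_frac` of its size on every side, compute an [activation_map()],
#' initialize a mask by thresholding the heat at Otsu's level, evolve it
#' with [level_set_segment()], keep the largest 8-connected foreground
#' component, and return its tight bounding box in parent coordinates. If
#' the segmentation degenerates (empty foreground, fewer than 4 foreground
#' pixels, or an uninformative heat map) the original box is returned with
#' `converged = FALSE`.
#'
#' @param image Parent intensity matrix.
#' @param loose_box Single-row box data frame (parent coordinates).
#' @param margin_frac Context margin as a fraction of box size
#'   (default 0.2).
#' @param iters Level-set iteration cap (default 100).
#' @param backend,classifier Passed to [activation_map()].
#' @return A `refinement_result` list: `original`, `refined`, `converged`,
#'   `fg_area_px`.
#' @export
refine_box <- function(image, loose_box, margin_frac = 0.2, iters = 100L,
                       backend = c("contrast", "cam"), classifier = NULL) {
  backend <- match.arg(backend)
  .assert(loose_box$x1 > loose_box$x0 && loose_box$y1 > loose_box$y0,
          "degenerate loose box", class = "skyfilter_invalid_argument")
  w <- loose_box$x1 - loose_box$x0; h <- loose_box$y1 - loose_box$y0
  cx0 <- max(0L, floor(loose_box$x0 - margin_frac * w))
  cy0 <- max(0L, floor(loose_box$y0 - margin_frac * h))
  cx1 <- min(ncol(image), ceiling(loose_box$x1 + margin_frac * w))
  cy1 <- min(nrow(image), ceiling(loose_box$y1 + margin_frac * h))
  .assert(cx1 > cx0 && cy1 > cy0, "loose box lies outside the image",
          class = "skyfilter_bounds_error")
  fallback <- list(original = loose_box, refined = loose_box,
                   converged = FALSE, fg_area_px = 0L)
  class(fallback) <- "refinement_result"
  crop <- image[(cy0 + 1):cy1, (cx0 + 1):cx1, drop = FALSE]
  if (nrow(crop) < 3 || ncol(crop) < 3) return(fallback)
  heat <- activation_map(crop, backend, classifier)
  if (max(heat) < 1e-9) return(fallback)
  thr <- EBImage::otsu(t(heat), range = c(0, 1))
  init <- heat > thr
  if (!any(init) || all(init)) return(fallback)
  seg <- level_set_segment(heat, init, iters)
  if (!isTRUE(attr(seg, "converged"))) return(fallback)
  comp <- .largest_component(seg)
  if (is.null(comp)) return(fallback)
  area <- sum(comp)
  if (area < 4L) return(fallback)
  idx <- which(comp, arr.ind = TRUE)
  refined <- boxes(cx0 + min(idx[, 2]) - 1, cy0 + min(idx[, 1]) - 1,
                   cx0 + max(idx[, 2]), cy0 + max(idx[, 1]))
  out <- list(original = loose_box, refined = refined,
              converged = isTRUE(attr(seg, "converged")),
              fg_area_px = as.integer(area))
  class(out) <- "refinement_result"
  out
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement_result: converged=%s, fg=%d px, IoU(orig,refined)=%.3f\n",
              x$converged, x$fg_area_px, iou(x$original, x$refined)))
  invisible(x)
}

#' Refine every annotation of a dataset
#'
#' Applies [refine_box()] to each annotation, preserving annotation ids,
#' image ids and categories, and reporting per-annotation the IoU between
#' the original and refined box and the convergence flag.
#'
#' @param aset An [annotation_set()] of loose boxes.
#' @param images Named list of intensity matrices keyed by image id (as
#'   character).
#' @param margin_frac,iters,backend,classifier Passed to [refine_box()].
#' @return List with `annotations` (refined [annotation_set()]) and
#'   `report` (data frame: `id`, `iou_orig_refined`, `converged`).
#' @export
refine_dataset <- function(aset, images, margin_frac = 0.2, iters = 100L,
                           backend = c("contrast", "cam"),
                           classifier = NULL) {
  backend <- match.arg(backend)
  .assert(inherits(aset, "annotation_set"), "aset must be an annotation_set")
  need <- unique(as.character(aset$annotations$image_id))
  missing <- setdiff(need, names(images))
  .assert(length(missing) == 0,
          sprintf("missing image(s) for annotation image id(s): %s",
                  paste(missing, collapse = ", ")),
          class = "skyfilter_invalid_argument")
  a <- aset$annotations
  report <- data.frame(id = a$id, iou_orig_refined = numeric(nrow(a)),
                       converged = logical(nrow(a)))
  for (i in seq_len(nrow(a))) {
    img <- images[[as.character(a$image_id[i])]]
    res <- refine_box(img, boxes(a$x0[i], a$y0[i], a$x1[i], a$y1[i]),
                      margin_frac = margin_frac, iters = iters,
                      backend = backend, classifier = classifier)
    a$x0[i] <- res$refined$x0; a$x1[i] <- res$refined$x1
    a$y0[i] <- res$refined$y0; a$y1[i] <- res$refined$y1
    report$iou_orig_refined[i] <- iou(res$original, res$refined)
    report$converged[i] <- res$converged
  }
  list(annotations = annotation_set(a, aset$images, aset$categories),
       report = report)
}
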