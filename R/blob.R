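#' Blob-proposal parameters
#'
#' Constants of the classical proposal stage: global intensity threshold
#' 0.9 and dilation factor 12 (the defaults), the foreground polarity
#' (dark birds on bright water by default), the contrast-enhancement
#' method applied before thresholding, and a minimum evidence-pixel count
#' per blob.
#'
#' @param intensity_threshold Threshold in `(0, 1)` applied to the
#'   contrast-enhanced image (default 0.9).
#' @param dilation_factor Side of the square structuring element used to
#'   merge nearby fragments (default 12; 0 disables dilation).
#' @param polarity `"dark_fg"` (foreground = enhanced intensity below the
#'   threshold) or `"bright_fg"` (above).
#' @param contrast_enhance `"none"`, `"stretch"` (white-point stretch:
#'   divide by the 99.9th intensity percentile, so near-saturated water
#'   maps above a high threshold regardless of scene content) or
#'   `"clahe"`.
#' @param min_blob_px Minimum number of pre-dilation foreground pixels a
#'   blob needs to become a proposal.
#' @return A `blob_params` list.
#' @export
blob_params <- function(intensity_threshold = 0.9, dilation_factor = 12L,
                        polarity = c("dark_fg", "bright_fg"),
                        contrast_enhance = c("stretch", "none", "clahe"),
                        min_blob_px = 4L) {
  polarity <- match.arg(polarity)
  contrast_enhance <- match.arg(contrast_enhance)
  .assert(.is_scalar_num(intensity_threshold) && intensity_threshold > 0 &&
          intensity_threshold < 1, "intensity_threshold must be in (0,1)",
          class = "skyfilter_invalid_argument")
  .assert(.is_count(dilation_factor), "dilation_factor must be >= 0",
          class = "skyfilter_invalid_argument")
  .assert(.is_count(min_blob_px), "min_blob_px must be >= 0",
          class = "skyfilter_invalid_argument")
  structure(list(intensity_threshold = intensity_threshold,
                 dilation_factor = as.integer(dilation_factor),
                 polarity = polarity, contrast_enhance = contrast_enhance,
                 min_blob_px = as.integer(min_blob_px)),
            class = "blob_params")
}

# Contrast enhancement before thresholding.
enhance_contrast <- function(image, method = c("stretch", "none", "clahe")) {
  method <- match.arg(method)
  if (method == "none") return(image)
  if (method == "stretch") {
    hi <- stats::quantile(image, 0.999, names = FALSE)
    if (hi <= 0) return(image)
    return(clamp01(image / hi))
  }
  # clahe: EBImage works in [x, y]
  t(as.matrix(EBImage::clahe(t(clamp01(image)))))
}

#' Binarize an image for blob proposals
#'
#' Applies the configured contrast enhancement, then thresholds: with
#' `dark_fg` polarity the foreground is every pixel strictly below
#' `intensity_threshold`; with `bright_fg`, strictly above.
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param params A [blob_params()].
#' @return Logical matrix (TRUE = foreground).
#' @export
binarize <- function(image, params = blob_params()) {
  .assert(params$intensity_threshold > 0 && params$intensity_threshold < 1,
          "intensity_threshold must be in (0,1)",
          class = "skyfilter_invalid_argument")
  enh <- enhance_contrast(image, params$contrast_enhance)
  if (params$polarity == "dark_fg") enh < params$intensity_threshold
  else enh > params$intensity_threshold
}

#' Morphological dilation with a square structuring element
#'
#' Dilates a binary mask with a `factor x factor` square element (for even
#' sizes the element extends one pixel further right/down of the origin).
#' Factor 0 or 1 is the identity; the output always contains the input.
#'
#' @param mask Logical matrix.
#' @param dilation_factor Side of the square element, `>= 0`.
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, dilation_factor = 12L) {
  .assert(.is_count(dilation_factor), "dilation factor must be >= 0",
          class = "skyfilter_invalid_argument")
  f <- as.integer(dilation_factor)
  if (f <= 1L || !any(mask)) return(mask)
  offs <- (-((f - 1L) %/% 2L)):((f - 1L) - (f - 1L) %/% 2L)
  shift_or <- function(m, offsets, along) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    n <- if (along == 1) nrow(m) else ncol(m)
    for (o in offsets) {
      src <- seq_len(n) - o
      ok <- src >= 1 & src <= n
      if (along == 1) out[ok, ] <- out[ok, ] | m[src[ok], ]
      else out[, ok] <- out[, ok] | m[, src[ok]]
    }
    out
  }
  shift_or(shift_or(mask, offs, 1), offs, 2)
}

#' Label connected components of a binary mask
#'
#' Flood-fill labeling under 4- or 8-pixel connectivity; labels are
#' contiguous integers from 1, assigned in order of each component's first
#' pixel in column-major scan order.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return List with `labels` (integer matrix, 0 = background) and `n`.
#' @export
connected_components <- function(mask, connectivity = 8L) {
  .assert(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8",
          class = "skyfilter_invalid_argument")
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask)
  if (!length(fg)) return(list(labels = labels, n = 0L))
  compact <- integer(h * w)
  compact[fg] <- seq_along(fg)
  y <- (fg - 1L) %% h + 1L
  x <- (fg - 1L) %/% h + 1L
  edge_pairs <- function(dy, dx) {
    ok <- y + dy >= 1L & y + dy <= h & x + dx >= 1L & x + dx <= w
    nb <- fg[ok] + dy + dx * h
    nb_ok <- compact[nb] > 0L
    cbind(compact[fg[ok]][nb_ok], compact[nb][nb_ok])
  }
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel in order of first appearance along the column-major scan
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  labels[fg] <- relab[memb]
  list(labels = labels, n = length(first))
}

#' Tight box proposals from labeled components
#'
#' One half-open box per component, from the min/max pixel coordinates of
#' its labeled pixels; components with fewer than `min_blob_px` pixels are
#' dropped. Proposals are ordered by `(y0, x0)`.
#'
#' @param labels Integer label matrix from [connected_components()].
#' @param min_blob_px Minimum pixel count per component.
#' @return Box data frame with an extra `area` column (component pixel
#'   count).
#' @export
proposals_from_components <- function(labels, min_blob_px = 1L) {
  fg <- which(labels > 0L)
  if (!length(fg))
    return(cbind(empty_boxes(), data.frame(area = numeric())))
  h <- nrow(labels)
  y <- (fg - 1L) %% h      # 0-based row
  x <- (fg - 1L) %/% h     # 0-based col
  lab <- labels[fg]
  x0 <- tapply(x, lab, min); x1 <- tapply(x, lab, max) + 1
  y0 <- tapply(y, lab, min); y1 <- tapply(y, lab, max) + 1
  area <- tapply(lab, lab, length)
  out <- data.frame(x0 = as.numeric(x0), y0 = as.numeric(y0),
                    x1 = as.numeric(x1), y1 = as.numeric(y1),
                    area = as.numeric(area))
  out <- out[out$area >= min_blob_px, , drop = FALSE]
  out <- out[order(out$y0, out$x0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' HOG descriptor parameters
#'
#' Geometry of the histogram-of-oriented-gradients descriptor: the crop is
#' resized to `window`, divided into `cell`-sized cells, and blocks of
#' `block` cells (stepped by `block_stride` pixels) are L2-Hys normalized.
#' The window must divide into whole cells and the block stride into whole
#' cells.
#'
#' @param window Descriptor window `(w, h)` in pixels (default 64x64).
#' @param cell Cell size `(w, h)` (default 8x8).
#' @param block Block size in cells (default 2x2).
#' @param block_stride Block step in pixels (default 8x8 = one cell).
#' @param orientations Number of unsigned orientation bins (default 9).
#' @return A `hog_params` list with the derived feature length.
#' @export
hog_params <- function(window = c(64L, 64L), cell = c(8L, 8L),
                       block = c(2L, 2L), block_stride = c(8L, 8L),
                       orientations = 9L) {
  window <- rep_len(as.integer(window), 2)
  cell <- rep_len(as.integer(cell), 2)
  block <- rep_len(as.integer(block), 2)
  block_stride <- rep_len(as.integer(block_stride), 2)
  ce <- "skyfilter_config_error"
  .assert(all(window %% cell == 0), "window must divide into whole cells",
          class = ce)
  .assert(all(block_stride %% cell == 0),
          "block_stride must be a whole number of cells", class = ce)
  .assert(orientations >= 2, "need at least 2 orientation bins", class = ce)
  ncells <- window %/% cell
  .assert(all(block <= ncells), "block larger than the cell grid", class = ce)
  stride_cells <- block_stride %/% cell
  nblocks <- (ncells - block) %/% stride_cells + 1L
  structure(list(window = window, cell = cell, block = block,
                 block_stride = block_stride,
                 orientations = as.integer(orientations),
                 n_cells = ncells, n_blocks = nblocks,
                 length = prod(nblocks) * prod(block) * orientations),
            class = "hog_params")
}

#' Histogram-of-oriented-gradients features of a box crop
#'
#' Crops the (clipped, integer-rounded) box, resizes it to the descriptor
#' window, computes central-difference gradients, votes gradient magnitude
#' into unsigned orientation bins with linear interpolation between
#' neighboring bins, pools per cell, and normalizes overlapping blocks
#' with L2-Hys (clip at 0.2, renormalize). A constant crop yields the zero
#' vector. Feature length is fixed by the geometry, independent of the
#' original box size.
#'
#' @param image Intensity matrix.
#' @param box Single-row box data frame.
#' @param params A [hog_params()].
#' @return Numeric feature vector of length `params$length`.
#' @export
hog_features <- function(image, box, params = hog_params()) {
  .assert(box$x1 > box$x0 && box$y1 > box$y0, "degenerate box",
          class = "skyfilter_invalid_argument")
  x0 <- max(0L, floor(box$x0)); y0 <- max(0L, floor(box$y0))
  x1 <- min(ncol(image), ceiling(box$x1)); y1 <- min(nrow(image), ceiling(box$y1))
  .assert(x1 > x0 && y1 > y0, "box lies outside the image",
          class = "skyfilter_bounds_error")
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  win <- resize_image(crop, height = params$window[2], width = params$window[1])
  h <- nrow(win); w <- ncol(win)
  # replicate-padded central differences
  gx <- win[, c(2:w, w)] - win[, c(1, 1:(w - 1))]
  gy <- win[c(2:h, h), ] - win[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                       # unsigned, [0, pi)
  nb <- params$orientations
  ob <- ang / pi * nb - 0.5                        # continuous bin index
  b0 <- floor(ob)
  w1 <- ob - b0                                    # weight of upper bin
  b0 <- as.integer(b0 %% nb); b1 <- as.integer((b0 + 1L) %% nb)
  cy <- (row(win) - 1L) %/% params$cell[2]
  cx <- (col(win) - 1L) %/% params$cell[1]
  ncx <- params$n_cells[1]; ncy <- params$n_cells[2]
  cell_id <- cy * ncx + cx                         # 0-based cell index
  acc <- numeric(ncx * ncy * nb)
  scatter <- function(bins, wts) {
    idx <- cell_id * nb + bins + 1L
    s <- tapply(as.vector(mag * wts), as.vector(idx), sum)
    acc[as.integer(names(s))] <<- acc[as.integer(names(s))] + s
  }
  scatter(b0, 1 - w1)
  scatter(b1, w1)
  hist_arr <- array(acc, dim = c(nb, ncx, ncy))    # [bin, cx, cy]
  sc <- params$block_stride %/% params$cell
  nbx <- params$n_blocks[1]; nby <- params$n_blocks[2]
  feats <- numeric(params$length)
  k <- 1L
  blk_len <- prod(params$block) * nb
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    cxs <- (bx - 1L) * sc[1] + seq_len(params$block[1])
    cys <- (by - 1L) * sc[2] + seq_len(params$block[2])
    v <- as.vector(hist_arr[, cxs, cys])
    n1 <- sqrt(sum(v^2) + 1e-10)
    v <- pmin(v / n1, 0.2)
    v <- v / sqrt(sum(v^2) + 1e-10)
    if (sum(v^2) < 1e-12) v[] <- 0
    feats[k:(k + blk_len - 1L)] <- v
    k <- k + blk_len
  }
  feats
}

#' Train the linear-SVM proposal classifier
#'
#' Fits a linear support-vector machine separating bird proposals from
#' background proposals in HOG-feature space. Scores for detection are the
#' SVM decision value mapped through a logistic, so downstream NMS and
#' ranking see comparable values in `(0, 1)`.
#'
#' @param pos_features,neg_features Numeric matrices (rows = examples);
#'   each class needs at least one example.
#' @param cost SVM cost parameter `C`.
#' @return A `proposal_classifier`.
#' @export
train_svm <- function(pos_features, neg_features, cost = 1) {
  pos_features <- rbind(pos_features); neg_features <- rbind(neg_features)
  .assert(!is.null(pos_features) && nrow(pos_features) >= 1 &&
          !is.null(neg_features) && nrow(neg_features) >= 1,
          "need at least one example per class (positive and negative)",
          class = "skyfilter_single_class_error")
  x <- rbind(pos_features, neg_features)
  y <- factor(rep(c("pos", "neg"), c(nrow(pos_features), nrow(neg_features))),
              levels = c("pos", "neg"))
  model <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                      probability = FALSE)
  structure(list(model = model, feature_length = ncol(x)),
            class = "proposal_classifier")
}

#' Score proposals with a trained classifier
#'
#' @param classifier A `proposal_classifier` from [train_svm()].
#' @param features Numeric matrix of HOG features (rows = proposals).
#' @return Numeric scores in `(0, 1)` (logistic of the SVM decision value).
#' @export
svm_scores <- function(classifier, features) {
  .assert(inherits(classifier, "proposal_classifier"),
          "classifier must come from train_svm()")
  features <- rbind(features)
  if (!nrow(features)) return(numeric())
  if (is.null(classifier$model))
    return(rep(classifier$constant, nrow(features)))
  pred <- stats::predict(classifier$model, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
  stats::plogis(sgn * as.numeric(dv[, 1]))
}

#' Generate blob proposals for one image
#'
#' The proposal half of the detector: enhance + threshold, dilate to merge
#' fragments, label 8-connected components of the dilated mask, and box
#' each component. Boxes are tightened back to the pre-dilation foreground
#' pixels of the component (`tighten = TRUE`), so the dilation that merges
#' fragments does not inflate the reported geometry; `min_blob_px` counts
#' those evidence pixels.
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param params A [blob_params()].
#' @param tighten Tighten proposal boxes to pre-dilation pixels.
#' @return Box data frame with `area` (evidence-pixel count).
#' @export
blob_proposals <- function(image, params = blob_params(), tighten = TRUE) {
  mask <- binarize(image, params)
  dil <- dilate_mask(mask, params$dilation_factor)
  cc <- connected_components(dil, 8L)
  if (!cc$n) return(cbind(empty_boxes(), data.frame(area = numeric())))
  if (!tighten) return(proposals_from_components(cc$labels, params$min_blob_px))
  ev <- cc$labels
  ev[!mask] <- 0L   # evidence pixels only, labeled by their dilated component
  proposals_from_components(ev, params$min_blob_px)
}

#' Run the full blob + HOG + SVM detector on one image
#'
#' Chains [blob_proposals()], [hog_features()] and [svm_scores()]; keeps
#' proposals whose logistic score reaches `score_threshold`. Deterministic:
#' the same input always yields the same detections.
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param blob A [blob_params()].
#' @param hog A [hog_params()].
#' @param classifier A `proposal_classifier`; its features must have been
#'   built with the same `hog` geometry.
#' @param score_threshold Minimum score to keep (default 0.5).
#' @return Detection box data frame with `score`.
#' @export
detect <- function(image, blob = blob_params(), hog = hog_params(),
                   classifier, score_threshold = 0.5) {
  .assert(inherits(classifier, "proposal_classifier"),
          "classifier must come from train_svm()")
  props <- blob_proposals(image, blob)
  if (!nrow(props)) return(empty_boxes(score = TRUE))
  .assert(classifier$feature_length == hog$length,
          "classifier was trained with a different HOG geometry",
          class = "skyfilter_config_error")
  feats <- t(vapply(seq_len(nrow(props)), function(i)
    hog_features(image, props[i, ], hog), numeric(hog$length)))
  sc <- svm_scores(classifier, feats)
  out <- props[sc >= score_threshold, c("x0", "y0", "x1", "y1"), drop = FALSE]
  out$score <- sc[sc >= score_threshold]
  rownames(out) <- NULL
  out
}

#' Label proposals against annotation boxes
#'
#' A proposal counts as positive iff its best IoU against any annotation
#' box reaches `iou_thresh` -- the same convention the evaluation uses for
#' true positives.
#'
#' @param proposals,ann_boxes Box data frames.
#' @param iou_thresh Positive-label threshold (default 0.5).
#' @return Logical vector over proposals.
#' @export
label_proposals <- function(proposals, ann_boxes, iou_thresh = 0.5) {
  if (!nrow(proposals)) return(logical())
  if (!nrow(ann_boxes)) return(rep(FALSE, nrow(proposals)))
  apply(iou_matrix(proposals, ann_boxes), 1, max) >= iou_thresh
}

#' Train the detector from scenes with annotations
#'
#' Convenience wrapper over the proposal/feature/label plumbing: generates
#' proposals per image, extracts HOG features, labels them against the
#' supplied annotation boxes and fits the SVM.
#'
#' @param images List of intensity matrices.
#' @param ann_boxes List of box data frames, parallel to `images`.
#' @param blob A [blob_params()].
#' @param hog A [hog_params()].
#' @param cost SVM cost.
#' @param iou_thresh Proposal-labeling threshold.
#' @return A `proposal_classifier`.
#' @export
train_blob_detector <- function(images, ann_boxes, blob = blob_params(),
                                hog = hog_params(), cost = 1,
                                iou_thresh = 0.5) {
  .assert(length(images) == length(ann_boxes),
          "images and ann_boxes must be parallel lists")
  feats <- list(); labs <- logical()
  for (i in seq_along(images)) {
    props <- blob_proposals(images[[i]], blob)
    if (!nrow(props)) next
    f <- t(vapply(seq_len(nrow(props)), function(j)
      hog_features(images[[i]], props[j, ], hog), numeric(hog$length)))
    feats[[length(feats) + 1L]] <- f
    labs <- c(labs, label_proposals(props, ann_boxes[[i]], iou_thresh))
  }
  .assert(length(labs) > 0, "no proposals found in the training images")
  X <- do.call(rbind, feats)
  if (all(labs) || !any(labs)) {
    # Degenerate but legitimate regime: every proposal matched a bird (very
    # clean water) or none did (annotations too loose to certify any
    # proposal). The SVM cannot be fit; fall back to the constant
    # classifier that accepts or rejects all proposals accordingly.
    warning(sprintf(
      "all %d training proposals are %s; returning a constant classifier",
      length(labs), if (all(labs)) "positive" else "negative"))
    return(structure(list(model = NULL, constant = as.numeric(all(labs)),
                          feature_length = ncol(X)),
                     class = "proposal_classifier"))
  }
  train_svm(X[labs, , drop = FALSE], X[!labs, , drop = FALSE], cost = cost)
}
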