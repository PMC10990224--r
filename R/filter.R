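#' Augmentation recipe for filter training patches
#'
#' Random resized crops in the style used for training image classifiers:
#' crop area a uniform fraction of the source patch (default 0.08-1.0
#' times), aspect jitter in `[3/4, 4/3]`, rescale to `out_size` (default
#' 480 x 480) and a horizontal flip with probability `hflip_prob`.
#'
#' @param crop_area_range Length-2 range of crop area fractions in
#'   `(0, 1]`.
#' @param out_size Output size `(w, h)` in pixels.
#' @param hflip_prob Horizontal-flip probability.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(crop_area_range = c(0.08, 1.0),
                         out_size = c(480L, 480L), hflip_prob = 0.5) {
  .assert(is.numeric(crop_area_range) && length(crop_area_range) == 2 &&
          crop_area_range[1] > 0 && crop_area_range[1] <= crop_area_range[2] &&
          crop_area_range[2] <= 1,
          "crop_area_range must lie inside (0, 1]",
          class = "skyfilter_invalid_argument")
  .assert(hflip_prob >= 0 && hflip_prob <= 1, "hflip_prob must be in [0,1]",
          class = "skyfilter_invalid_argument")
  structure(list(crop_area_range = crop_area_range,
                 out_size = rep_len(as.integer(out_size), 2),
                 hflip_prob = hflip_prob), class = "augment_spec")
}

#' Randomly crop, rescale and flip a training patch
#'
#' Draws one augmented patch under an [augment_spec()]. When `gt_boxes`
#' (patch-frame ground truth) is supplied, the augmented patch is labeled
#' positive iff at least one box center falls inside the crop -- the
#' center rule avoids double-counting birds that straddle crop borders.
#' Deterministic given `seed`.
#'
#' @param patch Intensity matrix (at least 32 x 32).
#' @param spec An [augment_spec()].
#' @param seed Integer seed.
#' @param gt_boxes Optional box data frame in patch coordinates.
#' @return List: `patch` (augmented), `label` (0/1 or `NA` when no
#'   `gt_boxes` given), `crop` (the crop box), `flipped`.
#' @export
augment_patch <- function(patch, spec = augment_spec(), seed = 1L,
                          gt_boxes = NULL) {
  .assert(nrow(patch) >= 32 && ncol(patch) >= 32,
          "patch must be at least 32x32",
          class = "skyfilter_invalid_argument")
  H <- nrow(patch); W <- ncol(patch)
  with_seed(.derive_seed(seed, 5L), {
    area <- stats::runif(1, spec$crop_area_range[1], spec$crop_area_range[2])
    aspect <- exp(stats::runif(1, log(3 / 4), log(4 / 3)))
    cw <- max(8L, round(sqrt(area * W * H * aspect)))
    ch <- max(8L, round(sqrt(area * W * H / aspect)))
    if (cw > W || ch > H) { cw <- W; ch <- H }   # jitter does not fit: full crop
    x0 <- if (W > cw) sample.int(W - cw + 1L, 1L) - 1L else 0L
    y0 <- if (H > ch) sample.int(H - ch + 1L, 1L) - 1L else 0L
    crop <- patch[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), drop = FALSE]
    out <- resize_image(crop, height = spec$out_size[2],
                        width = spec$out_size[1])
    flipped <- stats::runif(1) < spec$hflip_prob
    if (flipped) out <- out[, ncol(out):1, drop = FALSE]
    label <- NA_integer_
    if (!is.null(gt_boxes)) {
      if (nrow(gt_boxes)) {
        cx <- (gt_boxes$x0 + gt_boxes$x1) / 2
        cy <- (gt_boxes$y0 + gt_boxes$y1) / 2
        label <- as.integer(any(cx >= x0 & cx < x0 + cw &
                                cy >= y0 & cy < y0 + ch))
      } else label <- 0L
    }
    list(patch = out, label = label,
         crop = boxes(x0, y0, x0 + cw, y0 + ch), flipped = flipped)
  })
}

# ---------------------------------------------------------------------------
# Compact convolutional occupancy classifier
#
# One convolutional layer of fixed band-pass kernels (center-surround
# difference-of-Gaussians at three scales and four oriented Gaussian
# derivatives), squared-ReLU activations of both response signs, global
# average pooling, and a single fully connected (ridge-logistic) layer.
# The GAP + FC structure is what makes the CAM localization backend of the
# box refiner available. All parameters apart from the FC weights are
# fixed, so training is a deterministic convex fit that runs in seconds on
# a CPU.

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- outer(-r:r, -r:r, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

.dog_kernel <- function(s1, s2) {
  k1 <- .gauss_kernel(s1); k2 <- .gauss_kernel(s2)
  r <- (nrow(k2) - 1L) %/% 2L
  pad <- matrix(0, nrow(k2), ncol(k2))
  r1 <- (nrow(k1) - 1L) %/% 2L
  pad[(r - r1 + 1):(r + r1 + 1), (r - r1 + 1):(r + r1 + 1)] <- k1
  pad - k2
}

.deriv_kernel <- function(sigma, theta) {
  r <- max(1L, ceiling(3 * sigma))
  outer(-r:r, -r:r, function(y, x) {
    u <- x * cos(theta) + y * sin(theta)
    -u / sigma^2 * exp(-(x^2 + y^2) / (2 * sigma^2))
  })
}

.filter_bank <- function() {
  ks <- list(dog1 = .dog_kernel(1, 2), dog2 = .dog_kernel(2, 4),
             dog3 = .dog_kernel(3, 6))
  for (i in 0:3)
    ks[[sprintf("d%d", i)]] <- .deriv_kernel(1.5, i * pi / 4)
  ks
}

.conv_replicate <- function(img, kern) {
  r <- (dim(kern) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1, r[1]), 1:h, rep(h, r[1])),
             c(rep(1, r[2]), 1:w, rep(w, r[2])), drop = FALSE]
  out <- t(as.matrix(EBImage::filter2(t(pad), t(kern))))
  out[(r[1] + 1):(r[1] + h), (r[2] + 1):(r[2] + w), drop = FALSE]
}

# Response maps (squared ReLU of both signs) at the working resolution.
.cnn_maps <- function(model, patch) {
  wk <- resize_image(patch, model$working, model$working)
  maps <- list()
  for (nm in names(model$kernels)) {
    r <- .conv_replicate(wk, model$kernels[[nm]])
    maps[[paste0(nm, "_pos")]] <- pmax(r, 0)^2
    maps[[paste0(nm, "_neg")]] <- pmax(-r, 0)^2
  }
  maps
}

.cnn_features <- function(model, patch) {
  vapply(.cnn_maps(model, patch), mean, numeric(1))
}

#' Train the occupancy-filter model
#'
#' Two backends:
#'
#' * `proposal_heuristic`: no training; a patch is scored by how many blob
#'   proposals survive the minimum-area filter.
#' * `small_cnn`: the compact convolutional classifier described in the
#'   package vignette -- a fixed band-pass filter bank, squared-ReLU
#'   activations, global average pooling and one fully connected
#'   ridge-logistic layer fit with `glmnet`. Training is deterministic.
#'
#' @param patches List of intensity matrices (augmented training patches).
#' @param labels 0/1 vector, one per patch; both classes must be present
#'   for `small_cnn`.
#' @param backend `"small_cnn"` or `"proposal_heuristic"`.
#' @param blob A [blob_params()] for the heuristic backend.
#' @param lambda Ridge penalty for the FC layer.
#' @return A `filter_model`.
#' @export
train_filter <- function(patches, labels = NULL,
                         backend = c("small_cnn", "proposal_heuristic"),
                         blob = blob_params(), lambda = 1e-3) {
  backend <- match.arg(backend)
  if (backend == "proposal_heuristic") {
    return(structure(list(backend = backend, blob = blob,
                          input_size = 480L),
                     class = "filter_model"))
  }
  .assert(length(patches) == length(labels),
          "need one label per patch")
  .assert(length(unique(labels[!is.na(labels)])) == 2,
          "training data must contain both classes",
          class = "skyfilter_single_class_error")
  model <- structure(list(backend = backend, kernels = .filter_bank(),
                          input_size = 480L, working = 120L),
                     class = "filter_model")
  X <- t(vapply(patches, function(p) .cnn_features(model, p),
                numeric(2L * length(model$kernels))))
  fit <- glmnet::glmnet(X, as.numeric(labels), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta[, 1])
  model$weights <- stats::setNames(beta, rownames(fit$beta))
  model$intercept <- as.numeric(fit$a0[1])
  model
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf("filter_model: backend=%s\n", x$backend))
  invisible(x)
}

#' Occupancy probability of one patch
#'
#' For the `small_cnn` backend, patches larger than the model's native
#' 480-pixel input are scanned with a half-overlapping 480-pixel sliding
#' window and the maximum window probability is returned, so a bird
#' anywhere in a large evaluation patch is seen at the scale the model
#' was trained at. The heuristic backend scores by blob-proposal count
#' (exactly 0 for a patch with no proposals).
#'
#' @param model A `filter_model`.
#' @param patch Intensity matrix.
#' @return Probability in `[0, 1]`.
#' @export
predict_patch <- function(model, patch) {
  .assert(inherits(model, "filter_model"), "model must come from train_filter()")
  if (model$backend == "proposal_heuristic") {
    n <- nrow(blob_proposals(patch, model$blob))
    return(if (n == 0) 0 else stats::plogis(n))
  }
  .assert(!is.null(model$weights), "uninitialized filter model",
          class = "skyfilter_config_error")
  win <- model$input_size
  score_window <- function(p) {
    f <- .cnn_features(model, p)
    stats::plogis(model$intercept + sum(model$weights * f))
  }
  if (nrow(patch) <= win && ncol(patch) <= win) return(score_window(patch))
  grid <- plan_tiles(ncol(patch), nrow(patch), window = win,
                     stride = win %/% 2L)
  max(vapply(seq_len(nrow(grid$tiles)), function(i)
    score_window(extract_patch(patch, grid$tiles[i, ])), numeric(1)))
}

#' Class-activation map of a patch
#'
#' The localization by-product of the GAP-headed classifier: the
#' convolutional response maps weighted by the fully connected layer's
#' class weights, clamped at zero, bilinearly upsampled to the patch size
#' and min-max normalized.
#'
#' @param model A trained `small_cnn` `filter_model`.
#' @param patch Intensity matrix.
#' @return Heat matrix in `[0, 1]`, same size as `patch`.
#' @export
cam_map <- function(model, patch) {
  .assert(inherits(model, "filter_model") && model$backend == "small_cnn" &&
          !is.null(model$weights),
          "cam_map needs a trained small_cnn filter model",
          class = "skyfilter_config_error")
  maps <- .cnn_maps(model, patch)
  acc <- matrix(0, model$working, model$working)
  for (nm in names(maps)) acc <- acc + model$weights[[nm]] * maps[[nm]]
  acc <- pmax(acc, 0)
  up <- resize_image(acc, nrow(patch), ncol(patch))
  mx <- max(up)
  if (mx < 1e-12) return(matrix(0, nrow(patch), ncol(patch)))
  clamp01(up / mx)
}

#' Stage-1 filtering of parent frames
#'
#' Tiles every parent with the evaluation grid (default 1440-pixel
#' windows, 1080-pixel stride, rescaled to 960), predicts an occupancy
#' probability per patch, takes the maximum as the parent probability, and
#' keeps the parent iff that probability exceeds `threshold`. Thresholding
#' the maximum is exactly the any-patch rule: the parent is kept iff any
#' patch probability exceeds the threshold. All parents appear in the
#' probability table regardless of the decision, so filtered imagery is
#' never lost.
#'
#' @param model A `filter_model`.
#' @param parents Named list of parent intensity matrices (names = image
#'   ids).
#' @param tiling List with `window`, `stride`, `rescale` (the eval grid);
#'   default from the package configuration.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return List: `kept` ids, `dropped` ids, `probs` data frame
#'   (`image_id`, `p_occurrence`, `decision`).
#' @export
filter_images <- function(model, parents,
                          tiling = .default_config()$tiling$eval,
                          threshold = 0.5) {
  .assert(threshold > 0 && threshold < 1, "threshold must be in (0,1)",
          class = "skyfilter_invalid_argument")
  .assert(!is.null(names(parents)), "parents must be a named list")
  probs <- vapply(parents, function(img) {
    grid <- plan_tiles(ncol(img), nrow(img), window = tiling$window,
                       stride = tiling$stride)
    rescale <- if (!is.null(tiling$rescale))
      rep_len(tiling$rescale, 2) else NULL
    max(vapply(seq_len(nrow(grid$tiles)), function(i)
      predict_patch(model, extract_patch(img, grid$tiles[i, ],
                                         rescale_to = rescale)),
      numeric(1)))
  }, numeric(1))
  decision <- as.integer(probs > threshold)
  df <- data.frame(image_id = names(parents), p_occurrence = probs,
                   decision = decision, row.names = NULL)
  list(kept = names(parents)[decision == 1],
       dropped = names(parents)[decision == 0], probs = df)
}
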