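#' Specify a synthetic open-water scene
#'
#' A `scene_spec` fixes everything needed to generate one synthetic aerial
#' frame: its pixel size, the ground sample distance (GSD, cm per pixel),
#' how many birds to place, their physical body length and contrast against
#' the water, the sea state (wave-texture amplitude), the fraction of pixels
#' lost to saturated glare, and the seed that makes the scene reproducible.
#'
#' The pixel footprint of a bird follows the imaging geometry: its major
#' axis is `bird_length_cm / gsd_cm` pixels (never below 2). Surveys in the
#' regime this emulates flew GSDs of roughly 0.14-1.47 cm, so a 40 cm sea
#' duck spans anything from ~27 to ~285 pixels depending on altitude.
#'
#' @param width_px,height_px Frame size in pixels (at least 64 each).
#' @param gsd_cm Ground sample distance in cm/pixel; positive.
#' @param n_birds Number of birds to attempt to place (>= 0); birds whose
#'   placement would overlap an already-placed bird beyond a small IoU cap
#'   are re-sampled and eventually dropped, so the ground truth may hold
#'   fewer boxes than `n_birds`.
#' @param bird_length_cm Physical body length in cm (default 40).
#' @param bird_contrast Foreground-background intensity gap in `(0, 1]`.
#' @param sea_state Wave-texture amplitude in `[0, 1]`; 0 is flat calm.
#' @param glare_fraction Fraction of pixels inside saturated glare patches,
#'   in `[0, 1]`.
#' @param bird_polarity `"dark"` (default; dark ducks on sunlit water) or
#'   `"bright"`, to exercise the detector's polarity switch.
#' @param seed Integer seed; identical specs generate identical scenes.
#' @return An object of class `scene_spec`.
#' @export
#' @examples
#' scene_spec(256, 256, gsd_cm = 0.5, n_birds = 3, seed = 7)
scene_spec <- function(width_px, height_px, gsd_cm, n_birds,
                       bird_length_cm = 40, bird_contrast = 0.5,
                       sea_state = 0.2, glare_fraction = 0,
                       bird_polarity = c("dark", "bright"), seed = 1L) {
  bird_polarity <- match.arg(bird_polarity)
  .assert(.is_count(width_px) && .is_count(height_px) &&
          width_px >= 64 && height_px >= 64,
          "scene dimensions must be integers >= 64",
          class = "skyfilter_invalid_spec")
  .assert(.is_scalar_num(gsd_cm) && gsd_cm > 0, "gsd_cm must be positive",
          class = "skyfilter_invalid_spec")
  .assert(.is_count(n_birds), "n_birds must be a non-negative integer",
          class = "skyfilter_invalid_spec")
  .assert(.is_scalar_num(bird_length_cm) && bird_length_cm > 0,
          "bird_length_cm must be positive", class = "skyfilter_invalid_spec")
  .assert(.is_scalar_num(bird_contrast) && bird_contrast > 0 &&
          bird_contrast <= 1, "bird_contrast must be in (0, 1]",
          class = "skyfilter_invalid_spec")
  .assert(.is_scalar_num(sea_state) && sea_state >= 0 && sea_state <= 1,
          "sea_state must be in [0, 1]", class = "skyfilter_invalid_spec")
  .assert(.is_scalar_num(glare_fraction) && glare_fraction >= 0 &&
          glare_fraction <= 1, "glare_fraction must be in [0, 1]",
          class = "skyfilter_invalid_spec")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 gsd_cm = gsd_cm, n_birds = as.integer(n_birds),
                 bird_length_cm = bird_length_cm,
                 bird_contrast = bird_contrast, sea_state = sea_state,
                 glare_fraction = glare_fraction,
                 bird_polarity = bird_polarity, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "scene_spec: %dx%d px, GSD %.3g cm (bird footprint %d px), %d birds,\n",
    x$width_px, x$height_px, x$gsd_cm, bird_footprint_px(x), x$n_birds))
  cat(sprintf("  contrast %.2f, sea state %.2f, glare %.2f, %s birds, seed %d\n",
    x$bird_contrast, x$sea_state, x$glare_fraction, x$bird_polarity, x$seed))
  invisible(x)
}

#' Pixel footprint (major axis) of a bird under a scene spec
#' @param spec A [scene_spec()].
#' @return Integer major-axis length in pixels, at least 2.
#' @export
bird_footprint_px <- function(spec) {
  max(2L, as.integer(round(spec$bird_length_cm / spec$gsd_cm)))
}

# Water-surface constants. Water sits near the bright end of the range so
# that, after contrast enhancement, a high global intensity threshold
# separates background from dark bird targets -- the regime the classical
# detector is designed for. Wave texture is band-limited (low-frequency)
# noise; its amplitude at sea_state = 1 is WAVE_AMP.
.WATER_BASE <- 0.97
.WAVE_AMP <- 0.04
.BIRD_JITTER_SD <- 0.015

# Smooth low-frequency field: coarse white noise bilinearly upsampled.
.lowfreq_field <- function(height, width, cells = 24) {
  ch <- max(2L, as.integer(round(height / cells)))
  cw <- max(2L, as.integer(round(width / cells)))
  coarse <- matrix(stats::rnorm(ch * cw), ch, cw)
  f <- resize_image(coarse, height, width)
  f / max(stats::sd(f), 1e-12)
}

#' Generate the water background of a synthetic scene
#'
#' Bright open water with band-limited wave texture scaled by
#' `spec$sea_state` and saturated glare patches covering approximately
#' `spec$glare_fraction` of the pixels. Deterministic given `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return A `height_px x width_px` intensity matrix in `[0, 1]`.
#' @export
generate_background <- function(spec) {
  .assert(inherits(spec, "scene_spec"), "spec must be a scene_spec",
          class = "skyfilter_invalid_spec")
  h <- spec$height_px; w <- spec$width_px
  with_seed(.derive_seed(spec$seed, 1L), {
    img <- matrix(.WATER_BASE, h, w)
    if (spec$sea_state > 0) {
      waves <- .lowfreq_field(h, w, cells = 16) +
        0.5 * .lowfreq_field(h, w, cells = 48)
      img <- img + .WAVE_AMP * spec$sea_state * waves / 1.5
    }
    if (spec$glare_fraction > 0) {
      g <- .lowfreq_field(h, w, cells = 12)
      cut <- stats::quantile(g, 1 - spec$glare_fraction, names = FALSE)
      img[g >= cut] <- 1
    }
    clamp01(img)
  })
}

#' Place bird targets into a generated background
#'
#' Stamps `spec$n_birds` flat-shaded elliptical targets (random orientation,
#' axis ratio 0.35-0.65, mild per-pixel jitter) into the background, dark
#' against the water by `spec$bird_contrast` (or bright, under the
#' `"bright"` polarity). Placement is rejection-sampled so that no two
#' ground-truth boxes overlap with IoU above 0.1; a bird that cannot be
#' placed within 50 tries is dropped and the returned ground truth reflects
#' that.
#'
#' @param background Matrix from [generate_background()] with matching spec.
#' @param spec The same [scene_spec()].
#' @return A `synthetic_scene`: list with `image`, `gt_boxes` (tight boxes,
#'   parent 0-based half-open coordinates) and `spec`.
#' @export
place_birds <- function(background, spec) {
  .assert(inherits(spec, "scene_spec"), "spec must be a scene_spec",
          class = "skyfilter_invalid_spec")
  h <- spec$height_px; w <- spec$width_px
  .assert(all(dim(background) == c(h, w)),
          "background dimensions do not match spec",
          class = "skyfilter_invalid_spec")
  L <- bird_footprint_px(spec)
  .assert(L <= min(h, w),
          sprintf("bird footprint (%d px) exceeds image size", L),
          class = "skyfilter_invalid_spec")
  img <- background
  gt <- empty_boxes()
  if (spec$n_birds == 0)
    return(structure(list(image = img, gt_boxes = gt, spec = spec),
                     class = "synthetic_scene"))
  bg_mean <- mean(background)
  sgn <- if (spec$bird_polarity == "dark") -1 else 1
  target <- clamp01(bg_mean + sgn * spec$bird_contrast)
  a <- L / 2
  with_seed(.derive_seed(spec$seed, 2L), {
    for (i in seq_len(spec$n_birds)) {
      for (try in 1:50) {
        ratio <- stats::runif(1, 0.35, 0.65)
        theta <- stats::runif(1, 0, pi)
        b <- ratio * a
        # half-extent of the rotated ellipse along x and y
        ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
        ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
        cx <- stats::runif(1, ex + 1, w - ex - 1)
        cy <- stats::runif(1, ey + 1, h - ey - 1)
        xs <- floor(cx - ex):ceiling(cx + ex)
        ys <- floor(cy - ey):ceiling(cy + ey)
        xs <- xs[xs >= 0 & xs < w]; ys <- ys[ys >= 0 & ys < h]
        dx <- outer(rep(1, length(ys)), xs + 0.5 - cx)
        dy <- outer(ys + 0.5 - cy, rep(1, length(xs)))
        u <- (dx * cos(theta) + dy * sin(theta)) / a
        v <- (-dx * sin(theta) + dy * cos(theta)) / b
        inside <- u * u + v * v <= 1
        if (!any(inside)) next
        px <- which(inside, arr.ind = TRUE)
        bx0 <- min(xs[px[, 2]]); bx1 <- max(xs[px[, 2]]) + 1
        by0 <- min(ys[px[, 1]]); by1 <- max(ys[px[, 1]]) + 1
        cand <- boxes(bx0, by0, bx1, by1)
        if (nrow(gt) && max(iou_matrix(cand, gt)) > 0.1) next
        jit <- matrix(stats::rnorm(length(ys) * length(xs), 0, .BIRD_JITTER_SD),
                      length(ys), length(xs))
        block <- img[ys + 1, xs + 1, drop = FALSE]
        block[inside] <- clamp01(target + jit[inside])
        img[ys + 1, xs + 1] <- block
        gt <- rbind(gt, cand)
        break
      }
    }
  })
  structure(list(image = img, gt_boxes = gt, spec = spec),
            class = "synthetic_scene")
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: [generate_background()] followed by [place_birds()].
#'
#' @inheritParams generate_background
#' @return A `synthetic_scene` (see [place_birds()]).
#' @export
generate_scene <- function(spec) place_birds(generate_background(spec), spec)

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %dx%d px, %d ground-truth boxes\n",
              ncol(x$image), nrow(x$image), nrow(x$gt_boxes)))
  invisible(x)
}

#' Loosen tight boxes to emulate hand-drawn annotations
#'
#' Manual annotation boxes are usually padded well beyond the bird they
#' enclose; the bootstrap refiner exists to undo that. This helper
#' manufactures such loose boxes from tight ground truth: each side of each
#' box moves outward by an independent uniform fraction of the box's own
#' width/height drawn from `pad_frac_range`, then the box is clipped to the
#' image bounds if `image_size` is given.
#'
#' @param gt_boxes Box data frame (tight boxes).
#' @param pad_frac_range Length-2 numeric, `0 <= low <= high`; per-side pad
#'   fraction range.
#' @param seed Integer seed.
#' @param image_size Optional `c(width, height)` to clip against.
#' @return Box data frame in the same row order as the input.
#' @export
loosen_boxes <- function(gt_boxes, pad_frac_range, seed, image_size = NULL) {
  validate_boxes(gt_boxes)
  .assert(is.numeric(pad_frac_range) && length(pad_frac_range) == 2 &&
          all(is.finite(pad_frac_range)) && pad_frac_range[1] >= 0 &&
          pad_frac_range[1] <= pad_frac_range[2],
          "pad_frac_range must be 0 <= low <= high",
          class = "skyfilter_invalid_argument")
  n <- nrow(gt_boxes)
  if (!n) return(gt_boxes)
  with_seed(.derive_seed(seed, 3L), {
    pads <- matrix(stats::runif(4 * n, pad_frac_range[1], pad_frac_range[2]),
                   n, 4)
    w <- gt_boxes$x1 - gt_boxes$x0; h <- gt_boxes$y1 - gt_boxes$y0
    out <- gt_boxes
    out$x0 <- gt_boxes$x0 - pads[, 1] * w
    out$x1 <- gt_boxes$x1 + pads[, 2] * w
    out$y0 <- gt_boxes$y0 - pads[, 3] * h
    out$y1 <- gt_boxes$y1 + pads[, 4] * h
    if (!is.null(image_size))
      out <- clip_boxes(out, image_size[1], image_size[2])
    out
  })
}

#' Write a synthetic dataset to disk
#'
#' Renders each spec to a PNG, and writes COCO-style annotation files for
#' both the tight ground-truth boxes and a loosened copy (emulating manual
#' annotation), plus a CSV manifest carrying per-image GSD and split
#' assignment. Output is fully reproducible from the specs' seeds; no
#' timestamps are written.
#'
#' @param specs List of [scene_spec()] objects.
#' @param out_dir Output directory (created if needed).
#' @param split Character vector of split names, recycled over specs.
#' @param loose_pad Pad-fraction range passed to [loosen_boxes()].
#' @return Invisibly, a list with the manifest data frame and file paths.
#' @export
generate_dataset <- function(specs, out_dir, split = "train",
                             loose_pad = c(0.2, 0.4)) {
  .assert(length(specs) > 0, "need at least one scene_spec")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  .assert(ok, sprintf("cannot create output directory '%s'", out_dir),
          class = "skyfilter_io_error")
  split <- rep_len(as.character(split), length(specs))
  imgs <- data.frame(id = integer(), file_name = character(),
                     width = integer(), height = integer())
  tight <- loose <- data.frame(id = integer(), image_id = integer(),
                               category_id = integer(), x0 = numeric(),
                               y0 = numeric(), x1 = numeric(), y1 = numeric())
  man <- data.frame(image_id = integer(), file_name = character(),
                    gsd_cm = numeric(), split = character(),
                    n_birds = integer())
  ann_id <- 0L
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    .assert(inherits(sp, "scene_spec"), "specs must be scene_spec objects")
    scn <- generate_scene(sp)
    fn <- sprintf("img_%04d.png", i)
    path <- file.path(out_dir, fn)
    res <- tryCatch(png::writePNG(scn$image, path), error = function(e) e)
    .assert(!inherits(res, "error"),
            sprintf("failed to write image '%s': %s", path,
                    conditionMessage(if (inherits(res, "error")) res else
                                     simpleError(""))),
            class = "skyfilter_io_error")
    imgs <- rbind(imgs, data.frame(id = i, file_name = fn,
                                   width = sp$width_px,
                                   height = sp$height_px))
    gtb <- scn$gt_boxes
    if (nrow(gtb)) {
      ids <- ann_id + seq_len(nrow(gtb)); ann_id <- ann_id + nrow(gtb)
      tight <- rbind(tight, data.frame(id = ids, image_id = i,
                                       category_id = 1L, gtb))
      lb <- loosen_boxes(gtb, loose_pad, seed = .derive_seed(sp$seed, 4L),
                         image_size = c(sp$width_px, sp$height_px))
      loose <- rbind(loose, data.frame(id = ids, image_id = i,
                                       category_id = 1L, lb))
    }
    man <- rbind(man, data.frame(image_id = i, file_name = fn,
                                 gsd_cm = sp$gsd_cm, split = split[i],
                                 n_birds = nrow(gtb)))
  }
  cats <- data.frame(id = 1L, name = "bird")
  paths <- list(
    tight = file.path(out_dir, "annotations_tight.json"),
    loose = file.path(out_dir, "annotations_loose.json"),
    manifest = file.path(out_dir, "manifest.csv"))
  write_coco(annotation_set(tight, imgs, cats), paths$tight)
  write_coco(annotation_set(loose, imgs, cats), paths$loose)
  utils::write.csv(man, paths$manifest, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = man, paths = paths, dir = out_dir))
}
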