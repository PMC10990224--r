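#' Annotation sets
#'
#' Ground-truth bounding boxes for a collection of images, mirroring the
#' COCO object-detection layout: an annotation table (one row per box), an
#' image table and a category table. Boxes are stored in the package's
#' internal half-open `[x0, x1) x [y0, y1)` convention; conversion to and
#' from COCO's `[x, y, width, height]` happens only in [read_coco()] and
#' [write_coco()].
#'
#' @param annotations Data frame with columns `id`, `image_id`,
#'   `category_id`, `x0`, `y0`, `x1`, `y1`.
#' @param images Data frame with columns `id`, `file_name`, `width`,
#'   `height`.
#' @param categories Data frame with columns `id`, `name`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, images, categories) {
  .assert(is.data.frame(annotations) &&
          all(c("id", "image_id", "category_id", "x0", "y0", "x1", "y1")
              %in% names(annotations)),
          "annotations need id, image_id, category_id, x0, y0, x1, y1")
  .assert(is.data.frame(images) &&
          all(c("id", "file_name", "width", "height") %in% names(images)),
          "images need id, file_name, width, height")
  .assert(is.data.frame(categories) &&
          all(c("id", "name") %in% names(categories)),
          "categories need id, name")
  if (nrow(annotations)) {
    bad <- which(annotations$x1 < annotations$x0 |
                 annotations$y1 < annotations$y0 |
                 (annotations$x1 - annotations$x0) *
                 (annotations$y1 - annotations$y0) < 0)
    .assert(length(bad) == 0,
            sprintf("annotation(s) with negative extent at record(s): %s",
                    paste(bad, collapse = ", ")))
    .assert(all(annotations$image_id %in% images$id),
            "annotation references unknown image id")
  }
  structure(list(annotations = annotations, images = images,
                 categories = categories), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d boxes over %d images, %d categories\n",
              nrow(x$annotations), nrow(x$images), nrow(x$categories)))
  invisible(x)
}

# Boxes of one image as a box data frame.
annotations_for_image <- function(aset, image_id) {
  a <- aset$annotations[aset$annotations$image_id == image_id, , drop = FALSE]
  boxes(a$x0, a$y0, a$x1, a$y1)
}

#' Read / write COCO-style object-detection annotations
#'
#' The dialect is the standard COCO layout (`images`, `annotations`,
#' `categories`), with `bbox = [x, y, width, height]` in 0-based pixel
#' units, top-left origin. The round trip `read_coco(write_coco(x))` is the
#' identity on box geometry, ids and categories. No timestamps or `info`
#' blocks are written, so regeneration is byte-identical.
#'
#' @param aset An [annotation_set()].
#' @param path File path.
#' @return `read_coco` returns an [annotation_set()]; `write_coco` returns
#'   `path` invisibly.
#' @export
read_coco <- function(path) {
  .assert(file.exists(path), sprintf("no such file: '%s'", path),
          class = "skyfilter_io_error")
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                error = function(e)
                  stop(errorCondition(
                    sprintf("malformed COCO JSON '%s': %s", path,
                            conditionMessage(e)),
                    class = c("skyfilter_parse_error", "error"))))
  imgs <- as.data.frame(j$images %||%
    data.frame(id = integer(), file_name = character(),
               width = integer(), height = integer()))
  cats <- as.data.frame(j$categories %||%
    data.frame(id = integer(), name = character()))
  anns <- j$annotations
  if (is.null(anns) || (is.data.frame(anns) && !nrow(anns)) ||
      (is.list(anns) && !length(anns))) {
    adf <- data.frame(id = integer(), image_id = integer(),
                      category_id = integer(), x0 = numeric(),
                      y0 = numeric(), x1 = numeric(), y1 = numeric())
  } else {
    bb <- anns$bbox
    if (is.list(bb)) bb <- do.call(rbind, bb)
    .assert(!is.null(bb) && ncol(bb) == 4, "annotation bbox must have 4 values",
            class = "skyfilter_parse_error")
    bad <- which(bb[, 3] < 0 | bb[, 4] < 0)
    .assert(length(bad) == 0,
            sprintf("negative bbox width/height at annotation record(s): %s",
                    paste(bad, collapse = ", ")),
            class = "skyfilter_parse_error")
    adf <- data.frame(id = anns$id, image_id = anns$image_id,
                      category_id = anns$category_id,
                      x0 = bb[, 1], y0 = bb[, 2],
                      x1 = bb[, 1] + bb[, 3], y1 = bb[, 2] + bb[, 4])
  }
  annotation_set(adf, imgs, cats)
}

#' @rdname read_coco
#' @export
write_coco <- function(aset, path) {
  .assert(inherits(aset, "annotation_set"), "aset must be an annotation_set")
  a <- aset$annotations
  ann_list <- lapply(seq_len(nrow(a)), function(i) list(
    id = a$id[i], image_id = a$image_id[i], category_id = a$category_id[i],
    bbox = c(a$x0[i], a$y0[i], a$x1[i] - a$x0[i], a$y1[i] - a$y0[i]),
    area = (a$x1[i] - a$x0[i]) * (a$y1[i] - a$y0[i]), iscrowd = 0L))
  img_list <- lapply(seq_len(nrow(aset$images)), function(i) list(
    id = aset$images$id[i], file_name = aset$images$file_name[i],
    width = aset$images$width[i], height = aset$images$height[i]))
  cat_list <- lapply(seq_len(nrow(aset$categories)), function(i) list(
    id = aset$categories$id[i], name = aset$categories$name[i]))
  jsonlite::write_json(list(images = img_list, annotations = ann_list,
                            categories = cat_list),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write detections as COCO-results-style JSON
#'
#' Detections are a data frame with `image_id`, box columns and `score`;
#' serialized as a flat array of `{image_id, bbox, score}` records.
#'
#' @param dets Detection data frame (`image_id, x0, y0, x1, y1, score`).
#' @param path File path.
#' @export
write_detections <- function(dets, path) {
  validate_boxes(dets)
  recs <- lapply(seq_len(nrow(dets)), function(i) list(
    image_id = dets$image_id[i],
    bbox = c(dets$x0[i], dets$y0[i], dets$x1[i] - dets$x0[i],
             dets$y1[i] - dets$y0[i]),
    score = dets$score[i], category_id = 1L))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  .assert(file.exists(path), sprintf("no such file: '%s'", path),
          class = "skyfilter_io_error")
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j) || !length(j))
    return(cbind(data.frame(image_id = integer()),
                 empty_boxes(score = TRUE)))
  bb <- j$bbox
  if (is.list(bb)) bb <- do.call(rbind, bb)
  data.frame(image_id = j$image_id, x0 = bb[, 1], y0 = bb[, 2],
             x1 = bb[, 1] + bb[, 3], y1 = bb[, 2] + bb[, 4],
             score = j$score)
}

#' Read a dataset manifest
#'
#' CSV with header `image_id,file_name,gsd_cm,split,n_birds`; GSD rides in
#' the manifest rather than in the COCO file, which has no standard field
#' for it.
#'
#' @param path Manifest CSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  .assert(file.exists(path), sprintf("no such file: '%s'", path),
          class = "skyfilter_io_error")
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("image_id", "file_name", "gsd_cm", "split", "n_birds")
              %in% names(man)),
          "manifest must have image_id,file_name,gsd_cm,split,n_birds",
          class = "skyfilter_parse_error")
  man
}

#' Read an image file as an intensity matrix
#'
#' Reads PNG (and TIFF when the `tiff` package is available), converting
#' RGB to luminance, returning a `[row = y, col = x]` matrix in `[0, 1]`.
#'
#' @param path Image path.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  .assert(file.exists(path), sprintf("no such file: '%s'", path),
          class = "skyfilter_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    .assert(requireNamespace("tiff", quietly = TRUE),
            "reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    stop(errorCondition(sprintf("unsupported image format '%s'", ext),
                        class = c("skyfilter_io_error", "error")))
  }
  if (length(dim(img)) == 3) {
    # luminance from the first three channels; alpha ignored
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  clamp01(img)
}

# ---------------------------------------------------------------------------
# Run configuration

.default_config <- function() list(
  tiling = list(
    train = list(window = 720L, stride = 540L),
    eval = list(window = 1440L, stride = 1080L, rescale = 960L)),
  filter = list(threshold = 0.5, backend = "small_cnn"),
  nms = list(iou = 0.5),
  blob = list(intensity_threshold = 0.9, dilation_factor = 12L,
              polarity = "dark_fg", contrast_enhance = "stretch",
              min_blob_px = 4L),
  hog = list(window = c(64L, 64L), cell = c(8L, 8L), block = c(2L, 2L),
             block_stride = c(8L, 8L), orientations = 9L),
  detect = list(score_threshold = 0.5, svm_cost = 1),
  eval = list(iou_grid = seq(0.5, 0.95, by = 0.05),
              gsd_bins = c(0.6, 1.2)),
  seed = 1L)

.merge_config <- function(defaults, user, path = character()) {
  for (k in names(user)) {
    .assert(k %in% names(defaults),
            sprintf("unknown config key '%s'",
                    paste(c(path, k), collapse = ".")),
            class = "skyfilter_config_error")
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      .assert(is.list(user[[k]]),
              sprintf("config key '%s' must be a mapping",
                      paste(c(path, k), collapse = ".")),
              class = "skyfilter_config_error")
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  ce <- "skyfilter_config_error"
  for (g in c("train", "eval")) {
    t <- cfg$tiling[[g]]
    .assert(t$stride > 0 && t$window > 0, "tiling window/stride must be > 0",
            class = ce)
    .assert(all(t$stride <= t$window),
            sprintf("tiling.%s: stride must not exceed window", g), class = ce)
  }
  .assert(cfg$nms$iou > 0 && cfg$nms$iou < 1, "nms.iou must be in (0,1)",
          class = ce)
  .assert(cfg$blob$intensity_threshold > 0 && cfg$blob$intensity_threshold < 1,
          "blob.intensity_threshold must be in (0,1)", class = ce)
  .assert(cfg$blob$dilation_factor >= 0, "blob.dilation_factor must be >= 0",
          class = ce)
  .assert(cfg$blob$polarity %in% c("dark_fg", "bright_fg"),
          "blob.polarity must be dark_fg or bright_fg", class = ce)
  .assert(cfg$blob$contrast_enhance %in% c("none", "stretch", "clahe"),
          "blob.contrast_enhance must be none, stretch or clahe", class = ce)
  .assert(cfg$filter$threshold > 0 && cfg$filter$threshold < 1,
          "filter.threshold must be in (0,1)", class = ce)
  .assert(all(cfg$eval$iou_grid > 0 & cfg$eval$iou_grid <= 1),
          "eval.iou_grid thresholds must be in (0,1]", class = ce)
  .assert(length(cfg$eval$gsd_bins) == 2 &&
          cfg$eval$gsd_bins[1] < cfg$eval$gsd_bins[2],
          "eval.gsd_bins must be two increasing edges", class = ce)
  cfg
}

#' Load a YAML run configuration
#'
#' Reads a YAML file, overlays it on the package defaults (sliding windows
#' 720/540 for training and 1440/1080 with a 1440-to-960 rescale for
#' evaluation; blob threshold 0.9 and dilation factor 12; GSD bin edges 0.6
#' and 1.2 cm), rejects unknown keys so typos fail loudly, and validates
#' ranges. An empty or absent file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet Suppress the resolved-config log line.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  cfg <- .default_config()
  if (!is.null(path)) {
    .assert(file.exists(path), sprintf("no such file: '%s'", path),
            class = "skyfilter_io_error")
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .merge_config(cfg, user)
  }
  cfg <- .validate_config(cfg)
  cfg <- structure(cfg, class = "run_config")
  if (!quiet) message("resolved config:\n", yaml::as.yaml(unclass(cfg)))
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
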