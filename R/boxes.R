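#' Bounding-box tables
#'
#' Boxes are stored as plain data frames with numeric columns `x0`, `y0`,
#' `x1`, `y1` (half-open pixel rectangles, 0-based, top-left origin) and
#' optional `score` and `label` columns. An empty table with the right
#' columns is a valid, empty box set.
#'
#' @param x0,y0,x1,y1 Numeric vectors of box edges; `x1 > x0`, `y1 > y0`.
#' @param score Optional numeric vector of detection scores.
#' @param label Optional character vector of category labels.
#' @return A data frame of boxes.
#' @export
#' @examples
#' boxes(0, 0, 10, 10)
boxes <- function(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                  y1 = numeric(), score = NULL, label = NULL) {
  df <- data.frame(x0 = as.numeric(x0), y0 = as.numeric(y0),
                   x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(label)) df$label <- as.character(label)
  validate_boxes(df)
  df
}

#' @rdname boxes
#' @param b A box data frame to validate.
#' @export
validate_boxes <- function(b) {
  .assert(is.data.frame(b), "boxes must be a data frame")
  .assert(all(c("x0", "y0", "x1", "y1") %in% names(b)),
          "boxes need columns x0, y0, x1, y1")
  if (nrow(b)) {
    .assert(all(is.finite(b$x0)) && all(is.finite(b$y0)) &&
            all(is.finite(b$x1)) && all(is.finite(b$y1)),
            "box coordinates must be finite")
    .assert(all(b$x1 > b$x0) && all(b$y1 > b$y0),
            "degenerate box: require x1 > x0 and y1 > y0")
    if (!is.null(b$score)) .assert(all(is.finite(b$score)),
                                   "box scores must be finite")
  }
  invisible(b)
}

empty_boxes <- function(score = FALSE, label = FALSE) {
  boxes(score = if (score) numeric() else NULL,
        label = if (label) character() else NULL)
}

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

#' Intersection over union of two boxes
#'
#' The true-positive gate of detection evaluation: intersection area divided
#' by union area of a predicted and a ground-truth box. Zero for disjoint
#' boxes, one iff identical, symmetric in its arguments.
#'
#' @param a,b Single-row box data frames (or lists with `x0,y0,x1,y1`).
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(boxes(0, 0, 10, 10), boxes(5, 0, 15, 10))  # 1/3
iou <- function(a, b) {
  .assert(a$x1 > a$x0 && a$y1 > a$y0 && b$x1 > b$x0 && b$y1 > b$y0,
          "degenerate box passed to iou()", class = "skyfilter_invalid_argument")
  iw <- min(a$x1, b$x1) - max(a$x0, b$x0)
  ih <- min(a$y1, b$y1) - max(a$y0, b$y0)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter)
}

# Pairwise IoU matrix between two box tables (rows of a x rows of b).
iou_matrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  iw <- outer(a$x1, b$x1, pmin) - outer(a$x0, b$x0, pmax)
  ih <- outer(a$y1, b$y1, pmin) - outer(a$y0, b$y0, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  un <- outer(box_area(a), box_area(b), `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

# Clip boxes to an image of the given size; drops nothing, callers that care
# about emptied boxes check areas afterwards.
clip_boxes <- function(b, width, height) {
  b$x0 <- pmax(0, pmin(b$x0, width)); b$x1 <- pmax(0, pmin(b$x1, width))
  b$y0 <- pmax(0, pmin(b$y0, height)); b$y1 <- pmax(0, pmin(b$y1, height))
  b
}
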