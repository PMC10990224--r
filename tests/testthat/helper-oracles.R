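# Independent oracles used to cross-check the package's implementations.
# Everything here is deliberately written as plain loops / brute force,
# sharing no code with the package internals.

# Flood-fill connected-component count and labeling (explicit stack).
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        y <- p[1] + nb[k, 1]; x <- p[2] + nb[k, 2]
        if (y >= 1 && y <= h && x >= 1 && x <= w &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          stack[[length(stack) + 1L]] <- c(y, x)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# Direct area-arithmetic IoU for two boxes given as c(x0, y0, x1, y1).
brute_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

# Brute-force greedy matching + 101-point interpolated AP sweep for one
# pool of images. dets/gts: lists (by image) of matrices with columns
# x0,y0,x1,y1(,score). Returns the AP and the final recall.
brute_ap_sweep <- function(dets, gts, thr) {
  all_scores <- c(); all_tp <- c(); n_gt <- 0
  for (im in seq_along(dets)) {
    d <- dets[[im]]; g <- gts[[im]]
    n_gt <- n_gt + nrow(g)
    if (!nrow(d)) next
    ord <- order(-d[, "score"])
    used <- rep(FALSE, nrow(g))
    for (i in ord) {
      best <- 0; best_j <- 0
      if (nrow(g)) for (j in seq_len(nrow(g))) {
        if (used[j]) next
        v <- brute_iou(d[i, 1:4], g[j, 1:4])
        if (v > best) { best <- v; best_j <- j }
      }
      hit <- best_j > 0 && best >= thr
      if (hit) used[best_j] <- TRUE
      all_scores <- c(all_scores, d[i, "score"])
      all_tp <- c(all_tp, hit)
    }
  }
  if (n_gt == 0) return(list(ap = NA_real_, recall = NA_real_))
  if (!length(all_scores)) return(list(ap = 0, recall = 0))
  ord <- order(-all_scores)
  tp <- all_tp[ord]
  ap_sum <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best_p <- 0
    ctp <- 0
    for (k in seq_along(tp)) {
      ctp <- ctp + tp[k]
      if (ctp / n_gt >= r - 1e-12) best_p <- max(best_p, ctp / k)
    }
    ap_sum <- ap_sum + best_p
  }
  list(ap = ap_sum / 101, recall = sum(tp) / n_gt)
}

# Reference COCO-style evaluator: the accumulate() algorithm of the COCO
# detection benchmark (precision envelope by reverse running maximum,
# sampled at 101 recall thresholds), independent of both the package and
# brute_ap_sweep's direct scan.
coco_reference_ap <- function(dets, gts, thr) {
  scores <- c(); matched <- c(); n_gt <- 0
  for (im in seq_along(dets)) {
    d <- dets[[im]]; g <- gts[[im]]
    n_gt <- n_gt + nrow(g)
    if (!nrow(d)) next
    ord <- order(-d[, "score"])
    gt_used <- rep(FALSE, max(1, nrow(g)))
    for (i in ord) {
      m <- -1
      iou_best <- thr - 1e-10
      if (nrow(g)) for (j in seq_len(nrow(g))) {
        if (gt_used[j]) next
        v <- brute_iou(d[i, 1:4], g[j, 1:4])
        if (v > iou_best) { iou_best <- v; m <- j }
      }
      if (m > 0) gt_used[m] <- TRUE
      scores <- c(scores, d[i, "score"])
      matched <- c(matched, m > 0)
    }
  }
  if (n_gt == 0) return(NA_real_)
  if (!length(scores)) return(0)
  ord <- order(-scores)
  tps <- cumsum(matched[ord])
  fps <- cumsum(!matched[ord])
  rc <- tps / n_gt
  pr <- tps / (tps + fps)
  # envelope: pr[i] = max(pr[i:end])
  for (i in rev(seq_len(length(pr) - 1))) pr[i] <- max(pr[i], pr[i + 1])
  q <- numeric(101)
  rec_thrs <- seq(0, 1, by = 0.01)
  idx <- findInterval(rec_thrs - 1e-12, c(0, rc), left.open = FALSE)
  for (k in seq_along(rec_thrs)) {
    # first index with recall >= threshold
    pos <- which(rc >= rec_thrs[k] - 1e-12)
    q[k] <- if (length(pos)) pr[pos[1]] else 0
  }
  mean(q)
}

# Random box tables for property tests.
random_box_df <- function(n, width = 100, height = 100, scored = TRUE) {
  if (n == 0) {
    b <- skyfilter::boxes(score = if (scored) numeric() else NULL)
    return(b)
  }
  x0 <- runif(n, 0, width - 5); y0 <- runif(n, 0, height - 5)
  w <- runif(n, 2, 25); h <- runif(n, 2, 25)
  skyfilter::boxes(x0, y0, pmin(x0 + w, width), pmin(y0 + h, height),
                   score = if (scored) runif(n) else NULL)
}

box_df_to_mat <- function(b) {
  m <- cbind(x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1)
  if (!is.null(b$score)) m <- cbind(m, score = b$score)
  m
}
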