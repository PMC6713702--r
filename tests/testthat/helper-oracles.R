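# Independent oracles used to verify the package's geometry operations.

# IoU by explicit pixel rasterization: a box covers the integer pixels
# (x, y) with xmin <= x < xmax, ymin <= y < ymax.
raster_iou <- function(a, b) {
  px <- function(bx) {
    g <- expand.grid(x = seq.int(bx$xmin, bx$xmax - 1),
                     y = seq.int(bx$ymin, bx$ymax - 1))
    paste(g$x, g$y)
  }
  pa <- px(a); pb <- px(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Non-maximum suppression restated independently: repeatedly promote the
# highest-priority remaining detection and delete every remaining one that
# overlaps it at or above the threshold.
brute_nms <- function(dets, thr) {
  remaining <- dets[order(-dets$score, dets$xmin, dets$ymin, dets$xmax, dets$ymax),
                    , drop = FALSE]
  kept <- remaining[0, , drop = FALSE]
  while (nrow(remaining) > 0) {
    top <- remaining[1, , drop = FALSE]
    kept <- rbind(kept, top)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) > 0) {
      ious <- as.numeric(iou_matrix(top, remaining))
      remaining <- remaining[ious < thr, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  kept
}

# Maximum-cardinality bipartite matching by exhaustive recursion over the
# candidate pair list (feasible for <= ~12 candidate pairs).
max_matching_size <- function(a, b, thr) {
  iom <- iou_matrix(a, b)
  cand <- which(iom >= thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  best <- 0L
  recurse <- function(k, used_a, used_b, size) {
    if (k > nrow(cand)) { best <<- max(best, size); return(invisible()) }
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!(i %in% used_a) && !(j %in% used_b))
      recurse(k + 1, c(used_a, i), c(used_b, j), size + 1L)
    recurse(k + 1, used_a, used_b, size)
  }
  recurse(1L, integer(0), integer(0), 0L)
  best
}

random_boxes <- function(n, limit = 64, max_side = 20) {
  xmin <- sample.int(limit - 2, n, replace = TRUE) - 1
  ymin <- sample.int(limit - 2, n, replace = TRUE) - 1
  w <- pmin(sample.int(max_side, n, replace = TRUE), limit - xmin)
  h <- pmin(sample.int(max_side, n, replace = TRUE), limit - ymin)
  boxes(xmin, ymin, xmin + w, ymin + h)
}

easy_scene_spec <- function(seed, width = 600, height = 450, n = 6) {
  scene_spec(width = width, height = height, n_organoids = n,
             overlap_allowed = FALSE, defocus_fraction = 0,
             illumination_gradient = 0.1, noise_sigma = 0.02, seed = seed)
}
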