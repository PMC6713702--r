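#' Construct a set of bounding boxes
#'
#' Boxes are axis-aligned pixel rectangles with a 0-based, half-open
#' convention: a box covers pixel columns `[xmin, xmax)` and rows
#' `[ymin, ymax)`, with the origin at the top-left corner of the image.
#' Under this convention widths are exactly `xmax - xmin` and areas are
#' additive across adjacent boxes.
#'
#' @param xmin,ymin,xmax,ymax Numeric vectors of equal length (recycled),
#'   pixel coordinates. `xmax > xmin` and `ymax > ymin` are required.
#' @return A `data.frame` with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @examples
#' boxes(0, 0, 10, 10)
#' boxes(c(0, 5), c(0, 0), c(10, 15), c(10, 10))
#' @export
boxes <- function(xmin, ymin, xmax, ymax) {
  b <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                  xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  validate_boxes(b)
  b
}

#' Validate a box data frame
#'
#' Checks the box invariants: required columns present, finite coordinates,
#' strictly positive width and height.
#'
#' @param b A data frame with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @param allow_empty If `TRUE`, a zero-row data frame passes.
#' @return `b`, invisibly. Errors on violation.
#' @export
validate_boxes <- function(b, allow_empty = TRUE) {
  cols <- c("xmin", "ymin", "xmax", "ymax")
  if (!is.data.frame(b) || !all(cols %in% names(b)))
    stop("boxes must be a data.frame with columns xmin, ymin, xmax, ymax")
  if (nrow(b) == 0) {
    if (!allow_empty) stop("empty box set not allowed here")
    return(invisible(b))
  }
  m <- as.matrix(b[cols])
  if (!all(is.finite(m))) stop("box coordinates must be finite")
  if (any(b$xmax <= b$xmin) || any(b$ymax <= b$ymin))
    stop("degenerate box: xmax must exceed xmin and ymax must exceed ymin")
  invisible(b)
}

#' An empty box set
#' @return A zero-row box data frame.
#' @export
empty_boxes <- function() {
  data.frame(xmin = numeric(0), ymin = numeric(0),
             xmax = numeric(0), ymax = numeric(0))
}

#' Construct detections
#'
#' A detection is a box plus a confidence score in `[0, 1]` and a class
#' label (only `"organoid"` is used in this package).
#'
#' @param b Box data frame (see [boxes()]).
#' @param score Numeric vector of confidences in `[0, 1]`, recycled.
#' @param label Class label, recycled.
#' @return A `data.frame` with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `score`, `label`.
#' @export
detections <- function(b, score = 1, label = "organoid") {
  validate_boxes(b)
  score <- rep_len(as.numeric(score), nrow(b))
  if (nrow(b) > 0 && (any(!is.finite(score)) || any(score < 0) || any(score > 1)))
    stop("detection scores must lie in [0, 1]")
  data.frame(b[c("xmin", "ymin", "xmax", "ymax")],
             score = score, label = rep_len(as.character(label), nrow(b)))
}

#' An empty detection set
#' @return A zero-row detection data frame.
#' @export
empty_detections <- function() {
  data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
             ymax = numeric(0), score = numeric(0), label = character(0))
}

box_area <- function(b) (b$xmax - b$xmin) * (b$ymax - b$ymin)

#' Intersection over union of two boxes
#'
#' Computed on half-open pixel areas: the intersection area divided by the
#' union area. Symmetric; 0 for disjoint boxes; 1 only for identical boxes.
#'
#' @param a,b Single-row box data frames (or anything [boxes()] accepts with
#'   one row).
#' @return A number in `[0, 1]`.
#' @examples
#' iou(boxes(0, 0, 10, 10), boxes(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(a, b) {
  validate_boxes(a, allow_empty = FALSE)
  validate_boxes(b, allow_empty = FALSE)
  if (nrow(a) != 1 || nrow(b) != 1) stop("iou() takes single boxes; see iou_matrix()")
  iou_matrix(a, b)[1, 1]
}

#' Cross IoU matrix between two box sets
#'
#' @param a,b Box data frames with `m` and `n` rows.
#' @return An `m x n` numeric matrix of pairwise IoU values.
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  m <- nrow(a); n <- nrow(b)
  if (m == 0 || n == 0) return(matrix(numeric(0), m, n))
  ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- ix * iy
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

#' Greedy IoU matching between two box sets
#'
#' Considers every cross pair with IoU at or above `iou_threshold` and
#' accepts pairs greedily in descending IoU order; each box is matched at
#' most once. Ties in IoU are broken deterministically by lower index in
#' `a`, then lower index in `b`.
#'
#' @param a,b Box data frames.
#' @param iou_threshold Minimum IoU for a pair to be matchable, in `(0, 1]`.
#' @return A list of class `box_matching` with elements `pairs` (data frame
#'   with columns `a`, `b`, `iou`; indices are 1-based row numbers),
#'   `unmatched_a` and `unmatched_b` (integer vectors).
#' @export
greedy_match_boxes <- function(a, b, iou_threshold) {
  validate_boxes(a); validate_boxes(b)
  stopifnot(length(iou_threshold) == 1, iou_threshold > 0, iou_threshold <= 1)
  m <- nrow(a); n <- nrow(b)
  pairs <- data.frame(a = integer(0), b = integer(0), iou = numeric(0))
  if (m > 0 && n > 0) {
    iom <- iou_matrix(a, b)
    cand <- which(iom >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ious <- iom[cand]
      # descending IoU, then lower a index, then lower b index
      ord <- order(-ious, cand[, 1], cand[, 2])
      used_a <- logical(m); used_b <- logical(n)
      keep <- logical(length(ord))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      sel <- which(keep)
      sel <- sel[order(-ious[sel], cand[sel, 1], cand[sel, 2])]
      pairs <- data.frame(a = as.integer(cand[sel, 1]),
                          b = as.integer(cand[sel, 2]),
                          iou = ious[sel])
    }
  }
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(m), pairs$a),
                 unmatched_b = setdiff(seq_len(n), pairs$b)),
            class = "box_matching")
}

#' Clip boxes to an image frame
#'
#' Clamps coordinates into `[0, width] x [0, height]`. Errors if any box
#' becomes empty (zero width or height) after clamping, unless
#' `drop_empty = TRUE`, in which case emptied boxes are dropped.
#'
#' @param b Box (or detection) data frame.
#' @param width,height Frame dimensions in pixels, positive.
#' @param drop_empty Drop boxes emptied by clipping instead of erroring.
#' @return The clipped data frame (other columns preserved).
#' @export
clip_boxes <- function(b, width, height, drop_empty = FALSE) {
  validate_boxes(b)
  stopifnot(width > 0, height > 0)
  if (nrow(b) == 0) return(b)
  out <- b
  out$xmin <- pmax(0, pmin(out$xmin, width))
  out$xmax <- pmax(0, pmin(out$xmax, width))
  out$ymin <- pmax(0, pmin(out$ymin, height))
  out$ymax <- pmax(0, pmin(out$ymax, height))
  empty <- out$xmax <= out$xmin | out$ymax <= out$ymin
  if (any(empty) && !drop_empty)
    stop("box entirely outside the frame after clipping")
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  out
}
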