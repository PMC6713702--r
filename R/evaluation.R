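#' Per-image detection precision (fraction of ground truth found)
#'
#' The evaluation metric asks what fraction of the ground-truth (manually
#' annotated) bounding boxes were found by the detector: a predicted box
#' counts as finding a ground-truth box when their IoU is at least
#' `match_iou` (default 0.7). With two ground-truth organoids and one of
#' them found the value is 0.5; with both found it is 1.0. Matching is
#' one-to-one (greedy, descending IoU), so duplicate predictions of one
#' organoid count once, and unmatched predictions (false positives) do not
#' enter the value at all — under the standard taxonomy this is a recall.
#'
#' @param gt Ground-truth box data frame.
#' @param pred Predicted detection (or box) data frame.
#' @param match_iou Match threshold in `(0, 1]`, default 0.7.
#' @return `|matched gt| / |gt|`, or `NA` when the image has no
#'   ground-truth boxes (such images are excluded from the mean by
#'   [mean_average_precision()]).
#' @export
per_image_precision <- function(gt, pred, match_iou = 0.7) {
  stopifnot(match_iou > 0, match_iou <= 1)
  validate_boxes(gt)
  validate_boxes(pred)
  if (nrow(gt) == 0) return(NA_real_)
  if (nrow(pred) == 0) return(0)
  m <- greedy_match_boxes(gt, pred, match_iou)
  nrow(m$pairs) / nrow(gt)
}

#' Mean average precision over a test set (recall-style)
#'
#' The per-image precision of [per_image_precision()] averaged over all
#' images with at least one ground-truth box; images with empty ground
#' truth are excluded (their precision is undefined).
#'
#' @param dataset A list of images, each a list with elements `gt`
#'   (ground-truth boxes) and `pred` (predicted detections); optionally
#'   named by image id.
#' @param match_iou Match threshold, default 0.7.
#' @return A list of class `evaluation_report` with `per_image` (named
#'   numeric vector, `NA` for images without ground truth), `map_value`,
#'   `n_images` (evaluated images), `n_gt_boxes`, and `match_iou`.
#' @export
mean_average_precision <- function(dataset, match_iou = 0.7) {
  stopifnot(is.list(dataset), length(dataset) >= 1)
  ids <- names(dataset)
  if (is.null(ids) || any(ids == ""))
    ids <- sprintf("image_%03d", seq_along(dataset))
  per <- vapply(dataset, function(d)
    per_image_precision(d$gt, d$pred, match_iou), numeric(1))
  names(per) <- ids
  ok <- !is.na(per)
  if (!any(ok)) stop("no evaluable images: every image has empty ground truth")
  structure(list(per_image = per, map_value = mean(per[ok]),
                 n_images = sum(ok),
                 n_gt_boxes = sum(vapply(dataset, function(d) nrow(d$gt), numeric(1))),
                 match_iou = match_iou),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: mAP %.4f over %d images (%d ground-truth boxes, match IoU %.2f)\n",
              x$map_value, x$n_images, x$n_gt_boxes, x$match_iou))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per image (`image,precision`; `NA` precision for images without
#' ground truth) followed by a summary row `mAP,<value>`.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- data.frame(image = names(report$per_image),
                   precision = unname(report$per_image))
  df <- rbind(df, data.frame(image = "mAP", precision = report$map_value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
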