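#' Configure the reference blob detector
#'
#' Parameters of [reference_blob_detect()], the classical band-pass blob
#' detector bundled with the package. It serves as a deterministic,
#' CPU-only detector backend for spherical organoid-like blobs; a trained
#' neural detector can be plugged into the same [detector contract][detect]
#' instead.
#'
#' @param smoothing_sigma_fine,smoothing_sigma_coarse Gaussian sigmas
#'   (pixels) of the band-pass pair; fine must be smaller than coarse.
#'   Defaults 2 and 15 px bracket organoid radii of roughly 15-60 px.
#' @param threshold_mode `"otsu"` (adaptive) or `"fixed"`.
#' @param fixed_threshold Band-pass response threshold in `[0, 1]`, used
#'   when `threshold_mode = "fixed"`.
#' @param min_area Minimum component area in pixels squared.
#' @param focus_threshold Minimum mean gradient magnitude (intensity units
#'   per pixel) along a component's boundary; components blurrier than this
#'   are discarded, mirroring the annotation rule that only in-focus
#'   organoids are boxed.
#' @param score_floor Minimum confidence score for an emitted detection.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(smoothing_sigma_fine = 2, smoothing_sigma_coarse = 15,
                            threshold_mode = c("otsu", "fixed"),
                            fixed_threshold = 0.05, min_area = 150,
                            focus_threshold = 0.02, score_floor = 0.2) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(smoothing_sigma_fine > 0,
            smoothing_sigma_fine < smoothing_sigma_coarse,
            fixed_threshold >= 0, fixed_threshold <= 1, min_area > 0,
            focus_threshold >= 0, score_floor >= 0, score_floor <= 1)
  structure(list(smoothing_sigma_fine = smoothing_sigma_fine,
                 smoothing_sigma_coarse = smoothing_sigma_coarse,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold, min_area = min_area,
                 focus_threshold = focus_threshold, score_floor = score_floor),
            class = "detector_config")
}

as_gray_matrix <- function(patch) {
  arr <- as.array(patch)
  if (length(dim(arr)) > 2) arr <- apply(arr, c(1, 2), mean)
  if (!all(is.finite(arr))) stop("patch contains non-finite pixel values")
  arr
}

#' The per-patch detector contract
#'
#' A detector backend is any function `f(patch, origin)` that maps a square
#' `patch_size x patch_size` intensity array to a detection data frame (see
#' [detections()]) in *tile-local* coordinates: every box must satisfy
#' `0 <= xmin < xmax <= patch_size` (and likewise in y) and every score must
#' lie in `[0, 1]`. `origin` is the tile's 0-based top-left corner in the
#' full image; most backends ignore it (the oracle backend uses it to look
#' up ground truth). Backends must be deterministic for a fixed patch and
#' configuration.
#'
#' @param dets Candidate detector output.
#' @param patch_size Tile edge in pixels.
#' @return `dets`, invisibly; errors if the contract is violated.
#' @export
validate_detector_output <- function(dets, patch_size) {
  validate_boxes(dets)
  if (nrow(dets) == 0) return(invisible(dets))
  if (any(dets$xmin < 0 | dets$ymin < 0 |
          dets$xmax > patch_size | dets$ymax > patch_size))
    stop("detector contract violation: box outside the patch frame")
  if (any(dets$score < 0 | dets$score > 1))
    stop("detector contract violation: score outside [0, 1]")
  invisible(dets)
}

#' Classical band-pass blob detection on one patch
#'
#' A deterministic reference detector for dark, roughly elliptical blobs on
#' a bright background. Pipeline: (1) band-pass response on the inverted
#' patch, `smooth(sigma_fine) - smooth(sigma_coarse)`; (2) binarization
#' (Otsu on the normalized response, or a fixed response threshold);
#' (3) morphological closing and hole filling; (4) connected components;
#' (5) area filter; (6) focus filter by mean boundary-gradient magnitude;
#' (7) tight boxes from the component re-thresholded at half its peak
#' response (removing the dilation introduced by the fine smoothing), with
#' score = component mean response / patch maximum response, clamped to
#' `[0, 1]`; detections below `score_floor` are dropped.
#'
#' @param patch Square intensity array (values in `[0, 1]`; normalized
#'   internally if not).
#' @param config A [detector_config()].
#' @param origin Ignored; present to satisfy the [detector contract][validate_detector_output].
#' @return A detection data frame in tile-local coordinates, ordered by
#'   descending score then lexicographic box coordinates.
#' @export
reference_blob_detect <- function(patch, config = detector_config(), origin = c(0, 0)) {
  stopifnot(inherits(config, "detector_config"))
  p <- as_gray_matrix(patch)
  if (dim(p)[1] != dim(p)[2]) stop("detector patch must be square")
  rng <- range(p)
  if (rng[2] > 1 || rng[1] < 0) p <- (p - rng[1]) / max(rng[2] - rng[1], 1e-12)
  inv <- 1 - p
  resp <- EBImage::gblur(inv, sigma = config$smoothing_sigma_fine, boundary = "replicate") -
          EBImage::gblur(inv, sigma = config$smoothing_sigma_coarse, boundary = "replicate")
  if (diff(range(resp)) < 1e-4) return(empty_detections())
  if (config$threshold_mode == "otsu") {
    rn <- (resp - min(resp)) / diff(range(resp))
    mask <- rn > EBImage::otsu(EBImage::Image(rn), range = c(0, 1))
  } else {
    mask <- resp > config$fixed_threshold
  }
  mask <- EBImage::fillHull(EBImage::closing(EBImage::Image(mask * 1),
                                             EBImage::makeBrush(5, "disc")))
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(empty_detections())
  labv <- as.integer(lab)
  areas <- tabulate(labv, nbins = nlab)
  # gradient magnitude of the original patch (central differences)
  n <- dim(p)[1]
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[2:(n - 1), ] <- (p[3:n, ] - p[1:(n - 2), ]) / 2
  gy[, 2:(n - 1)] <- (p[, 3:n] - p[, 1:(n - 2)]) / 2
  grad <- sqrt(gx^2 + gy^2)
  interior <- EBImage::erode(lab > 0, EBImage::makeBrush(3, "box"))
  boundary <- (lab > 0) & !interior
  max_resp <- max(resp)
  out <- empty_detections()
  for (k in seq_len(nlab)) {
    if (areas[k] < config$min_area) next
    comp <- lab == k
    bnd <- comp & boundary
    if (sum(bnd) == 0) next
    if (mean(grad[bnd]) < config$focus_threshold) next
    core <- comp & (resp >= 0.5 * max(resp[comp]))
    if (!any(core)) core <- comp
    ix <- which(rowSums(core) > 0); iy <- which(colSums(core) > 0)
    score <- min(max(mean(resp[comp]) / max_resp, 0), 1)
    if (score < config$score_floor) next
    out <- rbind(out, data.frame(xmin = ix[1] - 1, ymin = iy[1] - 1,
                                 xmax = ix[length(ix)], ymax = iy[length(iy)],
                                 score = score, label = "organoid"))
  }
  if (nrow(out) > 1) {
    out <- out[order(-out$score, out$xmin, out$ymin, out$xmax, out$ymax), ]
    rownames(out) <- NULL
  }
  out
}

#' Detector backend constructors
#'
#' `make_reference_detector()` wraps [reference_blob_detect()] with a fixed
#' configuration. `make_oracle_detector()` builds the testing backend that
#' returns the known ground-truth boxes clipped to each tile (score 1);
#' it needs the tile origin to translate global ground truth into the tile
#' frame. `make_adapter_detector()` wraps an external command implementing
#' the same contract out of process: for each tile the patch is written as
#' an 8-bit PNG, the command is invoked as `command patch.png out.csv`, and
#' tile-local detections are read back from the CSV (columns
#' `xmin,ymin,xmax,ymax` and optionally `score`).
#'
#' @param config A [detector_config()] for the reference backend.
#' @param ground_truth_boxes Global ground-truth box data frame for the
#'   oracle backend.
#' @param command Path to the external detector executable for the adapter
#'   backend.
#' @return A detector function `f(patch, origin)` obeying the
#'   [detector contract][validate_detector_output].
#' @name detector-backends
NULL

#' @rdname detector-backends
#' @export
make_reference_detector <- function(config = detector_config()) {
  force(config)
  function(patch, origin = c(0, 0)) reference_blob_detect(patch, config)
}

#' @rdname detector-backends
#' @export
make_oracle_detector <- function(ground_truth_boxes) {
  validate_boxes(ground_truth_boxes)
  gt <- ground_truth_boxes
  function(patch, origin = c(0, 0)) {
    p <- dim(patch)[1]
    local <- gt
    local$xmin <- local$xmin - origin[1]; local$xmax <- local$xmax - origin[1]
    local$ymin <- local$ymin - origin[2]; local$ymax <- local$ymax - origin[2]
    local <- clip_boxes(local, p, p, drop_empty = TRUE)
    detections(local, score = 1)
  }
}

#' @rdname detector-backends
#' @export
make_adapter_detector <- function(command) {
  force(command)
  function(patch, origin = c(0, 0)) {
    tmp_png <- tempfile(fileext = ".png")
    tmp_csv <- tempfile(fileext = ".csv")
    on.exit(unlink(c(tmp_png, tmp_csv)))
    EBImage::writeImage(EBImage::Image(as.array(patch)), tmp_png)
    status <- system2(command, c(tmp_png, tmp_csv))
    if (status != 0) stop("adapter detector failed with exit status ", status)
    df <- utils::read.csv(tmp_csv, stringsAsFactors = FALSE)
    if (nrow(df) == 0) return(empty_detections())
    detections(boxes(df$xmin, df$ymin, df$xmax, df$ymax),
               score = if ("score" %in% names(df)) df$score else 1)
  }
}

#' Filter detections by confidence score
#'
#' Keeps the subsequence of detections with `score >= min_score`,
#' preserving the input order.
#'
#' @param dets Detection data frame.
#' @param min_score Threshold in `[0, 1]`.
#' @return The filtered detection data frame.
#' @export
score_threshold_filter <- function(dets, min_score) {
  stopifnot(length(min_score) == 1, min_score >= 0, min_score <= 1)
  out <- dets[dets$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}
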