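#' Configure the quantification pipeline
#'
#' Bundles the tiling, filtering, merging and measurement parameters used
#' by [quantify_image()] and [batch_quantify()].
#'
#' @param patch_size Sliding-window edge in pixels. Default 450, one of the
#'   two patch sizes the annotation dataset was built from.
#' @param overlap Window overlap: values in `[0, 1)` are read as a fraction
#'   of `patch_size` (converted to pixels rounding down); values `>= 1` are
#'   pixels. Default 0.5: with 50% overlap any box smaller than the stride
#'   is interior to some tile, so edge rejection loses nothing.
#' @param edge_margin Detections closer than this (pixels) to an interior
#'   tile edge are discarded; tile sides that coincide with the true image
#'   border are exempt. Default 2.
#' @param merge_iou_threshold IoU at or above which cross-tile detections
#'   are considered duplicates during merging, in `(0, 1]`. Default 0.5.
#' @param min_score Confidence cut applied to raw detector output.
#' @param microns_per_pixel Physical pixel size for morphometry.
#' @param detector A detector backend function `f(patch, origin)` (see
#'   [detector-backends]), or one of the names `"reference"` / `"oracle"`
#'   (the oracle additionally needs `ground_truth_boxes`).
#' @param detector_config A [detector_config()] for the reference backend.
#' @param ground_truth_boxes Global ground-truth boxes for the oracle
#'   backend.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(patch_size = 450, overlap = 0.5, edge_margin = 2,
                            merge_iou_threshold = 0.5, min_score = 0.2,
                            microns_per_pixel = 1, detector = "reference",
                            detector_config = orgadetect::detector_config(),
                            ground_truth_boxes = NULL) {
  stopifnot(patch_size > 0, edge_margin >= 0,
            merge_iou_threshold > 0, merge_iou_threshold <= 1,
            min_score >= 0, min_score <= 1, microns_per_pixel > 0)
  overlap_px <- if (overlap < 1) as.integer(floor(overlap * patch_size))
                else as.integer(overlap)
  if (overlap_px < 0 || overlap_px >= patch_size)
    stop("invalid config: overlap must resolve to [0, patch_size) pixels")
  if (is.character(detector)) {
    detector <- switch(detector,
      reference = make_reference_detector(detector_config),
      oracle = {
        if (is.null(ground_truth_boxes))
          stop("oracle detector requires ground_truth_boxes")
        make_oracle_detector(ground_truth_boxes)
      },
      stop("unknown detector backend: ", detector))
  }
  stopifnot(is.function(detector))
  structure(list(patch_size = as.integer(patch_size), overlap = overlap_px,
                 edge_margin = as.integer(edge_margin),
                 merge_iou_threshold = merge_iou_threshold,
                 min_score = min_score, microns_per_pixel = microns_per_pixel,
                 detector = detector),
            class = "pipeline_config")
}

#' Discard detections at interior tile edges
#'
#' Detections near a sliding-window edge are unreliable (the object may be
#' truncated by the window), so any detection whose box comes within
#' `margin` pixels of a patch side is dropped — unless that side coincides
#' with the boundary of the original (unpadded) image, in which case the
#' box is kept: organoids at the true image border could otherwise never be
#' reported. Window overlap guarantees that an interior organoid dropped in
#' one tile is seen away from the edge in another.
#'
#' @param dets Tile-local detection data frame.
#' @param tile_origin 0-based `c(x, y)` of the tile in the full image.
#' @param grid The [plan_tile_grid()] result for the image.
#' @param margin Edge margin in pixels (`>= 0`).
#' @return The surviving detections (still tile-local).
#' @export
filter_edge_detections <- function(dets, tile_origin, grid, margin) {
  stopifnot(inherits(grid, "tile_grid"), margin >= 0)
  if (nrow(dets) == 0) return(dets)
  p <- grid$patch_size
  ox <- unname(tile_origin[1]); oy <- unname(tile_origin[2])
  at_left <- ox == 0; at_top <- oy == 0
  at_right <- ox + p >= grid$original_width
  at_bottom <- oy + p >= grid$original_height
  drop <- (dets$xmin < margin     & !at_left)  |
          (dets$ymin < margin     & !at_top)   |
          (p - dets$xmax < margin & !at_right) |
          (p - dets$ymax < margin & !at_bottom)
  out <- dets[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate tile-local detections to image coordinates
#'
#' Offsets boxes by the tile origin and clips them to the original
#' (unpadded) image frame; detections emptied by clipping (i.e. lying
#' wholly in the padding strip) are dropped.
#'
#' @param dets Tile-local detection data frame (already edge-filtered).
#' @param tile_origin 0-based `c(x, y)` tile corner.
#' @param original_width,original_height Unpadded image dimensions.
#' @return Image-global detections.
#' @export
map_to_global <- function(dets, tile_origin, original_width, original_height) {
  if (nrow(dets) == 0) return(dets)
  out <- dets
  out$xmin <- out$xmin + tile_origin[1]; out$xmax <- out$xmax + tile_origin[1]
  out$ymin <- out$ymin + tile_origin[2]; out$ymax <- out$ymax + tile_origin[2]
  clip_boxes(out, original_width, original_height, drop_empty = TRUE)
}

#' Merge duplicate detections across tiles (greedy NMS)
#'
#' Overlapping windows report the same organoid more than once; duplicates
#' are resolved by greedy non-maximum suppression. Detections are visited
#' in descending score order (ties broken by lexicographic box
#' coordinates); one is kept iff its IoU with every already-kept detection
#' is below `iou_threshold`. Idempotent.
#'
#' @param dets Image-global detection data frame.
#' @param iou_threshold Suppression threshold in `(0, 1]`.
#' @return The kept detections, in visit order.
#' @export
merge_detections <- function(dets, iou_threshold) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  validate_boxes(dets)
  if (nrow(dets) <= 1) { rownames(dets) <- NULL; return(dets) }
  ord <- order(-dets$score, dets$xmin, dets$ymin, dets$xmax, dets$ymax)
  d <- dets[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(d))) {
    if (length(kept) == 0 ||
        all(iou_matrix(d[i, , drop = FALSE], d[kept, , drop = FALSE]) < iou_threshold))
      kept <- c(kept, i)
  }
  out <- d[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify all organoids in one image
#'
#' The full per-image pipeline: plan the tile grid, pad, extract patches,
#' run the detector on each patch, apply the confidence cut, discard
#' interior-edge detections, translate to image coordinates, merge
#' duplicates across tiles, and measure each surviving box under the
#' ellipse assumption.
#'
#' @param image An [EBImage::Image], an array (`dim[1]` = width), or a file
#'   path to a TIFF/PNG image.
#' @param config A [pipeline_config()].
#' @return A list with `detections` (image-global, merged), `measurements`
#'   (one row per detection, see [measure_organoid()]), `overlay` (RGB
#'   image with boxes drawn), and `grid` (the tiling used). Zero detections
#'   yield valid empty outputs.
#' @export
quantify_image <- function(image, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) {
    original <- tryCatch(read_image(image, as_gray = FALSE),
                         error = function(e) stop("failed to read image '",
                                                  image, "': ", conditionMessage(e)))
  } else original <- image
  gray <- as_gray_matrix(original)
  w <- dim(gray)[1]; h <- dim(gray)[2]
  grid <- plan_tile_grid(w, h, config$patch_size, config$overlap)
  padded <- pad_image(gray, grid)
  tiles <- extract_patches(padded, grid)
  collected <- lapply(tiles, function(tile) {
    dets <- config$detector(tile$patch, tile$origin)
    validate_detector_output(dets, config$patch_size)
    dets <- score_threshold_filter(dets, config$min_score)
    dets <- filter_edge_detections(dets, tile$origin, grid, config$edge_margin)
    map_to_global(dets, tile$origin, w, h)
  })
  all_dets <- do.call(rbind, c(list(empty_detections()), collected))
  merged <- merge_detections(all_dets, config$merge_iou_threshold)
  list(detections = merged,
       measurements = measure_organoid(merged, config$microns_per_pixel),
       overlay = render_overlay(original, merged),
       grid = grid)
}

#' Quantify every image under a folder tree
#'
#' Recursively discovers TIFF/PNG images under `root`, runs
#' [quantify_image()] on each, and writes `<stem>_labels.csv` and
#' `<stem>_labeled.png` next to each source image. Per-image failures are
#' logged and skipped so an unattended run always completes.
#'
#' @param root Folder to scan (recursively).
#' @param config A [pipeline_config()].
#' @param verbose Print one log line per image (detections and timing).
#' @return A list with `processed` and `failed` counts and a `results`
#'   data frame (`path`, `n_detections`, `status`).
#' @export
batch_quantify <- function(root, config, verbose = TRUE) {
  if (!dir.exists(root)) stop("configuration error: no such folder: ", root)
  files <- list.files(root, pattern = "\\.(tif|tiff|png)$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  files <- files[!grepl("_labeled\\.(png|tif|tiff)$", files, ignore.case = TRUE)]
  status <- character(length(files)); ndet <- integer(length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(quantify_image(f, config), error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res); ndet[i] <- NA_integer_
      if (verbose) message(sprintf("FAILED %s: %s", f, status[i]))
      next
    }
    stem <- tools::file_path_sans_ext(f)
    write_measurements_csv(res$detections, res$measurements,
                           paste0(stem, "_labels.csv"), basename(f))
    EBImage::writeImage(res$overlay, paste0(stem, "_labeled.png"))
    status[i] <- "ok"; ndet[i] <- nrow(res$detections)
    if (verbose)
      message(sprintf("%s: %d organoids (%.1f s)", f, ndet[i],
                      proc.time()[["elapsed"]] - t0))
  }
  ok <- status == "ok"
  list(processed = sum(ok), failed = sum(!ok),
       results = data.frame(path = files, n_detections = ndet, status = status))
}
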