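#' Physical-unit morphometry of detected organoids
#'
#' Converts bounding boxes into size measurements under the inscribed-
#' ellipse assumption: the organoid is taken to be the ellipse inscribed in
#' its box, so its axis lengths equal the box sides and its projected 2D
#' area is `pi/4 * major * minor`. With box sides `w = (xmax - xmin) * s`
#' and `h = (ymax - ymin) * s` (where `s` is the pixel size in microns),
#' the major axis is `max(w, h)`, the minor axis `min(w, h)`.
#'
#' @param b Box (or detection) data frame.
#' @param microns_per_pixel Physical pixel size `s` in microns per pixel,
#'   positive. Taken from the user's imaging configuration; scale bars are
#'   not read from the image.
#' @return A data frame with one row per box: `major_axis_um`,
#'   `minor_axis_um`, `area_um2`.
#' @examples
#' measure_organoid(boxes(0, 0, 100, 60), 1)  # 100 x 60, area pi*50*30
#' @export
measure_organoid <- function(b, microns_per_pixel = 1) {
  validate_boxes(b)
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("invalid config: microns_per_pixel must be a positive number")
  w <- (b$xmax - b$xmin) * microns_per_pixel
  h <- (b$ymax - b$ymin) * microns_per_pixel
  data.frame(major_axis_um = pmax(w, h), minor_axis_um = pmin(w, h),
             area_um2 = pi / 4 * w * h)
}

#' Write the per-image quantification CSV
#'
#' One row per detected organoid with its box, confidence and ellipse
#' morphometry; header
#' `filename,xmin,ymin,xmax,ymax,score,major_axis_um,minor_axis_um,area_um2`.
#' Rows are ordered by descending score, ties broken by lexicographic box
#' coordinates, so output is deterministic.
#'
#' @param detections Detection data frame.
#' @param measurements Matching rows from [measure_organoid()].
#' @param path Output CSV path.
#' @param image_name Value of the `filename` column.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(detections, measurements, path,
                                   image_name = "image") {
  if (nrow(detections) != nrow(measurements))
    stop("detections and measurements must be aligned one-to-one")
  df <- data.frame(filename = rep_len(image_name, nrow(detections)),
                   detections[c("xmin", "ymin", "xmax", "ymax", "score")],
                   measurements[c("major_axis_um", "minor_axis_um", "area_um2")])
  if (nrow(df) > 1) {
    df <- df[order(-df$score, df$xmin, df$ymin, df$xmax, df$ymax), ]
    rownames(df) <- NULL
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw detection boxes onto an image
#'
#' Renders each detection as a 2-px rectangle outline (drawn just inside
#' the box, clipped to the frame); all pixels outside the outlines are
#' unchanged. Grayscale inputs are promoted to RGB so the outlines can be
#' coloured.
#'
#' @param image [EBImage::Image] or array (`dim[1]` = width).
#' @param dets Detection data frame in image coordinates.
#' @param color Outline colour as an RGB triple in `[0, 1]`.
#' @return An RGB [EBImage::Image] of the same width and height.
#' @export
render_overlay <- function(image, dets, color = c(1, 0, 0)) {
  arr <- as.array(image)
  w <- dim(arr)[1]; h <- dim(arr)[2]
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(w, h, 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  validate_boxes(dets)
  for (i in seq_len(nrow(dets))) {
    x0 <- max(0, floor(dets$xmin[i])); x1 <- min(w, ceiling(dets$xmax[i]))
    y0 <- max(0, floor(dets$ymin[i])); y1 <- min(h, ceiling(dets$ymax[i]))
    if (x1 <= x0 || y1 <= y0) next
    xs <- (x0 + 1):x1; ys <- (y0 + 1):y1
    t2 <- function(v) v[seq_len(min(2, length(v)))]
    for (ch in 1:3) {
      arr[xs, c(t2(ys), rev(t2(rev(ys)))), ch] <- color[ch]
      arr[c(t2(xs), rev(t2(rev(xs)))), ys, ch] <- color[ch]
    }
  }
  EBImage::Image(arr, colormode = EBImage::Color)
}
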