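#' Plan a sliding-window tiling of an image
#'
#' Computes the minimal integer cover of a `width x height` image by square
#' windows of `patch_size` pixels sliding with `overlap` pixels of overlap
#' (stride `patch_size - overlap`). The image is conceptually padded at the
#' bottom and right so that an integer number of windows covers each axis:
#' along x, the number of windows is the smallest `n >= 1` with
#' `(n - 1) * stride + patch_size >= width`, and the padded width is
#' `(n - 1) * stride + patch_size`; likewise along y.
#'
#' @param width,height Image dimensions in pixels, positive.
#' @param patch_size Square window edge in pixels, positive.
#' @param overlap Window overlap in pixels, `0 <= overlap < patch_size`.
#' @return An object of class `tile_grid`: a list with `patch_size`,
#'   `stride`, `origins` (data frame of 0-based tile top-left corners `x`,
#'   `y`, enumerated row-major), `padded_width`, `padded_height`,
#'   `original_width`, `original_height`.
#' @examples
#' g <- plan_tile_grid(1500, 1125, 450, 150)
#' nrow(g$origins)  # 20 tiles (5 x 4)
#' @export
plan_tile_grid <- function(width, height, patch_size, overlap) {
  stopifnot(length(width) == 1, length(height) == 1, width > 0, height > 0,
            patch_size > 0)
  if (overlap < 0 || overlap >= patch_size)
    stop("invalid tiling config: overlap must satisfy 0 <= overlap < patch_size")
  width <- as.integer(width); height <- as.integer(height)
  patch_size <- as.integer(patch_size)
  stride <- patch_size - as.integer(overlap)
  n_along <- function(extent) {
    if (extent <= patch_size) 1L
    else as.integer(ceiling((extent - patch_size) / stride)) + 1L
  }
  nx <- n_along(width); ny <- n_along(height)
  ox <- (seq_len(nx) - 1L) * stride
  oy <- (seq_len(ny) - 1L) * stride
  origins <- data.frame(x = rep(ox, times = ny), y = rep(oy, each = nx))
  structure(list(patch_size = patch_size, stride = stride, origins = origins,
                 padded_width = (nx - 1L) * stride + patch_size,
                 padded_height = (ny - 1L) * stride + patch_size,
                 original_width = width, original_height = height),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d tiles of %d px (stride %d) over %d x %d, padded to %d x %d\n",
              nrow(x$origins), x$patch_size, x$stride,
              x$original_width, x$original_height,
              x$padded_width, x$padded_height))
  invisible(x)
}

img_width  <- function(image) dim(image)[1]
img_height <- function(image) dim(image)[2]

#' Pad an image to its tile grid
#'
#' Appends zero-intensity (black) pixels at the bottom and right edges so
#' the image dimensions equal the grid's padded dimensions. Original
#' content is unchanged.
#'
#' @param image An [EBImage::Image] or numeric array with `dim[1]` = width
#'   and `dim[2]` = height (grayscale or multi-channel).
#' @param grid A `tile_grid` whose original dimensions match `image`.
#' @return The padded image, same type as the input.
#' @export
pad_image <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- dim(image)
  if (d[1] != grid$original_width || d[2] != grid$original_height)
    stop(sprintf("image is %d x %d but grid was planned for %d x %d",
                 d[1], d[2], grid$original_width, grid$original_height))
  if (grid$padded_width == d[1] && grid$padded_height == d[2]) return(image)
  nd <- d
  nd[1] <- grid$padded_width; nd[2] <- grid$padded_height
  out <- array(0, dim = nd)
  idx <- c(list(seq_len(d[1]), seq_len(d[2])),
           lapply(d[-(1:2)], seq_len))
  out <- do.call(`[<-`, c(list(out), idx, list(value = as.array(image))))
  if (inherits(image, "Image"))
    out <- EBImage::Image(out, colormode = EBImage::colorMode(image))
  out
}

#' Extract all tiles of a padded image
#'
#' @param image Image already padded to the grid's padded dimensions.
#' @param grid A `tile_grid`.
#' @return A list with one element per tile origin (row-major order), each a
#'   list with `origin` (0-based `c(x, y)`) and `patch`
#'   (`patch_size x patch_size` array).
#' @export
extract_patches <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- dim(image)
  if (d[1] != grid$padded_width || d[2] != grid$padded_height)
    stop("image must be padded to the grid's padded dimensions first (see pad_image)")
  p <- grid$patch_size
  arr <- as.array(image)
  lapply(seq_len(nrow(grid$origins)), function(i) {
    ox <- grid$origins$x[i]; oy <- grid$origins$y[i]
    idx <- c(list(ox + seq_len(p), oy + seq_len(p)),
             lapply(d[-(1:2)], seq_len))
    list(origin = c(x = ox, y = oy),
         patch = do.call(`[`, c(list(arr), idx, list(drop = FALSE))))
  })
}

#' Read an 8-bit brightfield image from disk
#'
#' Reads TIFF or PNG through EBImage and collapses RGB to grayscale
#' (channel mean) for detection; intensities are scaled to `[0, 1]`.
#'
#' @param path Path to a `.tif`, `.tiff` or `.png` file.
#' @param as_gray Collapse colour channels to a single grayscale channel.
#' @return An [EBImage::Image].
#' @export
read_image <- function(path, as_gray = TRUE) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- EBImage::readImage(path)
  if (as_gray && length(dim(img)) > 2)
    img <- EBImage::channel(img, "gray")
  img
}
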