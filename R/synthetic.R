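#' Specify a synthetic brightfield organoid scene
#'
#' Describes a scene to be rendered by [generate_scene()]: spherical-to-
#' elliptical organoids with a dark rim and a lighter lumen on a bright
#' background, mimicking low-magnification brightfield images of organoids
#' embedded in a hydrogel droplet. The controls reproduce the imaging
#' artifacts that make such images hard to segment classically: organoid
#' overlap, out-of-focus organoids, heterogeneous sizes, a lighting
#' gradient, and dense or sparse fields.
#'
#' @param width,height Scene dimensions in pixels.
#' @param n_organoids Number of organoids to place.
#' @param radius_range Range (min, max) of the semi-major axis in pixels;
#'   sampled uniformly.
#' @param axis_ratio_range Range of the minor/major semi-axis ratio in
#'   `(0, 1]`; 1 renders circles. Controls eccentricity.
#' @param overlap_allowed If `FALSE`, organoids are placed by rejection
#'   sampling so their ground-truth boxes are pairwise disjoint.
#' @param defocus_fraction Fraction of organoids rendered out of focus.
#' @param defocus_sigma Gaussian blur sigma (pixels) applied to defocused
#'   organoids.
#' @param illumination_gradient Peak-to-peak relative amplitude in `[0, 1]`
#'   of a linear illumination field across the scene.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise,
#'   on the `[0, 1]` intensity scale.
#' @param background,rim_intensity,lumen_intensity Appearance model on the
#'   `[0, 1]` intensity scale: bright background, dark organoid rim,
#'   intermediate lumen.
#' @param rim_fraction Rim thickness as a fraction of the local radius.
#' @param max_place_tries Rejection-sampling cap per organoid when
#'   `overlap_allowed = FALSE`.
#' @param seed Integer seed; the scene is fully determined by it.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 1500, height = 1125, n_organoids = 30,
                       radius_range = c(15, 60), axis_ratio_range = c(0.7, 1),
                       overlap_allowed = TRUE, defocus_fraction = 0.2,
                       defocus_sigma = 8, illumination_gradient = 0.2,
                       noise_sigma = 0.02, background = 0.85,
                       rim_intensity = 0.40, lumen_intensity = 0.65,
                       rim_fraction = 0.25, max_place_tries = 1000,
                       seed = 1) {
  stopifnot(width > 0, height > 0, n_organoids >= 0,
            length(radius_range) == 2, radius_range[1] > 0,
            radius_range[2] >= radius_range[1],
            radius_range[2] < min(width, height) / 2,
            axis_ratio_range[1] > 0, axis_ratio_range[2] <= 1,
            defocus_fraction >= 0, defocus_fraction <= 1,
            illumination_gradient >= 0, illumination_gradient <= 1,
            noise_sigma >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

with_scene_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Tight 0-based half-open box of the in-frame pixels (centres) of a rotated
# ellipse; also returns the pixel mask on its local window.
ellipse_geometry <- function(cx, cy, a, b, theta, width, height) {
  hw <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  hh <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  x0 <- max(0L, floor(cx - hw - 1)); x1 <- min(width, ceiling(cx + hw + 1))
  y0 <- max(0L, floor(cy - hh - 1)); y1 <- min(height, ceiling(cy + hh + 1))
  xs <- seq.int(x0, x1 - 1L); ys <- seq.int(y0, y1 - 1L)
  dx <- outer(xs + 0.5 - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys + 0.5 - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  r2 <- (u / a)^2 + (v / b)^2
  inside <- r2 <= 1
  if (!any(inside)) return(NULL)
  ix <- which(rowSums(inside) > 0); iy <- which(colSums(inside) > 0)
  list(x0 = x0, y0 = y0, r2 = r2, inside = inside,
       box = data.frame(xmin = x0 + ix[1] - 1, ymin = y0 + iy[1] - 1,
                        xmax = x0 + ix[length(ix)], ymax = y0 + iy[length(iy)]))
}

#' Render a synthetic organoid scene with exact ground truth
#'
#' Renders each organoid as a rotated ellipse (dark rim, lighter lumen) on a
#' bright background; applies per-organoid Gaussian defocus to a flagged
#' fraction; multiplies by a linear illumination field; adds Gaussian noise
#' and quantizes to 8-bit levels. The ground-truth box of each organoid is
#' the tight axis-aligned bound of its rendered (pre-blur) pixels.
#'
#' All random draws come from a single stream seeded with `spec$seed`, in a
#' fixed order (per organoid: semi-major axis, axis ratio, orientation, then
#' placement attempts; then defocus flags; then the illumination direction;
#' then pixel noise), so identical specs yield identical scenes.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (grayscale [EBImage::Image], values on the
#'   8-bit grid in `[0, 1]`) and `ground_truth`, itself a list with `boxes`
#'   (tight integer boxes), `in_focus` (logical), and `true_axes` (data
#'   frame of `semi_major`, `semi_minor` in pixels).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    w <- as.integer(spec$width); h <- as.integer(spec$height)
    canvas <- matrix(spec$background, nrow = w, ncol = h)
    n <- spec$n_organoids
    gt_boxes <- empty_boxes()
    axes <- data.frame(semi_major = numeric(0), semi_minor = numeric(0))
    geoms <- list()
    for (i in seq_len(n)) {
      a <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      b <- a * stats::runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
      theta <- stats::runif(1, 0, pi)
      hw <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
      hh <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
      placed <- FALSE
      for (try in seq_len(spec$max_place_tries)) {
        cx <- stats::runif(1, hw + 1, w - hw - 1)
        cy <- stats::runif(1, hh + 1, h - hh - 1)
        g <- ellipse_geometry(cx, cy, a, b, theta, w, h)
        if (is.null(g)) next
        if (!spec$overlap_allowed && nrow(gt_boxes) > 0 &&
            any(iou_matrix(g$box, gt_boxes) > 0)) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop("scene generation failed: could not place organoid ", i,
             " without overlap within ", spec$max_place_tries, " tries")
      gt_boxes <- rbind(gt_boxes, g$box)
      axes <- rbind(axes, data.frame(semi_major = a, semi_minor = b))
      geoms[[i]] <- g
    }
    in_focus <- rep(TRUE, n)
    if (n > 0 && spec$defocus_fraction > 0) {
      k <- round(spec$defocus_fraction * n)
      if (k > 0) in_focus[sample.int(n, k)] <- FALSE
    }
    for (i in seq_len(n)) {
      g <- geoms[[i]]
      sprite <- matrix(spec$background, nrow = nrow(g$r2), ncol = ncol(g$r2))
      r <- sqrt(pmax(g$r2, 0))
      rim <- g$inside & r > (1 - spec$rim_fraction)
      lumen <- g$inside & !rim
      sprite[rim] <- spec$rim_intensity
      sprite[lumen] <- spec$lumen_intensity
      if (!in_focus[i] && spec$defocus_sigma > 0) {
        pad <- ceiling(3 * spec$defocus_sigma)
        big <- matrix(spec$background, nrow = nrow(sprite) + 2 * pad,
                      ncol = ncol(sprite) + 2 * pad)
        big[pad + seq_len(nrow(sprite)), pad + seq_len(ncol(sprite))] <- sprite
        big <- EBImage::gblur(big, sigma = spec$defocus_sigma)
        # composite the blurred sprite over its enlarged, in-frame window
        bx0 <- g$x0 - pad; by0 <- g$y0 - pad
        xs <- seq_len(nrow(big)); ys <- seq_len(ncol(big))
        okx <- xs + bx0 >= 1 & xs + bx0 <= w
        oky <- ys + by0 >= 1 & ys + by0 <= h
        cxs <- xs[okx] + bx0; cys <- ys[oky] + by0
        canvas[cxs, cys] <- pmin(canvas[cxs, cys], big[xs[okx], ys[oky]])
      } else {
        xs <- g$x0 + seq_len(nrow(sprite)); ys <- g$y0 + seq_len(ncol(sprite))
        canvas[xs, ys] <- pmin(canvas[xs, ys], sprite)
      }
    }
    if (spec$illumination_gradient > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      px <- (seq_len(w) - 0.5) / w; py <- (seq_len(h) - 0.5) / h
      t <- outer(px * cos(phi), py * sin(phi), `+`)
      t <- (t - min(t)) / max(max(t) - min(t), .Machine$double.eps)
      canvas <- canvas * (1 - spec$illumination_gradient * t)
    }
    if (spec$noise_sigma > 0)
      canvas <- canvas + matrix(stats::rnorm(w * h, 0, spec$noise_sigma), w, h)
    canvas <- round(pmin(pmax(canvas, 0), 1) * 255) / 255
    rownames(gt_boxes) <- NULL
    list(image = EBImage::Image(canvas, colormode = EBImage::Grayscale),
         ground_truth = list(boxes = gt_boxes, in_focus = in_focus,
                             true_axes = axes))
  })
}

#' Write a synthetic fixture dataset with its annotation CSV
#'
#' Renders `n_images` scenes from a template spec (per-image seeds are
#' `spec$seed + 0:(n_images - 1)`), writes each as an 8-bit image file, and
#' writes one annotation CSV covering all scenes in the published schema
#' (`filename,width,height,class,xmin,ymin,xmax,ymax`, class `"organoid"`).
#'
#' @param n_images Number of scenes.
#' @param spec Template [scene_spec()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` (default) or `"tiff"`.
#' @param prefix Filename prefix.
#' @return Invisibly, a list with `images` (file paths), `csv` (annotation
#'   file path) and `ground_truths` (per-scene ground truth).
#' @export
generate_fixture_dataset <- function(n_images, spec, dir, format = c("png", "tiff"),
                                     prefix = "scene") {
  stopifnot(inherits(spec, "scene_spec"), n_images >= 1)
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_images)
  gts <- vector("list", n_images)
  recs <- list()
  for (i in seq_len(n_images)) {
    sp <- spec; sp$seed <- spec$seed + i - 1L
    scene <- generate_scene(sp)
    fname <- sprintf("%s_%03d.%s", prefix, i, ext)
    paths[i] <- file.path(dir, fname)
    if (format == "tiff")
      EBImage::writeImage(scene$image, paths[i], bits.per.sample = 8L)
    else
      EBImage::writeImage(scene$image, paths[i])
    gts[[i]] <- scene$ground_truth
    if (nrow(scene$ground_truth$boxes) > 0)
      recs[[i]] <- data.frame(filename = fname, width = sp$width,
                              height = sp$height, class = "organoid",
                              scene$ground_truth$boxes)
  }
  csv <- file.path(dir, "annotations.csv")
  write_annotation_csv(do.call(rbind, c(recs, list(annotation_schema_frame()))), csv)
  invisible(list(images = paths, csv = csv, ground_truths = gts))
}
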