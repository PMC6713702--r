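#' @name annotation-csv
#' @title The bounding-box annotation CSV schema
#' @description
#' Annotations travel as CSV files with header
#' `filename,width,height,class,xmin,ymin,xmax,ymax`: one row per box, where
#' `filename` names the image patch the box belongs to, `width`/`height` are
#' the patch dimensions, `class` is the box label (`"organoid"`), and
#' `xmin,ymin,xmax,ymax` are pixel coordinates with the origin at the
#' top-left corner. This package reads the coordinates under a 0-based,
#' half-open convention. An upstream dialect storing `x_min, y_min, width,
#' height` of the box instead of two corners is supported via
#' `dialect = "corner_size"` in [read_annotation_csv()].
NULL

annotation_schema_frame <- function() {
  data.frame(filename = character(0), width = integer(0), height = integer(0),
             class = character(0), xmin = numeric(0), ymin = numeric(0),
             xmax = numeric(0), ymax = numeric(0))
}

#' Read an annotation CSV
#'
#' Parses bounding-box annotation records (see [annotation-csv]). The header
#' is matched by name, order-insensitively. Rows violating the box
#' invariants (`xmin < xmax`, `ymin < ymax`) are rejected with their row
#' numbers. Boxes extending beyond the stated patch frame raise an error;
#' patch sizes other than 300 or 450 only produce a warning when
#' `expect_published_sizes = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param dialect `"corners"` for `xmin,ymin,xmax,ymax` columns (the
#'   published schema) or `"corner_size"` for the upstream dialect whose
#'   `width`/`height` columns are the box size (converted to corners on
#'   read; the patch dimensions are then unknown and reported as `NA`, and
#'   the patch-frame check is skipped).
#' @param expect_published_sizes Warn when patch sizes are not 300 or 450.
#' @return A data frame with columns `filename`, `width`, `height`, `class`,
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
read_annotation_csv <- function(path, dialect = c("corners", "corner_size"),
                                expect_published_sizes = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- if (dialect == "corners")
    c("filename", "width", "height", "class", "xmin", "ymin", "xmax", "ymax")
  else c("filename", "class", "x_min", "y_min", "width", "height")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("annotation CSV schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (dialect == "corner_size") {
    df$xmin <- df$x_min; df$ymin <- df$y_min
    df$xmax <- df$x_min + df$width
    df$ymax <- df$y_min + df$height
    df$width <- NA_integer_; df$height <- NA_integer_
  }
  df <- df[c("filename", "width", "height", "class", "xmin", "ymin", "xmax", "ymax")]
  if (nrow(df) == 0) return(df)
  bad <- which(!is.finite(df$xmin) | !is.finite(df$ymin) |
               !is.finite(df$xmax) | !is.finite(df$ymax) |
               df$xmax <= df$xmin | df$ymax <= df$ymin |
               df$xmin < 0 | df$ymin < 0)
  if (length(bad) > 0)
    stop("invalid box on data row(s) ", paste(bad, collapse = ", "),
         " of ", path, " (need 0 <= xmin < xmax and 0 <= ymin < ymax)")
  out <- which(!is.na(df$width) & !is.na(df$height) &
               (df$xmax > df$width | df$ymax > df$height))
  if (length(out) > 0)
    stop("box outside its patch frame on data row(s) ",
         paste(out, collapse = ", "), " of ", path)
  if (expect_published_sizes && !all(df$width %in% c(300, 450) & df$height %in% c(300, 450)))
    warning("patch sizes other than 300 or 450 px present in ", path)
  df
}

#' Write an annotation CSV
#'
#' Writes records in the published schema; row order is preserved, so
#' read -> write -> read is the identity.
#'
#' @param records Data frame with the [annotation-csv] columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(records, path) {
  cols <- names(annotation_schema_frame())
  if (is.null(records) || nrow(records) == 0) records <- annotation_schema_frame()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0)
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  validate_boxes(records)
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cut a large image into grid-aligned annotation patches
#'
#' For each requested size, extracts every full, non-overlapping
#' `size x size` patch starting from the top-left corner; partial remainder
#' strips at the bottom and right are discarded. This is the patchification
#' used to turn full-frame microscope images into annotation-sized tiles.
#'
#' @param image An [EBImage::Image] or array (`dim[1]` = width).
#' @param patch_sizes Integer vector of square patch sizes in pixels
#'   (the annotation dataset used 300 and 450).
#' @param stem Filename stem encoded into patch names.
#' @return A list with one element per patch: `patch` (array), `filename`
#'   (`<stem>_s<size>_r<row>_c<col>.png`), `size`, `row`, `col` (0-based
#'   grid position). Sizes larger than the image are skipped with a warning.
#' @export
patchify_for_annotation <- function(image, patch_sizes = c(300, 450), stem = "image") {
  arr <- as.array(image)
  w <- dim(arr)[1]; h <- dim(arr)[2]
  out <- list()
  for (size in patch_sizes) {
    if (size > w || size > h) {
      warning(sprintf("patch size %d exceeds image %d x %d; skipped", size, w, h))
      next
    }
    nx <- w %/% size; ny <- h %/% size
    for (r in seq_len(ny) - 1L) for (cc in seq_len(nx) - 1L) {
      idx <- c(list(cc * size + seq_len(size), r * size + seq_len(size)),
               lapply(dim(arr)[-(1:2)], seq_len))
      out[[length(out) + 1L]] <- list(
        patch = do.call(`[`, c(list(arr), idx, list(drop = FALSE))),
        filename = sprintf("%s_s%d_r%d_c%d.png", stem, size, r, cc),
        size = as.integer(size), row = r, col = cc)
    }
  }
  out
}

#' Split annotation records into training and test sets
#'
#' Splits at the level of filenames so that all boxes of one patch stay on
#' the same side (no leakage between sets). Seeded and reproducible.
#'
#' @param records Annotation data frame (see [annotation-csv]).
#' @param test_fraction Fraction of filenames held out, in `(0, 1)`.
#'   The dataset workflow this mirrors held out 10%.
#' @param seed Integer seed for the draw.
#' @return A list with `train` and `test` data frames partitioning
#'   `records` by filename.
#' @export
train_test_split <- function(records, test_fraction = 0.10, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  files <- unique(records$filename)
  if (length(files) < 2)
    stop("need at least 2 distinct filenames to split")
  n_test <- max(1L, round(test_fraction * length(files)))
  test_files <- with_scene_seed(seed, sample(files, n_test))
  is_test <- records$filename %in% test_files
  list(train = records[!is_test, , drop = FALSE],
       test = records[is_test, , drop = FALSE])
}
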