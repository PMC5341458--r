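#' Read a plate image
#'
#' Loads a PNG, TIFF or JPEG plate photograph as an 8-bit colour array.
#' Single-channel (grayscale) files are replicated to three identical
#' channels so downstream code sees one shape. PNG and TIFF are read with the
#' \pkg{png} and \pkg{tiff} packages; JPEG goes through
#' \code{EBImage::readImage} when \pkg{EBImage} is installed.
#'
#' @param path Path to an image file.
#' @return An `H x W x 3` integer array of 8-bit values (0--255).
#' @export
load_plate_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read image: no such file '", path, "'"),
          class = "rootproxy_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = read_jpeg_ebimage(path),
      abort(paste0("unsupported image format '.", ext, "' for '", path, "'"),
            class = "rootproxy_format_error")
    ),
    error = function(e) {
      if (inherits(e, "rootproxy_format_error")) stop(e)
      abort(paste0("cannot read image '", path, "': ", conditionMessage(e)),
            class = "rootproxy_io_error")
    }
  )
  img <- as_rgb8(img, path)
  img
}

read_jpeg_ebimage <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("JPEG input needs the EBImage package",
          class = "rootproxy_format_error")
  }
  e <- EBImage::readImage(path)
  a <- EBImage::imageData(e)
  # EBImage stores x in dim 1, y in dim 2; transpose to row = y, col = x
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

# normalise whatever the readers produced into H x W x 3 8-bit
as_rgb8 <- function(img, path) {
  if (is.list(img)) img <- img[[1]]           # multi-page TIFF: first page
  if (is.double(img) || is.integer(img)) {
    v <- if (max(img, na.rm = TRUE) <= 1) round(img * 255) else round(img)
  } else {
    abort(paste0("unsupported pixel type in '", path, "'"),
          class = "rootproxy_format_error")
  }
  d <- dim(v)
  if (is.null(d) || length(d) < 2L) {
    abort(paste0("'", path, "' is not a 2-D image"),
          class = "rootproxy_format_error")
  }
  if (length(d) == 2L) {
    out <- array(v, dim = c(d[1], d[2], 3L))
  } else if (d[3] >= 3L) {
    out <- v[, , 1:3, drop = FALSE]           # drop alpha if present
  } else if (d[3] == 1L) {
    out <- array(v[, , 1L], dim = c(d[1], d[2], 3L))
  } else {
    abort(paste0("'", path, "' has ", d[3], " channels; need 1, 3 or 4"),
          class = "rootproxy_format_error")
  }
  storage.mode(out) <- "integer"
  pmax(pmin(out, 255L), 0L)
}

#' Convert a colour image to 8-bit grayscale
#'
#' Standard luma weighting `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer. The downstream likelihood method depends only on relative
#' brightness, so any fixed monotone conversion would do; luma is the
#' conventional choice.
#'
#' @param image An `H x W x 3` 8-bit array.
#' @return An `H x W` integer matrix of 8-bit values.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    abort("to_grayscale expects an H x W x 3 array",
          class = "rootproxy_format_error")
  }
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  g <- round(g)
  dim(g) <- d[1:2]
  storage.mode(g) <- "integer"
  g
}

#' Fixed-range contrast stretch
#'
#' Linearly maps the interval `[low, high]` onto the full 8-bit range:
#' values at or below `low` go to 0, values at or above `high` go to 255, and
#' the interior is scaled as `round(255 * (v - low) / (high - low))`. The
#' mapping is monotone non-decreasing, so pixel ordering is preserved; with
#' bounds (0, 255) it is the identity.
#'
#' @param image An `H x W` 8-bit matrix.
#' @param bounds A [stretch_bounds()] pair.
#' @return An `H x W` integer matrix of stretched 8-bit values.
#' @export
contrast_stretch <- function(image, bounds = stretch_bounds()) {
  if (!inherits(bounds, "stretch_bounds")) {
    bounds <- stretch_bounds(bounds[[1]], bounds[[2]])
  }
  v <- (image - bounds$low) / (bounds$high - bounds$low)
  out <- round(255 * pmin(pmax(v, 0), 1))
  storage.mode(out) <- "integer"
  dim(out) <- dim(image)
  out
}

#' Cut a plate image into per-well intensity fields
#'
#' Extracts each well rectangle of `grid` from a grayscale plate image and
#' normalises its 8-bit values into `[0, 1]` (division by 255). Wells are
#' returned left to right, in the order of the grid rows.
#'
#' @param image An `H x W` 8-bit grayscale matrix (already stretched).
#' @param grid A [well_grid()].
#' @return A list of `gray_well` objects, each holding `intensities`
#'   (`height x width` matrix in `[0, 1]`), `width`, `height` and the 0-based
#'   `well_index`.
#' @export
extract_wells <- function(image, grid) {
  stopifnot(inherits(grid, "well_grid"))
  validate_grid_for_image(grid, nrow(image), ncol(image))
  purrr::map(seq_len(grid$n_wells), function(i) {
    r <- grid$well_rects[i, ]
    sub <- image[r$y0 + seq_len(r$height), r$x0 + seq_len(r$width),
                 drop = FALSE]
    gray_well(sub / 255, well_index = i - 1L)
  })
}

#' One well's normalised intensity field
#'
#' @param intensities `H x W` numeric matrix with values in `[0, 1]`
#'   (row = y downward, column = x rightward).
#' @param well_index 0-based index of the well within its plate.
#' @return A `gray_well` object.
#' @export
gray_well <- function(intensities, well_index = 0L) {
  intensities <- as.matrix(intensities)
  if (any(intensities < 0 | intensities > 1)) {
    abort("gray_well intensities must lie in [0, 1]",
          class = "rootproxy_contract_error")
  }
  structure(
    list(intensities = intensities,
         width = ncol(intensities), height = nrow(intensities),
         well_index = as.integer(well_index)),
    class = "gray_well"
  )
}

#' @export
print.gray_well <- function(x, ...) {
  cat("<gray_well> ", x$width, "x", x$height, " (well ", x$well_index, ")\n",
      sep = "")
  invisible(x)
}
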