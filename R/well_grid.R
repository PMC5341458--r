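#' Plate geometry: where the wells sit in an image
#'
#' A `well_grid` records the pixel rectangle of every growth well in a plate
#' photograph, plus the fraction of well height searched for seed points.
#' Rectangles are 0-based, half-open is *not* used: a rectangle of `width` w
#' covers columns `x0 .. x0 + w - 1`. Imaging rigs with robotic plate handling
#' place wells at fixed positions, so the grid is supplied explicitly in the
#' run configuration rather than detected.
#'
#' @param well_rects A data frame (or tibble) with columns `x0`, `y0`,
#'   `width`, `height`, one row per well, left to right.
#' @param strip_fraction Fraction of the well height, measured from the top,
#'   scanned for seed points. Default 0.05 (seeds are sown above this line).
#' @return A `well_grid` object.
#' @examples
#' grid <- well_grid(data.frame(x0 = c(0, 300), y0 = 0,
#'                              width = 290, height = 710))
#' grid$n_wells
#' @export
well_grid <- function(well_rects, strip_fraction = 0.05) {
  well_rects <- as_tibble(well_rects)
  needed <- c("x0", "y0", "width", "height")
  if (!all(needed %in% names(well_rects))) {
    abort(paste("well_rects needs columns", paste(needed, collapse = ", ")),
          class = "rootproxy_config_error")
  }
  if (nrow(well_rects) < 1L) {
    abort("well_grid needs at least one well rectangle",
          class = "rootproxy_config_error")
  }
  if (any(well_rects$width < 1 | well_rects$height < 1) ||
      any(well_rects$x0 < 0 | well_rects$y0 < 0)) {
    abort("well rectangles must have non-negative origins and positive size",
          class = "rootproxy_config_error")
  }
  if (!is.numeric(strip_fraction) || length(strip_fraction) != 1L ||
      strip_fraction <= 0 || strip_fraction >= 1) {
    abort("strip_fraction must lie strictly between 0 and 1",
          class = "rootproxy_config_error")
  }
  structure(
    list(n_wells = nrow(well_rects),
         well_rects = well_rects,
         strip_fraction = strip_fraction),
    class = "well_grid"
  )
}

#' @export
print.well_grid <- function(x, ...) {
  cat("<well_grid> ", x$n_wells, " wells, strip_fraction = ",
      x$strip_fraction, "\n", sep = "")
  print(x$well_rects, n = 8)
  invisible(x)
}

#' Evenly spaced single-row grid
#'
#' Convenience constructor for the common plate layout: `n` equal wells in one
#' horizontal row, separated by fixed gutters.
#'
#' @param n_wells Number of wells.
#' @param well_width,well_height Well size in pixels.
#' @param x0,y0 Pixel origin of the first (leftmost) well.
#' @param gap Horizontal gutter between consecutive wells, pixels.
#' @inheritParams well_grid
#' @return A `well_grid`.
#' @export
well_grid_row <- function(n_wells, well_width, well_height,
                          x0 = 0L, y0 = 0L, gap = 0L,
                          strip_fraction = 0.05) {
  rects <- tibble(
    x0 = x0 + (seq_len(n_wells) - 1L) * (well_width + gap),
    y0 = y0, width = well_width, height = well_height
  )
  well_grid(rects, strip_fraction = strip_fraction)
}

#' Contrast-stretch bounds
#'
#' The 8-bit intensity interval mapped onto the full 0--255 range. Values at
#' or below `low` become 0, values at or above `high` become 255. One pair is
#' fixed per batch: plate-imaging lighting is constant enough that the bounds
#' are determined once and applied to every image.
#'
#' @param low,high 8-bit intensities, `0 <= low < high <= 255`.
#' @return A `stretch_bounds` object.
#' @export
stretch_bounds <- function(low = 0L, high = 255L) {
  if (!is.numeric(low) || !is.numeric(high) ||
      low < 0 || high > 255 || low >= high) {
    abort("stretch bounds need 0 <= low < high <= 255",
          class = "rootproxy_config_error")
  }
  structure(list(low = as.numeric(low), high = as.numeric(high)),
            class = "stretch_bounds")
}

# internal: check a grid fits inside an H x W image
validate_grid_for_image <- function(grid, height, width) {
  r <- grid$well_rects
  bad <- which(r$x0 + r$width > width | r$y0 + r$height > height)
  if (length(bad) > 0L) {
    abort(sprintf("well %d: rectangle exceeds the %dx%d image bounds",
                  bad[1] - 1L, width, height),
          class = "rootproxy_config_error")
  }
  invisible(TRUE)
}
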