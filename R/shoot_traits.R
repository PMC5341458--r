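# Top-down shoot traits. Rosettes are photographed against a white
# background, so "leaf" is simply "not white": saturation above a low
# threshold in hue-saturation-value space.

#' Leaf (non-white) pixel mask of a top-down well region
#'
#' Converts the region to HSV and marks pixels whose saturation strictly
#' exceeds `sat_threshold` (fractions of full scale). White background has
#' saturation 0; any coloured leaf pixel clears a low threshold easily.
#'
#' @param top_well An `H x W x 3` 8-bit array (a top-camera well region).
#' @param sat_threshold Saturation threshold, default 0.20.
#' @return A `leaf_mask`: list with logical `mask` and the threshold.
#' @export
leaf_mask <- function(top_well, sat_threshold = 0.20) {
  d <- dim(top_well)
  if (length(d) != 3L || d[3] != 3L) {
    abort("leaf_mask expects an H x W x 3 array",
          class = "rootproxy_format_error")
  }
  hsv <- rgb2hsv_pixels(top_well)
  mask <- matrix(hsv[2, ] > sat_threshold, nrow = d[1], ncol = d[2])
  structure(list(mask = mask, sat_threshold = sat_threshold),
            class = "leaf_mask")
}

# 3 x n matrix (h in [0,1), s, v) for all pixels, column-major
rgb2hsv_pixels <- function(img) {
  d <- dim(img)
  grDevices::rgb2hsv(
    r = as.vector(img[, , 1]),
    g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]),
    maxColorValue = 255
  )
}

#' Leaf area
#'
#' Total count of leaf (non-white) pixels in the mask.
#'
#' @param mask A [leaf_mask()].
#' @return Integer pixel count.
#' @export
leaf_area <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  sum(mask$mask)
}

#' Mean leaf hue
#'
#' Circular mean of the hue angle over leaf pixels: each hue is a unit
#' vector, the vectors are averaged and the result converted back to an
#' angle in `[0, 360)` degrees. An arithmetic mean would fail at the red
#' wrap-around (10 and 350 average to 0, not 180). Hue is independent of the
#' value channel, so the trait ignores brightness.
#'
#' @param top_well An `H x W x 3` 8-bit array.
#' @param mask A [leaf_mask()] of the same region.
#' @return Mean hue in degrees, or `NA` if the mask is empty.
#' @export
leaf_hue <- function(top_well, mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  hsv <- rgb2hsv_pixels(top_well)
  sel <- as.vector(mask$mask)
  if (!any(sel)) return(NA_real_)
  ang <- hsv[1, sel] * 2 * pi          # rgb2hsv returns hue in [0, 1)
  mh <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  (mh + 360) %% 360
}

#' Shoot traits for one top-down well region
#'
#' @param top_well An `H x W x 3` 8-bit array.
#' @param sat_threshold Saturation threshold for the leaf mask.
#' @return One-row tibble with `leaf_area` and `leaf_hue`.
#' @export
shoot_traits <- function(top_well, sat_threshold = 0.20) {
  m <- leaf_mask(top_well, sat_threshold)
  tibble(leaf_area = leaf_area(m), leaf_hue = leaf_hue(top_well, m))
}

#' Cut a top-down plate image into per-well colour regions
#'
#' @param image An `H x W x 3` 8-bit array.
#' @param grid The top camera's [well_grid()].
#' @return List of `H x W x 3` arrays, one per well.
#' @export
extract_top_wells <- function(image, grid) {
  stopifnot(inherits(grid, "well_grid"))
  validate_grid_for_image(grid, dim(image)[1], dim(image)[2])
  purrr::map(seq_len(grid$n_wells), function(i) {
    r <- grid$well_rects[i, ]
    image[r$y0 + seq_len(r$height), r$x0 + seq_len(r$width), , drop = FALSE]
  })
}
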