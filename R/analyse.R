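#' Analyse a single well image end to end
#'
#' Convenience wrapper around the per-well chain: contrast stretch, seed
#' detection, multi-source Dijkstra, likelihood, traits. Useful for working
#' with standalone well images (synthetic or cropped) outside the batch
#' pipeline.
#'
#' @param image `H x W` 8-bit matrix (one well, side view).
#' @param bounds [stretch_bounds()] for the contrast stretch.
#' @param strip_fraction Seed-strip height fraction.
#' @param min_seed_intensity Minimum normalised seed intensity.
#' @param exponent Likelihood exponent.
#' @param norm_max Normalising constant; `NULL` (default) uses this well's
#'   maximum path cost. Pass a batch constant for population work.
#' @param weight_mode Edge-weight mode.
#' @param image_id,well_index Identifiers for the trait record.
#' @return List: `traits` (one-row tibble), `lmap`, `dist`, `seeds`,
#'   `well`. For an empty well `lmap`/`dist` are `NULL` and the record is
#'   flagged.
#' @examples
#' spec <- synthetic_root_spec(width = 100, height = 220, length = 120,
#'                             seed = 42)
#' res <- analyse_well(generate_root_well(spec)$image)
#' res$traits$depth_m
#' @export
analyse_well <- function(image, bounds = stretch_bounds(48, 230),
                         strip_fraction = 0.05, min_seed_intensity = 0.2,
                         exponent = 1, norm_max = NULL,
                         weight_mode = "clamp",
                         image_id = NA_character_, well_index = 0L) {
  w <- gray_well(contrast_stretch(image, bounds) / 255, well_index)
  seeds <- detect_seed_points(w, strip_fraction, min_seed_intensity)
  if (nrow(seeds$points) == 0L) {
    return(list(traits = well_traits(NULL, NULL, image_id, well_index,
                                     empty = TRUE),
                lmap = NULL, dist = NULL, seeds = seeds, well = w))
  }
  d <- multi_source_dijkstra(w, seeds, weight_mode)
  nm <- norm_max %||% max(d$distances)
  lmap <- likelihood(d, norm_max = nm, exponent = exponent)
  list(traits = well_traits(lmap, orientation_field(w), image_id, well_index),
       lmap = lmap, dist = d, seeds = seeds, well = w)
}

#' Analyse a set of standalone well images as one batch
#'
#' Applies the per-well chain to every image and binds the trait records.
#' With `norm_mode = "empirical"` the per-well maximum path costs are
#' computed first and their mean becomes the shared normalising constant —
#' the population convention that keeps likelihood scales comparable
#' across wells.
#'
#' @param images List of `H x W` 8-bit matrices.
#' @param norm_mode `"well"`, `"empirical"` or `"theoretical"`.
#' @inheritParams analyse_well
#' @return A tibble with one trait record per image.
#' @export
analyse_well_set <- function(images, bounds = stretch_bounds(48, 230),
                             norm_mode = c("well", "empirical", "theoretical"),
                             strip_fraction = 0.05, min_seed_intensity = 0.2,
                             exponent = 1, weight_mode = "clamp") {
  norm_mode <- match.arg(norm_mode)
  pre <- purrr::map(images, function(img) {
    w <- gray_well(contrast_stretch(img, bounds) / 255)
    seeds <- detect_seed_points(w, strip_fraction, min_seed_intensity)
    if (nrow(seeds$points) == 0L) return(list(well = w, dist = NULL))
    list(well = w, dist = multi_source_dijkstra(w, seeds, weight_mode))
  })
  maxima <- purrr::map_dbl(pre, function(p)
    if (is.null(p$dist)) NA_real_ else max(p$dist$distances))
  batch_nm <- if (norm_mode == "empirical") mean(maxima, na.rm = TRUE)
  recs <- purrr::imap(pre, function(p, i) {
    if (is.null(p$dist)) {
      return(well_traits(NULL, NULL, well_index = i - 1L, empty = TRUE))
    }
    nm <- switch(norm_mode,
      well = max(p$dist$distances),
      empirical = batch_nm,
      theoretical = p$well$height + p$well$width)
    well_traits(likelihood(p$dist, norm_max = nm, exponent = exponent),
                orientation_field(p$well), well_index = i - 1L)
  })
  dplyr::bind_rows(recs)
}
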