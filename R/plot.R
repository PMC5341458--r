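# Diagnostics: likelihood heat maps per well and a PCA view of a trait
# table. Everything returns a ggplot so it composes with the usual grammar.

#' Heat-map plot of a likelihood map
#'
#' Renders `L(x, y)` with brighter colours where the method is more
#' confident of root material — the standard per-well diagnostic.
#'
#' @param object A `likelihood_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.likelihood_map <- function(object, ...) {
  df <- tibble(
    x = rep(0:(object$width - 1L), each = object$height),
    y = rep(0:(object$height - 1L), times = object$width),
    L = as.vector(object$L)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$L)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("black", "darkred", "orange", "yellow", "white"),
      limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "L")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a likelihood heat map as an 8-bit PNG
#'
#' @param lmap A `likelihood_map`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_heatmap <- function(lmap, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ramp <- grDevices::colorRamp(
    c("black", "darkred", "orange", "yellow", "white"))
  rgb <- ramp(as.vector(lmap$L)) / 255
  arr <- array(0, dim = c(lmap$height, lmap$width, 3L))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(rgb[, ch], lmap$height, lmap$width)
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' PCA view of a trait table
#'
#' Standardises the numeric trait columns, projects wells onto the first
#' two principal components and colours by a grouping column — the quick
#' check that conditions separate in trait space.
#'
#' @param traits A trait tibble (rows = wells).
#' @param group Name of a grouping column in `traits` (optional).
#' @return A ggplot.
#' @export
plot_trait_pca <- function(traits, group = NULL) {
  pcs <- trait_pca(traits)
  df <- tibble(PC1 = pcs$scores[, 1], PC2 = pcs$scores[, 2])
  if (!is.null(group)) df$group <- traits[[group]]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pcs$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pcs$var_explained[2]))
  if (is.null(group)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Principal components of the numeric trait columns
#'
#' @param traits A trait tibble.
#' @return List: `scores` (wells x PCs), `var_explained`, the `prcomp` fit.
#' @export
trait_pca <- function(traits) {
  num <- dplyr::select(traits, dplyr::where(is.numeric),
                       -dplyr::any_of("well_index"))
  keep <- vapply(num, function(v) stats::sd(v) > 0, TRUE)
  fit <- stats::prcomp(num[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  list(scores = fit$x,
       var_explained = fit$sdev^2 / sum(fit$sdev^2),
       fit = fit)
}
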