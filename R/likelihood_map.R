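#' Detect seed points in the top strip of a well
#'
#' Scans each pixel row of the top strip (strip height =
#' `ceiling(strip_fraction * well height)`) for local intensity maxima:
#' pixels strictly brighter than both horizontal neighbours, with intensity
#' at least `min_intensity`. A plateau of equal maximal values contributes
#' its centre pixel; a pixel (or plateau) touching the row border is compared
#' only against its one existing neighbour. A plateau spanning an entire row
#' carries no local contrast evidence and yields no seed.
#'
#' Seedlings are sown above the strip line, so these maxima mark positions
#' almost certainly containing plant material; they become the sources of the
#' shortest-path search.
#'
#' @param well A [gray_well()].
#' @param strip_fraction Fraction of well height scanned from the top.
#' @param min_intensity Minimum normalised intensity for a seed. The default
#'   0.2 avoids seeding on background noise in empty wells; 0 restores plain
#'   local-maximum behaviour.
#' @return A `seed_points` object: tibble `points` with 0-based columns
#'   `x`, `y`, plus `strip_height`. Zero rows means the well is empty.
#' @examples
#' w <- gray_well(matrix(c(0.1, 0.9, 0.1), nrow = 1))
#' detect_seed_points(w, strip_fraction = 0.99)$points
#' @export
detect_seed_points <- function(well, strip_fraction = 0.05,
                               min_intensity = 0.2) {
  stopifnot(inherits(well, "gray_well"))
  strip_h <- min(well$height, ceiling(strip_fraction * well$height))
  pts <- purrr::map_dfr(seq_len(strip_h), function(row) {
    v <- well$intensities[row, ]
    xs <- row_local_maxima(v, min_intensity)
    if (length(xs) == 0L) return(NULL)
    tibble(x = xs, y = row - 1L)
  })
  if (nrow(pts) == 0L) pts <- tibble(x = integer(), y = integer())
  structure(list(points = pts, strip_height = strip_h),
            class = "seed_points")
}

# 0-based column indices of strict local maxima (plateau centres) in one row
row_local_maxima <- function(v, min_intensity) {
  n <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- logical(length(r$values))
  for (i in seq_along(r$values)) {
    if (r$values[i] < min_intensity) next
    left_ok <- if (starts[i] > 1L) r$values[i] > v[starts[i] - 1L] else NA
    right_ok <- if (ends[i] < n) r$values[i] > v[ends[i] + 1L] else NA
    if (is.na(left_ok) && is.na(right_ok)) next  # full-row plateau
    keep[i] <- all(c(left_ok, right_ok), na.rm = TRUE)
  }
  centres <- (starts[keep] + ends[keep]) %/% 2L
  as.integer(centres - 1L)
}

#' @export
print.seed_points <- function(x, ...) {
  cat("<seed_points> ", nrow(x$points), " seeds in a ", x$strip_height,
      "-row strip\n", sep = "")
  invisible(x)
}

#' Edge weight between two neighbouring pixels
#'
#' The pixel graph rewards travel over bright (likely root) material:
#' `w = 1 - alpha * I(p) * I(q)` with `alpha = 1` for orthogonal neighbours
#' and `sqrt(2)` for diagonals (longer centre-to-centre distance). Two very
#' bright diagonal neighbours make the raw value negative, which Dijkstra
#' cannot accept; in the default `"clamp"` mode such weights are clamped at
#' zero (free travel through saturated root material). Mode `"scaled"`
#' applies the alternative reading `w = alpha * (1 - I(p) * I(q))`, which is
#' non-negative by construction.
#'
#' @param ip,iq Normalised intensities in `[0, 1]` (vectorised).
#' @param diagonal Logical; are the pixels diagonal neighbours?
#' @param mode `"clamp"` (default) or `"scaled"`.
#' @return Non-negative edge weight(s).
#' @export
edge_weight <- function(ip, iq, diagonal = FALSE, mode = c("clamp", "scaled")) {
  mode <- match.arg(mode)
  if (any(ip < 0 | ip > 1 | iq < 0 | iq > 1)) {
    abort("edge_weight intensities must lie in [0, 1]",
          class = "rootproxy_contract_error")
  }
  alpha <- ifelse(diagonal, sqrt(2), 1)
  if (mode == "clamp") pmax(0, 1 - alpha * ip * iq)
  else alpha * (1 - ip * iq)
}

#' Multi-source shortest-path distances over a well
#'
#' Runs Dijkstra's algorithm simultaneously from every seed point over the
#' 8-connected pixel graph with [edge_weight()] weights: each pixel receives
#' the cheapest path cost from *any* seed. Bright connected root material is
#' cheap to traverse, so genuinely root-connected pixels end up close;
#' isolated bright noise must be reached over dark background and ends up
#' far. All weights are finite, so every pixel gets a finite distance.
#'
#' @param well A [gray_well()].
#' @param seeds A `seed_points` object (or a data frame with 0-based
#'   `x`, `y` columns) with at least one point.
#' @param weight_mode Passed to [edge_weight()].
#' @return A `distance_map`: list with `distances` (matrix, same shape as the
#'   well), `source` (the seeds) and `weight_mode`.
#' @export
multi_source_dijkstra <- function(well, seeds, weight_mode = c("clamp", "scaled")) {
  stopifnot(inherits(well, "gray_well"))
  weight_mode <- match.arg(weight_mode)
  pts <- if (inherits(seeds, "seed_points")) seeds$points else as_tibble(seeds)
  if (nrow(pts) == 0L) {
    abort("multi_source_dijkstra needs at least one seed point",
          class = "rootproxy_contract_error")
  }
  d <- dijkstra_grid_cpp(well$intensities,
                         as.integer(pts$x), as.integer(pts$y),
                         scaled_weights = (weight_mode == "scaled"))
  structure(list(distances = d,
                 source = pts,
                 weight_mode = weight_mode,
                 width = well$width, height = well$height,
                 well_index = well$well_index),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("<distance_map> ", x$width, "x", x$height, ", ", nrow(x$source),
      " sources, max distance ", format(max(x$distances)), "\n", sep = "")
  invisible(x)
}

#' Normalisation constant for the likelihood map
#'
#' The likelihood divides path cost by a normalising maximum. Three
#' conventions are supported:
#' \describe{
#'   \item{`"well"`}{the observed maximum distance within this well — the
#'     literal form of the likelihood definition. Default.}
#'   \item{`"theoretical"`}{`H + W`, an upper bound for an all-background
#'     well (every pixel is reachable in at most `H + W` unit-weight steps).}
#'   \item{`"empirical"`}{the per-well maximum averaged over all wells of a
#'     batch, computed in a first pass; supply these maxima via `well_maxima`.}
#' }
#'
#' @param height,width Well dimensions in pixels.
#' @param mode One of `"well"`, `"theoretical"`, `"empirical"`.
#' @param dist A `distance_map` (required for `"well"`).
#' @param well_maxima Numeric vector of per-well maximum distances
#'   (required for `"empirical"`).
#' @return A positive scalar.
#' @export
norm_max <- function(height, width, mode = c("well", "theoretical", "empirical"),
                     dist = NULL, well_maxima = NULL) {
  mode <- match.arg(mode)
  out <- switch(mode,
    theoretical = height + width,
    empirical = {
      if (is.null(well_maxima) || length(well_maxima) == 0L) {
        abort("empirical norm_max needs per-well maximum distances",
              class = "rootproxy_config_error")
      }
      mean(well_maxima)
    },
    well = {
      if (is.null(dist)) {
        abort("mode 'well' needs the distance map",
              class = "rootproxy_config_error")
      }
      max(dist$distances)
    }
  )
  if (!is.finite(out) || out <= 0) {
    abort("norm_max must be a positive finite scalar",
          class = "rootproxy_config_error")
  }
  out
}

#' Root likelihood map
#'
#' Converts shortest-path cost into a per-pixel likelihood of root material:
#' `L = (1 - dist / norm_max) ^ exponent`, clamped into `[0, 1]`. Seeds have
#' distance 0, hence likelihood 1. Larger exponents sharpen the drop-off away
#' from bright material; the default 1 changes results only marginally.
#'
#' @param dist A `distance_map`.
#' @param norm_max Positive normalising constant (see [norm_max()]).
#' @param exponent Positive power applied to the normalised likelihood.
#' @return A `likelihood_map`: list with `L` (matrix in `[0, 1]`),
#'   `norm_max`, `exponent`, and the well geometry.
#' @export
likelihood <- function(dist, norm_max = max(dist$distances), exponent = 1) {
  stopifnot(inherits(dist, "distance_map"))
  if (!is.numeric(norm_max) || norm_max <= 0) {
    abort("norm_max must be positive", class = "rootproxy_config_error")
  }
  if (!is.numeric(exponent) || exponent <= 0) {
    abort("exponent must be positive", class = "rootproxy_config_error")
  }
  L <- pmin(pmax(1 - dist$distances / norm_max, 0), 1) ^ exponent
  dim(L) <- dim(dist$distances)
  structure(list(L = L, norm_max = norm_max, exponent = exponent,
                 width = dist$width, height = dist$height,
                 well_index = dist$well_index),
            class = "likelihood_map")
}

#' Build a likelihood map directly from a likelihood matrix
#'
#' Mostly useful in tests and examples where a likelihood field is
#' constructed by hand rather than computed from distances.
#'
#' @param L Numeric matrix with values in `[0, 1]`.
#' @param norm_max,exponent Recorded metadata.
#' @return A `likelihood_map`.
#' @export
likelihood_map <- function(L, norm_max = 1, exponent = 1) {
  L <- as.matrix(L)
  if (any(L < 0 | L > 1)) {
    abort("likelihood values must lie in [0, 1]",
          class = "rootproxy_contract_error")
  }
  structure(list(L = L, norm_max = norm_max, exponent = exponent,
                 width = ncol(L), height = nrow(L), well_index = NA_integer_),
            class = "likelihood_map")
}

#' @export
print.likelihood_map <- function(x, ...) {
  cat("<likelihood_map> ", x$width, "x", x$height, ", norm_max = ",
      format(x$norm_max), ", exponent = ", x$exponent, "\n", sep = "")
  invisible(x)
}
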