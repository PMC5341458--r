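# Likelihood-weighted proxy traits. Every trait is a weighted sum or argmax
# over the whole well: no pixel is ever classified as root / not-root, its
# likelihood simply scales its contribution. Units are pixels / arbitrary
# likelihood mass; correlation-based downstream analysis makes real-world
# calibration unnecessary.

#' Likelihood-weighted centroid
#'
#' The weighted centre of mass of the root system:
#' `(sum(L * x) / sum(L), sum(L * y) / sum(L))`, 0-based pixel coordinates.
#'
#' @param lmap A `likelihood_map`.
#' @return Named numeric vector `c(x = , y = )`; `NA` if total likelihood
#'   is zero (empty well).
#' @export
centroid <- function(lmap) {
  L <- lmap$L
  tot <- sum(L)
  if (tot <= 0) return(c(x = NA_real_, y = NA_real_))
  xs <- matrix(rep(0:(lmap$width - 1L), each = lmap$height), nrow = lmap$height)
  ys <- matrix(rep(0:(lmap$height - 1L), times = lmap$width), nrow = lmap$height)
  c(x = sum(L * xs) / tot, y = sum(L * ys) / tot)
}

#' Total likelihood mass
#'
#' Sum of all likelihoods in the well — the threshold-free analogue of a
#' root pixel count. Also available per pixel (`mass / (W * H)`) as
#' `mass_norm` in [well_traits()].
#'
#' @param lmap A `likelihood_map`.
#' @return Scalar.
#' @export
trait_mass <- function(lmap) sum(lmap$L)

#' Bounding box by mass-weighted extremities
#'
#' The box edge on each side is the pixel maximising the product of
#' likelihood and distance towards that side: right edge at
#' `argmax L(x, y) * x`, left at `argmax L(x, y) * (W - 1 - x)`, bottom at
#' `argmax L(x, y) * y`, top at `argmax L(x, y) * (H - 1 - y)`. A dim far
#' pixel can outscore a bright near one, so the box tracks the mass-bearing
#' extremities rather than the farthest nonzero pixel. Ties resolve to the
#' first pixel in column-major order (deterministic).
#'
#' `depth_m` is the bottom edge's y, i.e. distance from the well top — the
#' proxy for root-system length.
#'
#' @param lmap A `likelihood_map`.
#' @return Named vector `c(width_m, depth_m, left, right, top, bottom)`;
#'   zeros with `NA` edges when the well is empty.
#' @export
bbox_argmax <- function(lmap) {
  L <- lmap$L
  if (sum(L) <= 0) {
    return(c(width_m = 0, depth_m = 0, left = NA, right = NA,
             top = NA, bottom = NA))
  }
  H <- lmap$height; W <- lmap$width
  xs <- matrix(rep(0:(W - 1L), each = H), nrow = H)
  ys <- matrix(rep(0:(H - 1L), times = W), nrow = H)
  right  <- xs[which.max(L * xs)]
  left   <- xs[which.max(L * (W - 1L - xs))]
  bottom <- ys[which.max(L * ys)]
  top    <- ys[which.max(L * (H - 1L - ys))]
  c(width_m = right - left + 1, depth_m = bottom,
    left = left, right = right, top = top, bottom = bottom)
}

#' Bounding box by likelihood quantiles
#'
#' Depth: the smallest y whose cumulative row mass (from the well top)
#' reaches `fraction` of the total likelihood — roots grow downward from
#' seeds at the top, so depth is one-sided. Width: the shortest central
#' column interval left after trimming `(1 - fraction) / 2` of the mass from
#' each side. Less outlier-sensitive than the argmax box.
#'
#' @param lmap A `likelihood_map`.
#' @param fraction Mass fraction to enclose (0.95 or 0.99 in practice).
#' @return Named vector `c(width, depth)`; zeros when empty.
#' @export
bbox_quantile <- function(lmap, fraction = 0.95) {
  stopifnot(fraction > 0, fraction <= 1)
  L <- lmap$L
  tot <- sum(L)
  if (tot <= 0) return(c(width = 0, depth = 0))
  eps <- 1e-9 * tot
  row_mass <- rowSums(L)
  depth <- which(cumsum(row_mass) >= fraction * tot - eps)[1] - 1L
  col_mass <- colSums(L)
  tail_mass <- (1 - fraction) / 2 * tot
  cl <- cumsum(col_mass)
  cr <- rev(cumsum(rev(col_mass)))
  left <- which(cl > tail_mass + eps)[1]
  right <- rev(which(cr > tail_mass + eps))[1]
  c(width = right - left + 1, depth = as.numeric(depth))
}

# row index ranges (1-based) of the four stacked horizontal bands;
# remainder rows go to the bottom band
quadrant_bands <- function(H) {
  h <- H %/% 4L
  starts <- c(0L, h, 2L * h, 3L * h)
  ends <- c(h, 2L * h, 3L * h, H)
  purrr::map2(starts + 1L, ends, seq_len_range)
}
seq_len_range <- function(from, to) if (to >= from) seq(from, to) else integer()

#' Likelihood mass per depth quadrant
#'
#' The well is split into four stacked horizontal bands of (near-)equal
#' height, Q0 at the top through Q3 at the bottom; remainder rows join the
#' bottom band. Returns the likelihood mass per band, which always sums to
#' [trait_mass()].
#'
#' @param lmap A `likelihood_map`.
#' @return Named numeric vector `q0..q3`.
#' @export
quadrant_mass <- function(lmap) {
  bands <- quadrant_bands(lmap$height)
  out <- vapply(bands, function(rows) sum(lmap$L[rows, , drop = FALSE]), 0)
  names(out) <- paste0("q", 0:3)
  out
}

#' Local structure orientation from Sobel gradients
#'
#' Convolves the well with the standard 3x3 Sobel kernels (replicate padding
#' at the borders) to get gradients `Gx`, `Gy`, then converts the gradient
#' direction into a *structure* angle: the intensity gradient across a root
#' is perpendicular to the root's axis, so
#' `theta = 90 - atan2(|Gy|, |Gx|)` in degrees. A vertical root therefore
#' reads ~90 (vertical), a horizontal one ~0. Pixels with zero gradient
#' magnitude have no defined orientation and are skipped by the histograms.
#'
#' @param well A [gray_well()] (at least 3x3).
#' @return An `orientation_field`: list with `theta` (degrees, `[0, 90]`)
#'   and `magnitude` matrices.
#' @export
orientation_field <- function(well) {
  stopifnot(inherits(well, "gray_well"))
  m <- well$intensities
  H <- nrow(m); W <- ncol(m)
  if (H < 3L || W < 3L) {
    abort("orientation_field needs a well of at least 3x3 pixels",
          class = "rootproxy_contract_error")
  }
  p <- m[c(1L, seq_len(H), H), c(1L, seq_len(W), W)]  # replicate padding
  sy <- p[seq_len(H), ] + 2 * p[seq_len(H) + 1L, ] + p[seq_len(H) + 2L, ]
  gx <- sy[, seq_len(W) + 2L] - sy[, seq_len(W)]
  sx <- p[, seq_len(W)] + 2 * p[, seq_len(W) + 1L] + p[, seq_len(W) + 2L]
  gy <- sx[seq_len(H) + 2L, ] - sx[seq_len(H), ]
  magnitude <- sqrt(gx^2 + gy^2)
  theta <- 90 - atan2(abs(gy), abs(gx)) * 180 / pi
  theta[magnitude == 0] <- 0
  structure(list(theta = theta, magnitude = magnitude,
                 width = W, height = H),
            class = "orientation_field")
}

# 0-based bin index for angles in [0, 90]: equal half-open bins, last closed
orientation_bin <- function(theta, n_bins) {
  pmin(floor(theta / (90 / n_bins)), n_bins - 1L)
}

#' Likelihood-weighted orientation histogram
#'
#' Partitions the structure-angle range `[0, 90]` degrees into `n_bins`
#' equal half-open brackets (the last closed at 90). Each pixel with nonzero
#' gradient magnitude adds its likelihood to the bracket containing its
#' angle; zero-magnitude pixels contribute nothing. Bracket totals therefore
#' sum to the likelihood mass over oriented pixels. More mass in the
#' near-horizontal brackets indicates lateral root material.
#'
#' @param lmap A `likelihood_map`.
#' @param field An [orientation_field()] of the same well.
#' @param n_bins Number of brackets (default 10).
#' @return Numeric vector of length `n_bins`, names `orient_1..orient_n`
#'   from horizontal to vertical.
#' @export
orientation_histogram <- function(lmap, field, n_bins = 10L) {
  stopifnot(inherits(field, "orientation_field"),
            all(dim(lmap$L) == dim(field$theta)))
  sel <- field$magnitude > 0
  bins <- orientation_bin(field$theta[sel], n_bins)
  out <- vapply(0:(n_bins - 1L),
                function(b) sum(lmap$L[sel][bins == b]), 0)
  names(out) <- paste0("orient_", seq_len(n_bins))
  out
}

#' Orientation by depth quadrant
#'
#' Crosses the four depth bands of [quadrant_mass()] with four equal
#' orientation brackets over `[0, 90]` degrees: 16 values per well, returned
#' band-major (Q0 brackets 1-4, then Q1, ...). The 16 values sum to the
#' total of the plain orientation histogram.
#'
#' @inheritParams orientation_histogram
#' @return Numeric vector of length 16, names `qorient_q<band>_b<bracket>`.
#' @export
quadrant_orientation <- function(lmap, field) {
  stopifnot(inherits(field, "orientation_field"),
            all(dim(lmap$L) == dim(field$theta)))
  bands <- quadrant_bands(lmap$height)
  out <- numeric(16)
  k <- 1L
  for (qi in seq_along(bands)) {
    rows <- bands[[qi]]
    Lq <- lmap$L[rows, , drop = FALSE]
    th <- field$theta[rows, , drop = FALSE]
    mg <- field$magnitude[rows, , drop = FALSE]
    sel <- mg > 0
    bins <- orientation_bin(th[sel], 4L)
    for (b in 0:3) {
      out[k] <- sum(Lq[sel][bins == b])
      k <- k + 1L
    }
  }
  names(out) <- paste0("qorient_q", rep(0:3, each = 4), "_b", rep(1:4, 4))
  out
}

#' All proxy traits for one well
#'
#' Computes the full trait record from a likelihood map and the well's
#' orientation field: centroid, mass (raw and per-pixel), argmax and
#' quantile bounding boxes, quadrant masses, the 10-bracket orientation
#' histogram and the 16 quadrant-orientation values. An empty well (no
#' seeds / zero likelihood) yields an all-zero row with `empty_flag = TRUE`.
#'
#' @param lmap A `likelihood_map` (or `NULL` for an empty well).
#' @param field An [orientation_field()] (ignored when empty).
#' @param image_id Identifier of the source image.
#' @param well_index 0-based well index.
#' @param empty Logical; force an empty record.
#' @return A one-row tibble.
#' @export
well_traits <- function(lmap, field, image_id = NA_character_,
                        well_index = NA_integer_, empty = FALSE) {
  if (empty || is.null(lmap) || sum(lmap$L) <= 0) {
    return(empty_trait_record(image_id, well_index))
  }
  cen <- centroid(lmap)
  m <- trait_mass(lmap)
  bb <- bbox_argmax(lmap)
  q95 <- bbox_quantile(lmap, 0.95)
  q99 <- bbox_quantile(lmap, 0.99)
  qm <- quadrant_mass(lmap)
  oh <- orientation_histogram(lmap, field, 10L)
  qo <- quadrant_orientation(lmap, field)
  tibble(
    image_id = image_id, well_index = as.integer(well_index),
    empty_flag = FALSE,
    centroid_x = unname(cen["x"]), centroid_y = unname(cen["y"]),
    mass = m, mass_norm = m / (lmap$width * lmap$height),
    width_m = unname(bb["width_m"]), depth_m = unname(bb["depth_m"]),
    width_p95 = unname(q95["width"]), depth_p95 = unname(q95["depth"]),
    depth_p99 = unname(q99["depth"]),
    !!!as.list(c(qm_names(qm), oh, qo))
  )
}

qm_names <- function(qm) { names(qm) <- paste0("mass_", names(qm)); qm }

empty_trait_record <- function(image_id, well_index) {
  zeros <- as.list(stats::setNames(
    rep(0, 4 + 10 + 16),
    c(paste0("mass_q", 0:3), paste0("orient_", 1:10),
      paste0("qorient_q", rep(0:3, each = 4), "_b", rep(1:4, 4)))
  ))
  tibble(
    image_id = image_id, well_index = as.integer(well_index),
    empty_flag = TRUE,
    centroid_x = 0, centroid_y = 0, mass = 0, mass_norm = 0,
    width_m = 0, depth_m = 0, width_p95 = 0, depth_p95 = 0, depth_p99 = 0,
    !!!zeros
  )
}
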