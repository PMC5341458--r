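# Deterministic synthetic plate imagery with known ground truth. The
# generator emulates what a side camera sees through an agar-filled well:
# bright, slightly out-of-focus curvilinear roots descending from a seed
# near the top of the well, against a dark noisy background. It exists so
# every stage of the pipeline is testable without any captured image set.

#' Specification of one synthetic root well
#'
#' @param width,height Well size in pixels (defaults match a typical plate
#'   well, roughly 290 x 710).
#' @param length Primary root arc length in pixels (unit steps along the
#'   rendered polyline).
#' @param curvature Maximum heading deviation from vertical, degrees; the
#'   heading sways sinusoidally along the root.
#' @param n_laterals Number of lateral roots branching off the primary.
#' @param lateral_angle Range (degrees from vertical) of lateral headings.
#' @param lateral_length Range of lateral lengths in pixels (absolute:
#'   young laterals are short regardless of how long the primary is).
#' @param half_width Stroke half-width in pixels.
#' @param root_intensity,background 8-bit intensities of root material and
#'   well background (`root_intensity > background`).
#' @param noise_sd Gaussian pixel noise standard deviation, 8-bit scale.
#' @param salt_density Fraction of pixels replaced by bright salt noise.
#' @param salt_intensity 8-bit intensity of salt pixels.
#' @param start_x Root origin column (0-based); default centre of the well
#'   with a small seeded jitter.
#' @param start_y Root origin row; must lie in the seed strip (top 5%).
#' @param profile `"gauss"` for an anti-aliased Gaussian cross-section
#'   (emulating out-of-focus imaging) or `"sharp"` for a binary stroke
#'   (exact-mask tests).
#' @param seed Random seed; the rendered image is fully determined by it.
#' @return A `synthetic_root_spec` list.
#' @export
synthetic_root_spec <- function(width = 290L, height = 710L,
                                length = 400,
                                curvature = 12,
                                n_laterals = 4L,
                                lateral_angle = c(40, 60),
                                lateral_length = c(40, 90),
                                half_width = 2,
                                root_intensity = 220L, background = 30L,
                                noise_sd = 6, salt_density = 5e-4,
                                salt_intensity = 235L,
                                start_x = NULL, start_y = 5L,
                                profile = c("gauss", "sharp"),
                                seed = 1L) {
  profile <- match.arg(profile)
  if (root_intensity <= background) {
    abort("root_intensity must exceed background",
          class = "rootproxy_config_error")
  }
  if (start_y >= 0.05 * height) {
    abort("start_y must lie inside the top 5% strip",
          class = "rootproxy_config_error")
  }
  structure(as.list(environment()), class = "synthetic_root_spec")
}

# unit-step polyline of the primary root; heading sways sinusoidally
render_primary_path <- function(spec) {
  n <- max(1L, round(spec$length))
  period <- stats::runif(1, 150, 300)
  phase <- stats::runif(1, 0, 2 * pi)
  x0 <- if (is.null(spec$start_x)) {
    spec$width / 2 + stats::runif(1, -spec$width / 8, spec$width / 8)
  } else spec$start_x
  xs <- numeric(n + 1L); ys <- numeric(n + 1L)
  xs[1] <- x0; ys[1] <- spec$start_y
  k <- 1L
  truncated <- FALSE
  while (k <= n) {
    delta <- spec$curvature * pi / 180 * sin(2 * pi * k / period + phase)
    nx <- xs[k] + sin(delta)
    ny <- ys[k] + cos(delta)
    if (ny > spec$height - 1L) { truncated <- TRUE; break }
    nx <- min(max(nx, 0), spec$width - 1L)
    xs[k + 1L] <- nx; ys[k + 1L] <- ny
    k <- k + 1L
  }
  list(x = xs[seq_len(k)], y = ys[seq_len(k)],
       steps = k - 1L, truncated = truncated)
}

render_lateral_path <- function(spec, bx, by, side) {
  a <- stats::runif(1, spec$lateral_angle[1], spec$lateral_angle[2]) * pi / 180
  len <- round(stats::runif(1, spec$lateral_length[1], spec$lateral_length[2]))
  if (len < 1L) return(NULL)
  dxy <- c(side * sin(a), cos(a))
  xs <- bx + dxy[1] * seq_len(len)
  ys <- by + dxy[2] * seq_len(len)
  ok <- xs >= 0 & xs <= spec$width - 1L & ys <= spec$height - 1L
  if (!any(ok)) return(NULL)
  list(x = xs[ok], y = ys[ok])
}

# stamp a polyline onto the coverage canvas A (values in [0, 1], max-combined)
stamp_stroke <- function(A, xs, ys, half_width, profile) {
  H <- nrow(A); W <- ncol(A)
  sigma <- half_width / 2
  r <- if (profile == "gauss") ceiling(3 * sigma) else ceiling(half_width)
  for (i in seq_along(xs)) {
    cx <- round(xs[i]); cy <- round(ys[i])
    jx <- max(0L, cx - r):min(W - 1L, cx + r)
    jy <- max(0L, cy - r):min(H - 1L, cy + r)
    d2 <- outer((jy - ys[i])^2, (jx - xs[i])^2, "+")
    v <- if (profile == "gauss") exp(-d2 / (2 * sigma^2))
         else (d2 <= half_width^2) * 1
    blk <- A[jy + 1L, jx + 1L, drop = FALSE]
    A[jy + 1L, jx + 1L] <- pmax(blk, v)
  }
  A
}

#' Render one synthetic root well
#'
#' Draws the primary root polyline (unit steps downward from a top-strip
#' start point, sinusoidally swaying heading), adds laterals branching below
#' 20% of the primary's length, strokes everything at the configured
#' half-width and intensity, then applies Gaussian and salt noise. A root
#' longer than the well is truncated at the bottom row and the truth records
#' the truncated length.
#'
#' @param spec A [synthetic_root_spec()].
#' @return List with `image` (`H x W` 8-bit integer matrix) and `truth`
#'   (list: `mask` — pre-noise root pixels, `primary_length`,
#'   `lateral_count`, `max_depth`, `start_x`, `start_y`, `truncated`).
#' @export
generate_root_well <- function(spec) {
  stopifnot(inherits(spec, "synthetic_root_spec"))
  withr::with_seed(spec$seed, {
    prim <- render_primary_path(spec)
    A <- matrix(0, spec$height, spec$width)
    A <- stamp_stroke(A, prim$x, prim$y, spec$half_width, spec$profile)
    n_lat <- 0L
    if (spec$n_laterals > 0L && prim$steps > 10L) {
      lo <- max(2L, round(0.2 * prim$steps))
      branch_at <- sort(sample(lo:prim$steps, spec$n_laterals, replace = TRUE))
      sides <- sample(c(-1, 1), spec$n_laterals, replace = TRUE)
      for (j in seq_len(spec$n_laterals)) {
        lat <- render_lateral_path(spec, prim$x[branch_at[j]],
                                   prim$y[branch_at[j]], sides[j])
        if (!is.null(lat)) {
          A <- stamp_stroke(A, lat$x, lat$y, spec$half_width, spec$profile)
          n_lat <- n_lat + 1L
        }
      }
    }
    clean <- round(spec$background + (spec$root_intensity - spec$background) * A)
    mask <- clean != spec$background
    img <- clean
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    }
    if (spec$salt_density > 0) {
      n_salt <- stats::rbinom(1, length(img), spec$salt_density)
      if (n_salt > 0) {
        img[sample(length(img), n_salt)] <- spec$salt_intensity
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    dim(img) <- c(spec$height, spec$width)
    list(image = img,
         truth = list(mask = mask,
                      primary_length = prim$steps,
                      lateral_count = n_lat,
                      max_depth = floor(max(prim$y)),
                      start_x = prim$x[1], start_y = prim$y[1],
                      truncated = prim$truncated))
  })
}

#' Composite synthetic wells into a plate image
#'
#' @param specs List of [synthetic_root_spec()], one per grid well.
#' @param grid A [well_grid()] giving each well's rectangle in the plate.
#' @param margin_intensity 8-bit intensity of the inter-well plate material.
#' @return List with `image` (plate-sized 8-bit matrix) and `truths`
#'   (list of per-well ground truths, left to right).
#' @export
generate_plate <- function(specs, grid, margin_intensity = 12L) {
  stopifnot(inherits(grid, "well_grid"))
  if (length(specs) != grid$n_wells) {
    abort(sprintf("got %d specs for a %d-well grid",
                  length(specs), grid$n_wells),
          class = "rootproxy_config_error")
  }
  r <- grid$well_rects
  Wimg <- max(r$x0 + r$width) + 10L
  Himg <- max(r$y0 + r$height) + 10L
  canvas <- matrix(as.integer(margin_intensity), Himg, Wimg)
  truths <- vector("list", grid$n_wells)
  for (i in seq_len(grid$n_wells)) {
    gw <- generate_root_well(specs[[i]])
    if (nrow(gw$image) != r$height[i] || ncol(gw$image) != r$width[i]) {
      abort(sprintf("spec %d renders %dx%d but grid well is %dx%d", i,
                    ncol(gw$image), nrow(gw$image), r$width[i], r$height[i]),
            class = "rootproxy_config_error")
    }
    canvas[r$y0[i] + seq_len(r$height[i]),
           r$x0[i] + seq_len(r$width[i])] <- gw$image
    truths[[i]] <- gw$truth
  }
  list(image = canvas, truths = truths)
}

#' Synthetic top-down rosette image
#'
#' Saturated coloured discs ("leaves") on a pure white background; the truth
#' leaf pixel count is exactly the number of rendered non-white pixels.
#'
#' @param leaf_count Number of discs.
#' @param radius_range Disc radius range, pixels.
#' @param hue Disc hue in degrees.
#' @param seed Random seed.
#' @param width,height Image size.
#' @return List with `image` (`H x W x 3` 8-bit array) and `truth`
#'   (list: `leaf_pixels`).
#' @export
generate_top_view <- function(leaf_count, radius_range = c(8, 16),
                              hue = 120, seed = 1L,
                              width = 240L, height = 240L) {
  stopifnot(all(radius_range > 0))
  withr::with_seed(seed, {
    img <- array(255L, dim = c(height, width, 3L))
    col <- grDevices::col2rgb(grDevices::hsv(hue / 360, s = 0.9, v = 0.85))
    covered <- matrix(FALSE, height, width)
    if (leaf_count > 0) {
      for (i in seq_len(leaf_count)) {
        r <- stats::runif(1, radius_range[1], radius_range[2])
        cx <- stats::runif(1, width * 0.25, width * 0.75)
        cy <- stats::runif(1, height * 0.25, height * 0.75)
        jx <- max(0, floor(cx - r)):min(width - 1, ceiling(cx + r))
        jy <- max(0, floor(cy - r)):min(height - 1, ceiling(cy + r))
        d2 <- outer((jy - cy)^2, (jx - cx)^2, "+")
        inside <- d2 <= r^2
        for (ch in 1:3) {
          blk <- img[jy + 1L, jx + 1L, ch]
          blk[inside] <- col[ch]
          img[jy + 1L, jx + 1L, ch] <- blk
        }
        cov <- covered[jy + 1L, jx + 1L]
        covered[jy + 1L, jx + 1L] <- cov | inside
      }
    }
    list(image = img, truth = list(leaf_pixels = sum(covered)))
  })
}

#' Sample a population of synthetic wells under one growth condition
#'
#' Two parameterised conditions stand in for a growth experiment with and
#' without a root-inhibiting treatment: `"inhibited"` wells draw
#' stochastically shorter primary roots and fewer laterals than
#' `"control"`. Defaults: control length ~ Normal(450, 80) px with
#' Poisson(8) laterals; inhibited length ~ Normal(200, 50) px with
#' Poisson(3) laterals; lengths clamped to the well.
#'
#' @param n_wells Number of wells to sample.
#' @param condition `"control"` or `"inhibited"`.
#' @param seed Random seed (per-well seeds are derived from it).
#' @param params Optional overrides: list with `length_mean`, `length_sd`,
#'   `length_range`, `lateral_lambda`.
#' @param ... Further arguments passed to [synthetic_root_spec()] (well
#'   size, noise, ...).
#' @return List with `specs` (list of specs) and `truth` (tibble:
#'   `condition`, `length`, `laterals` as sampled).
#' @export
generate_population <- function(n_wells, condition = c("control", "inhibited"),
                                seed = 1L, params = NULL, ...) {
  condition <- match.arg(condition)
  defaults <- if (condition == "control") {
    list(length_mean = 450, length_sd = 80, length_range = c(120, 680),
         lateral_lambda = 8)
  } else {
    list(length_mean = 200, length_sd = 50, length_range = c(60, 400),
         lateral_lambda = 3)
  }
  p <- utils::modifyList(defaults, params %||% list())
  withr::with_seed(seed, {
    lens <- pmin(pmax(stats::rnorm(n_wells, p$length_mean, p$length_sd),
                      p$length_range[1]), p$length_range[2])
    lats <- stats::rpois(n_wells, p$lateral_lambda)
    well_seeds <- sample.int(2^30, n_wells)
  })
  specs <- purrr::pmap(list(lens, lats, well_seeds), function(l, nl, s) {
    synthetic_root_spec(length = l, n_laterals = nl, seed = s, ...)
  })
  list(specs = specs,
       truth = tibble(condition = condition, length = lens,
                      laterals = as.integer(lats)))
}

#' @importFrom rlang %||%
NULL

#' Write a reproducible synthetic dataset to disk
#'
#' Renders `n_plates` plate images (PNG) plus a ground-truth CSV — the
#' fixture backend of the command-line interface.
#'
#' @param dir Output directory (created if missing).
#' @param n_plates Number of plate images.
#' @param grid A [well_grid()]; defaults to an 8-well row of 100 x 220 wells.
#' @param seed Random seed.
#' @param ... Passed to [synthetic_root_spec()] (noise levels etc.); well
#'   size comes from the grid.
#' @return Invisibly, a tibble of truth rows (one per well).
#' @export
write_synthetic_dataset <- function(dir, n_plates = 3L, grid = NULL,
                                    seed = 1L, ...) {
  if (is.null(grid)) {
    grid <- well_grid_row(8L, well_width = 100L, well_height = 220L,
                          x0 = 10L, y0 = 10L, gap = 8L)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- grid$well_rects
  rows <- list()
  for (pl in seq_len(n_plates)) {
    withr::with_seed(seed + pl, {
      lens <- stats::runif(grid$n_wells, 0.3, 0.85) * min(r$height)
      lats <- stats::rpois(grid$n_wells, 4)
      sds <- sample.int(2^30, grid$n_wells)
    })
    specs <- purrr::pmap(list(lens, lats, sds), function(l, nl, s) {
      synthetic_root_spec(width = r$width[1], height = r$height[1],
                          length = l, n_laterals = nl, seed = s, ...)
    })
    plate <- generate_plate(specs, grid)
    fn <- sprintf("plate_%03d.png", pl)
    png::writePNG(plate$image / 255, file.path(dir, fn))
    rows[[pl]] <- tibble(
      file = fn, well_index = seq_len(grid$n_wells) - 1L,
      true_length = purrr::map_dbl(plate$truths, "primary_length"),
      true_laterals = purrr::map_int(plate$truths, "lateral_count"),
      true_max_depth = purrr::map_dbl(plate$truths, "max_depth")
    )
  }
  truth <- dplyr::bind_rows(rows)
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  invisible(truth)
}
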