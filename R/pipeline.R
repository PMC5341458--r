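# Batch pipeline: directories of plate images in, one traits CSV out, no
# interaction. Failures are quarantined per image so an unattended run over
# thousands of plates never stops on one bad file.

#' Run configuration
#'
#' Bundles everything a batch run needs. Only `input` and `grid` are
#' required; all method parameters have the package defaults.
#'
#' @param input Input directory or glob of side-view plate images.
#' @param grid Side camera [well_grid()].
#' @param output Output CSV path.
#' @param bounds [stretch_bounds()] applied to every image (fixed lighting
#'   makes one batch-wide pair sufficient).
#' @param top_input Optional directory of top-down images, paired to side
#'   images by shared filename stem (`top_suffix` appended).
#' @param top_grid Top camera [well_grid()] (required with `top_input`).
#' @param top_suffix Filename stem suffix of top images, default `"_top"`.
#' @param min_seed_intensity Minimum normalised intensity for seed points.
#' @param exponent Likelihood exponent.
#' @param norm_mode `"well"`, `"theoretical"` or `"empirical"` (see
#'   [norm_max()]); `"empirical"` triggers a two-pass batch.
#' @param weight_mode Edge-weight mode, `"clamp"` or `"scaled"`.
#' @param sat_threshold Leaf-mask saturation threshold.
#' @param heatmaps Optional directory for per-well likelihood heat-map PNGs.
#' @param verbose Log one line per image to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(input, grid, output = "traits.csv",
                       bounds = stretch_bounds(),
                       top_input = NULL, top_grid = NULL, top_suffix = "_top",
                       min_seed_intensity = 0.2,
                       exponent = 1, norm_mode = "well",
                       weight_mode = "clamp",
                       sat_threshold = 0.20,
                       heatmaps = NULL, verbose = FALSE) {
  norm_mode <- match.arg(norm_mode, c("well", "theoretical", "empirical"))
  weight_mode <- match.arg(weight_mode, c("clamp", "scaled"))
  stopifnot(inherits(grid, "well_grid"))
  if (!is.null(top_input) && is.null(top_grid)) {
    abort("top_input needs a top_grid", class = "rootproxy_config_error")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Expected keys: `input`, `output`, `wells` (list of `[x0, y0, width,
#' height]`), `strip_fraction`, `stretch: [low, high]`, and optionally
#' `top_input`, `top_wells`, `top_suffix`, `min_seed_intensity`, `exponent`,
#' `norm_mode`, `weight_mode`, `sat_threshold`, `heatmaps`.
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: '", path, "'"),
          class = "rootproxy_io_error")
  }
  y <- yaml::read_yaml(path)
  rects_tbl <- function(w) {
    m <- do.call(rbind, w)
    tibble(x0 = m[, 1], y0 = m[, 2], width = m[, 3], height = m[, 4])
  }
  grid <- well_grid(rects_tbl(y$wells),
                    strip_fraction = y$strip_fraction %||% 0.05)
  top_grid <- if (!is.null(y$top_wells)) well_grid(rects_tbl(y$top_wells))
  args <- list(
    input = y$input, grid = grid,
    output = y$output %||% "traits.csv",
    bounds = if (!is.null(y$stretch))
      stretch_bounds(y$stretch[[1]], y$stretch[[2]]) else stretch_bounds(),
    top_input = y$top_input, top_grid = top_grid,
    top_suffix = y$top_suffix %||% "_top",
    min_seed_intensity = y$min_seed_intensity %||% 0.2,
    exponent = y$exponent %||% 1,
    norm_mode = y$norm_mode %||% "well",
    weight_mode = y$weight_mode %||% "clamp",
    sat_threshold = y$sat_threshold %||% 0.20,
    heatmaps = y$heatmaps
  )
  do.call(run_config, utils::modifyList(args, list(...)))
}

# distance maps and seed status for every well of one image
image_distance_maps <- function(path, config) {
  img <- load_plate_image(path)
  gray <- contrast_stretch(to_grayscale(img), config$bounds)
  wells <- extract_wells(gray, config$grid)
  purrr::map(wells, function(w) {
    seeds <- detect_seed_points(w, config$grid$strip_fraction,
                                config$min_seed_intensity)
    if (nrow(seeds$points) == 0L) {
      list(well = w, dist = NULL, empty = TRUE)
    } else {
      list(well = w,
           dist = multi_source_dijkstra(w, seeds, config$weight_mode),
           empty = FALSE)
    }
  })
}

#' Process one plate image into per-well trait records
#'
#' Runs the full chain — load, grayscale, stretch, well extraction, seed
#' detection, multi-source Dijkstra, likelihood, traits, and (when a paired
#' top image exists) shoot traits — and returns one record per well. Wells
#' with no seed points are emitted as flagged zero records, never an error.
#'
#' @param path Image path.
#' @param config A [run_config()].
#' @param batch_norm_max Normalising constant computed in a first pass
#'   (used when `norm_mode = "empirical"`).
#' @return A tibble with `grid$n_wells` rows.
#' @export
process_image <- function(path, config, batch_norm_max = NULL) {
  image_id <- tools::file_path_sans_ext(basename(path))
  dmaps <- image_distance_maps(path, config)
  recs <- purrr::imap(dmaps, function(d, i) {
    if (d$empty) {
      return(well_traits(NULL, NULL, image_id, i - 1L, empty = TRUE))
    }
    nm <- switch(config$norm_mode,
      well = max(d$dist$distances),
      theoretical = d$well$height + d$well$width,
      empirical = batch_norm_max %||% max(d$dist$distances)
    )
    lmap <- likelihood(d$dist, norm_max = nm, exponent = config$exponent)
    if (!is.null(config$heatmaps)) {
      write_heatmap(lmap, file.path(
        config$heatmaps, sprintf("%s_well%02d.png", image_id, i - 1L)))
    }
    well_traits(lmap, orientation_field(d$well), image_id, i - 1L)
  })
  out <- dplyr::bind_rows(recs)
  if (!is.null(config$top_input)) {
    out <- dplyr::bind_cols(out, image_shoot_traits(path, config))
  }
  out
}

image_shoot_traits <- function(path, config) {
  stem <- tools::file_path_sans_ext(basename(path))
  candidates <- file.path(config$top_input,
                          paste0(stem, config$top_suffix, ".",
                                 c("png", "tif", "tiff", "jpg", "jpeg")))
  top_path <- candidates[file.exists(candidates)][1]
  n <- config$grid$n_wells
  if (is.na(top_path)) {
    return(tibble(leaf_area = rep(NA_integer_, n),
                  leaf_hue = rep(NA_real_, n)))
  }
  top <- load_plate_image(top_path)
  regions <- extract_top_wells(top, config$top_grid)
  dplyr::bind_rows(purrr::map(regions, shoot_traits,
                              sat_threshold = config$sat_threshold))
}

#' Batch-process a directory of plate images
#'
#' Lists the input images (lexicographic order, so reruns are
#' reproducible), processes each independently, and writes all trait
#' records to one CSV, atomically (temp file, then rename). An unreadable
#' image is logged and skipped; the batch always completes. With
#' `norm_mode = "empirical"` a first pass computes every well's maximum
#' path cost and the batch-mean normaliser before traits are measured.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `traits` (the tibble written), `summary`
#'   (tibble: images, wells, empties, failures) and `failed` (paths).
#' @export
run_batch <- function(config) {
  files <- list_input_files(config$input)
  if (length(files) == 0L) {
    abort(paste0("no input images match '", config$input, "'"),
          class = "rootproxy_io_error")
  }
  files <- sort(files)

  batch_nm <- NULL
  if (config$norm_mode == "empirical") {
    maxima <- purrr::map(files, function(f) {
      tryCatch(
        purrr::map_dbl(image_distance_maps(f, config), function(d)
          if (d$empty) NA_real_ else max(d$dist$distances)),
        error = function(e) NULL)
    })
    maxima <- unlist(maxima)
    maxima <- maxima[is.finite(maxima)]
    if (length(maxima) == 0L) {
      abort("empirical norm_mode found no non-empty wells",
            class = "rootproxy_config_error")
    }
    batch_nm <- mean(maxima)
  }

  failed <- character()
  recs <- purrr::map(files, function(f) {
    if (isTRUE(config$verbose)) message("processing ", f)
    tryCatch(process_image(f, config, batch_norm_max = batch_nm),
             error = function(e) {
               message("skipping '", f, "': ", conditionMessage(e))
               failed <<- c(failed, f)
               NULL
             })
  })
  traits <- dplyr::bind_rows(recs)

  dir.create(dirname(config$output), showWarnings = FALSE, recursive = TRUE)
  tmp <- paste0(config$output, ".tmp")
  readr::write_csv(traits, tmp)
  file.rename(tmp, config$output)

  summary <- tibble(
    images = length(files) - length(failed),
    wells = nrow(traits),
    empties = sum(traits$empty_flag),
    failures = length(failed)
  )
  if (isTRUE(config$verbose)) {
    message(sprintf("batch done: %d images, %d wells (%d empty), %d failures",
                    summary$images, summary$wells, summary$empties,
                    summary$failures))
  }
  invisible(list(traits = traits, summary = summary, failed = failed))
}

list_input_files <- function(input) {
  exts <- "\\.(png|tif|tiff|jpg|jpeg)$"
  if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = exts, full.names = TRUE, ignore.case = TRUE)
  } else {
    Sys.glob(input)
  }
}
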