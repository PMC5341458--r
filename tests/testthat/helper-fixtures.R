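# Shared fixtures: tiny wells built in code, plus an independent
# shortest-path oracle (igraph) for checking the Dijkstra engine.

# A noise-free straight vertical root of the given length; sharp stroke so
# the rendered mask is exact.
straight_root_spec <- function(length = 300, width = 120L, height = 340L,
                               start_x = 60, start_y = 10L, seed = 7L,
                               half_width = 2, ...) {
  synthetic_root_spec(width = width, height = height, length = length,
                      curvature = 0, n_laterals = 0,
                      noise_sd = 0, salt_density = 0,
                      root_intensity = 220L, background = 30L,
                      half_width = half_width,
                      start_x = start_x, start_y = start_y,
                      profile = "sharp", seed = seed, ...)
}

# Stretch bounds matched to the synthetic generator: low above the
# background noise band (30 + 3 * 6), high just below root intensity.
synthetic_bounds <- function() stretch_bounds(48, 230)

# Independent multi-source shortest-path oracle over the same pixel graph,
# via igraph; never touches the package's Dijkstra.
oracle_distances <- function(intens, seeds_x, seeds_y) {
  H <- nrow(intens); W <- ncol(intens)
  id <- function(x, y) y * W + x + 1L
  px <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(-1, 1, 1))
  edges <- do.call(rbind, lapply(shifts, function(k) {
    nx <- px$x + k[1]; ny <- px$y + k[2]
    ok <- nx >= 0 & nx < W & ny < H
    data.frame(from = id(px$x[ok], px$y[ok]), to = id(nx[ok], ny[ok]),
               diag = as.logical(k[3]))
  }))
  ids_rc <- function(n) cbind((n - 1) %/% W + 1, (n - 1) %% W + 1)
  wt <- edge_weight(intens[ids_rc(edges$from)], intens[ids_rc(edges$to)],
                    diagonal = edges$diag)
  from <- edges$from; to <- edges$to
  g <- igraph::add_edges(igraph::make_empty_graph(n = H * W, directed = FALSE),
                         rbind(from, to))
  D <- igraph::distances(g, v = id(seeds_x, seeds_y), weights = wt,
                         algorithm = "dijkstra")
  matrix(apply(D, 2, min), H, W, byrow = TRUE)
}

# uniform-likelihood map over an arbitrary matrix shape
uniform_lmap <- function(H, W, value = 1) {
  likelihood_map(matrix(value, H, W))
}
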