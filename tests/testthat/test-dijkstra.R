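test_that("edge weights follow the intensity-product formula with clamping", {
  expect_equal(edge_weight(0, 0), 1)
  expect_equal(edge_weight(0, 0, diagonal = TRUE), 1)
  expect_equal(edge_weight(1, 1), 0)
  # raw diagonal value 1 - sqrt(2) is negative; clamped to zero
  expect_equal(edge_weight(1, 1, diagonal = TRUE), 0)
  expect_equal(edge_weight(0.5, 0.8), 1 - 0.4)
  expect_equal(edge_weight(0.9, 0.9, diagonal = TRUE, mode = "scaled"),
               sqrt(2) * (1 - 0.81))
  expect_error(edge_weight(1.2, 0.5), class = "rootproxy_contract_error")
})

test_that("all-dark 3x3 well distances match hand enumeration", {
  w <- gray_well(matrix(0, 3, 3))
  d <- multi_source_dijkstra(w, data.frame(x = 1L, y = 0L))
  # every step costs 1 (orthogonal or diagonal: I*I = 0), so the distance
  # is the chessboard distance from the seed
  expected <- matrix(c(1, 1, 1,
                       1, 1, 1,
                       2, 2, 2), 3, 3, byrow = TRUE)
  expected[1, 2] <- 0
  expect_equal(d$distances, expected)
})

test_that("distances are zero exactly at seeds and finite everywhere", {
  set.seed(5)
  m <- matrix(runif(30 * 20), 30, 20)
  seeds <- data.frame(x = c(3L, 15L), y = c(0L, 2L))
  d <- multi_source_dijkstra(gray_well(m), seeds)
  expect_true(all(is.finite(d$distances)))
  expect_equal(d$distances[cbind(seeds$y + 1, seeds$x + 1)], c(0, 0))
  expect_true(all(d$distances >= 0))
})

test_that("multi-source Dijkstra matches the independent igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:12) {
    H <- sample(10:16, 1); W <- sample(10:16, 1)
    m <- matrix(runif(H * W), H, W)
    ns <- sample(1:4, 1)
    sx <- sample(0:(W - 1), ns); sy <- sample(0:(H - 1), ns)
    d <- multi_source_dijkstra(gray_well(m), data.frame(x = sx, y = sy))
    expect_equal(d$distances, oracle_distances(m, sx, sy), tolerance = 1e-12)
  }
})

test_that("multi-source distances equal the pointwise minimum over single sources", {
  set.seed(23)
  m <- matrix(runif(15 * 15), 15, 15)
  seeds <- data.frame(x = c(2L, 9L, 14L), y = c(0L, 1L, 0L))
  multi <- multi_source_dijkstra(gray_well(m), seeds)$distances
  singles <- lapply(seq_len(nrow(seeds)), function(i)
    multi_source_dijkstra(gray_well(m), seeds[i, ])$distances)
  expect_equal(multi, pmin(singles[[1]], singles[[2]], singles[[3]]))
})

test_that("raising any pixel's intensity never increases any distance", {
  set.seed(31)
  m <- matrix(runif(12 * 12, 0, 0.9), 12, 12)
  seeds <- data.frame(x = 5L, y = 0L)
  base <- multi_source_dijkstra(gray_well(m), seeds)$distances
  for (i in 1:10) {
    m2 <- m
    px <- sample(length(m2), 1)
    m2[px] <- min(1, m2[px] + runif(1, 0.05, 0.5))
    d2 <- multi_source_dijkstra(gray_well(m2), seeds)$distances
    expect_true(all(d2 <= base + 1e-12))
  }
})

test_that("repeated runs are bit-identical", {
  set.seed(41)
  m <- matrix(runif(20 * 20), 20, 20)
  seeds <- data.frame(x = c(0L, 19L), y = c(0L, 0L))
  d1 <- multi_source_dijkstra(gray_well(m), seeds)$distances
  d2 <- multi_source_dijkstra(gray_well(m), seeds)$distances
  expect_identical(d1, d2)
})
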