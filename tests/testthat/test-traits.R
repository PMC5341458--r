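test_that("centroid is the likelihood-weighted mean position", {
  expect_equal(centroid(uniform_lmap(11, 7)), c(x = 3, y = 5))
  L <- matrix(0, 5, 9); L[3, 5] <- 0.4
  expect_equal(centroid(likelihood_map(L)), c(x = 4, y = 2))
  # {(x=0,y=0): 1, (x=2,y=0): 3} -> x = 1.5
  L <- matrix(0, 1, 3); L[1, 1] <- 0.25; L[1, 3] <- 0.75
  expect_equal(centroid(likelihood_map(L))[["x"]], 1.5)
  expect_true(all(is.na(centroid(likelihood_map(matrix(0, 3, 3))))))
})

test_that("mass sums likelihoods; mass_norm divides by pixel count", {
  expect_equal(trait_mass(likelihood_map(matrix(0, 10, 10))), 0)
  expect_equal(trait_mass(uniform_lmap(10, 10)), 100)
  chk <- matrix(rep(c(1, 0), 50), 10, 10)
  expect_equal(trait_mass(likelihood_map(chk)), 50)
})

test_that("argmax bounding box scores extremities by likelihood times distance", {
  L <- matrix(0, 50, 20); L[41, 6] <- 0.7  # (x=5, y=40)
  bb <- bbox_argmax(likelihood_map(L))
  expect_equal(bb[["width_m"]], 1)
  expect_equal(bb[["depth_m"]], 40)
  # uniform field: pure coordinate argmax
  bb <- bbox_argmax(uniform_lmap(30, 12))
  expect_equal(bb[["right"]], 11)
  expect_equal(bb[["bottom"]], 29)
  expect_equal(bb[["left"]], 0)
  # a dim far pixel can outscore a bright near one: 0.3*8 > 0.9*2
  L <- matrix(0, 1, 10); L[1, 3] <- 0.9; L[1, 9] <- 0.3
  expect_equal(bbox_argmax(likelihood_map(L))[["right"]], 8)
})

test_that("quantile boxes follow cumulative-mass definitions", {
  # all mass in one row
  L <- matrix(0, 200, 10); L[101, ] <- 1
  expect_equal(bbox_quantile(likelihood_map(L), 0.95)[["depth"]], 100)
  # uniform over 100 rows: first row reaching 95% is index 94
  expect_equal(bbox_quantile(uniform_lmap(100, 10), 0.95)[["depth"]], 94)
  # 99 units at y=10, 1 unit at y=500
  L <- matrix(0, 600, 5); L[11, 1] <- 99; L[501, 1] <- 1
  L <- L / max(L)
  expect_equal(bbox_quantile(likelihood_map(L), 0.95)[["depth"]], 10)
  expect_equal(bbox_quantile(likelihood_map(L), 1.0)[["depth"]], 500)
})

test_that("quadrant masses partition the well top to bottom and conserve mass", {
  lm <- uniform_lmap(40, 10)
  qm <- quadrant_mass(lm)
  expect_equal(unname(qm), rep(100, 4))
  # all mass in the bottom row lands in q3
  L <- matrix(0, 41, 10); L[41, ] <- 1  # H = 41: remainder row joins q3
  qm <- quadrant_mass(likelihood_map(L))
  expect_equal(unname(qm), c(0, 0, 0, 10))
  set.seed(3)
  for (i in 1:20) {
    H <- sample(8:37, 1); W <- sample(3:15, 1)
    lm <- likelihood_map(matrix(runif(H * W), H, W))
    expect_equal(sum(quadrant_mass(lm)), trait_mass(lm), tolerance = 1e-12)
  }
})

test_that("structure angle reads 90 for vertical roots and 0 for horizontal", {
  m <- matrix(0, 21, 21)
  m[, 10:12] <- 1  # vertical bright stripe
  f <- orientation_field(gray_well(m))
  flank <- f$magnitude[8:14, 9] > 0
  expect_true(all(abs(f$theta[8:14, 9][flank] - 90) < 1e-9))
  m2 <- t(m)       # horizontal stripe
  f2 <- orientation_field(gray_well(m2))
  flank2 <- f2$magnitude[9, 8:14] > 0
  expect_true(all(abs(f2$theta[9, 8:14][flank2]) < 1e-9))
  # uniform image: magnitude identically zero
  fu <- orientation_field(gray_well(matrix(0.5, 9, 9)))
  expect_true(all(fu$magnitude == 0))
})

test_that("orientation histogram bins likelihood by structure angle", {
  # single oriented pixel with L = 0.8 at 45 degrees -> bin [45, 54)
  f <- structure(list(theta = matrix(45, 1, 1), magnitude = matrix(5, 1, 1),
                      width = 1, height = 1), class = "orientation_field")
  lm <- likelihood_map(matrix(0.8, 1, 1))
  oh <- orientation_histogram(lm, f)
  expect_equal(unname(oh[6]), 0.8)
  expect_equal(sum(oh), 0.8)
  # zero-gradient well contributes nothing
  fu <- orientation_field(gray_well(matrix(0.5, 9, 9)))
  expect_true(all(orientation_histogram(uniform_lmap(9, 9), fu) == 0))
})

test_that("orientation totals conserve across bins and quadrants", {
  set.seed(13)
  for (i in 1:20) {
    H <- sample(9:30, 1); W <- sample(9:30, 1)
    m <- matrix(runif(H * W), H, W)
    w <- gray_well(m)
    f <- orientation_field(w)
    lm <- likelihood_map(matrix(runif(H * W), H, W))
    oh <- orientation_histogram(lm, f)
    qo <- quadrant_orientation(lm, f)
    oriented_mass <- sum(lm$L[f$magnitude > 0])
    expect_equal(sum(oh), oriented_mass, tolerance = 1e-9)
    expect_equal(sum(qo), sum(oh), tolerance = 1e-9)
  }
})

test_that("diagonal texture lands in the third 4-bracket quadrant bin", {
  # 45-degree bright diagonal band: structure angle 45 -> bracket [45, 67.5)
  m <- outer(1:25, 1:25, function(y, x) as.numeric(abs(x - y) <= 1))
  w <- gray_well(m)
  f <- orientation_field(w)
  lm <- uniform_lmap(25, 25)
  qo <- quadrant_orientation(lm, f)
  by_bracket <- tapply(qo, rep(1:4, 4), sum)
  expect_gt(by_bracket[[3]] / sum(qo), 0.8)
})

test_that("trait records shift with translation and grow with elongation", {
  base <- analyse_well(generate_root_well(straight_root_spec())$image,
                       bounds = synthetic_bounds())
  for (k in c(3, 6)) {
    shifted <- analyse_well(
      generate_root_well(straight_root_spec(start_y = 10 + k))$image,
      bounds = synthetic_bounds())
    expect_equal(shifted$traits$depth_m, base$traits$depth_m + k)
    expect_equal(shifted$traits$centroid_y, base$traits$centroid_y + k,
                 tolerance = 0.05)
  }
  longer <- analyse_well(generate_root_well(straight_root_spec(length = 250,
                                                              height = 400))$image,
                         bounds = synthetic_bounds())
  shorter <- analyse_well(generate_root_well(straight_root_spec(length = 150,
                                                               height = 400))$image,
                          bounds = synthetic_bounds())
  expect_gt(longer$traits$depth_m, shorter$traits$depth_m)
  expect_gt(longer$traits$depth_p95, shorter$traits$depth_p95)
  expect_gt(longer$traits$depth_p99, shorter$traits$depth_p99)
  expect_gt(longer$traits$mass_q3, shorter$traits$mass_q3)
})
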