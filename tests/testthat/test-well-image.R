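test_that("plate images round-trip through PNG and grayscale TIFF", {
  img <- array(0L, dim = c(20, 30, 3))
  img[, , 1] <- 10L; img[, , 2] <- 200L; img[, , 3] <- 77L
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img / 255, f)
  got <- load_plate_image(f)
  expect_equal(dim(got), c(20, 30, 3))
  expect_equal(got, img)

  g <- matrix(seq(0, 255, length.out = 12) / 255, 3, 4)
  ft <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(g, ft)
  got <- load_plate_image(ft)
  expect_equal(dim(got), c(3, 4, 3))
  expect_equal(got[, , 1], got[, , 2])
  expect_equal(got[, , 2], got[, , 3])
})

test_that("unreadable or unsupported files raise typed errors naming the path", {
  expect_error(load_plate_image("no/such/file.png"), "no/such/file",
               class = "rootproxy_io_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_plate_image(bad), class = "rootproxy_io_error")
  txt <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", txt)
  expect_error(load_plate_image(txt), class = "rootproxy_format_error")
})

test_that("grayscale conversion uses luma weighting", {
  px <- function(r, g, b) {
    a <- array(0, dim = c(1, 1, 3)); a[1, 1, ] <- c(r, g, b); a
  }
  expect_equal(to_grayscale(px(255, 255, 255))[1, 1], 255L)
  expect_equal(to_grayscale(px(0, 0, 0))[1, 1], 0L)
  # round(0.299*100 + 0.587*200 + 0.114*50) = round(153.0) = 153
  expect_equal(to_grayscale(px(100, 200, 50))[1, 1], 153L)
})

test_that("contrast stretch maps endpoints, midpoints, and is identity at (0,255)", {
  b <- stretch_bounds(64, 192)
  m <- matrix(c(64L, 192L, 128L, 0L, 255L), 1)
  expect_equal(as.vector(contrast_stretch(m, b)), c(0L, 255L, 128L, 0L, 255L))
  v <- matrix(0:255, 16, 16)
  expect_identical(contrast_stretch(v, stretch_bounds(0, 255)), v)
  # idempotent under identity bounds
  s <- contrast_stretch(v, b)
  expect_identical(contrast_stretch(s, stretch_bounds(0, 255)), s)
})

test_that("contrast stretch preserves pixel ordering", {
  set.seed(1)
  v <- matrix(sample(0:255, 400, replace = TRUE), 20)
  for (b in list(stretch_bounds(10, 60), stretch_bounds(100, 240))) {
    out <- contrast_stretch(v, b)
    o <- order(v)
    expect_true(all(diff(out[o]) >= 0))
  }
  expect_error(stretch_bounds(200, 100), class = "rootproxy_config_error")
})

test_that("wells extract in order, normalised to [0,1], and reassemble exactly", {
  set.seed(2)
  img <- matrix(sample(0:255, 60 * 100, replace = TRUE), 60, 100)
  grid <- well_grid_row(3, well_width = 30, well_height = 50,
                        x0 = 2, y0 = 5, gap = 2)
  wells <- extract_wells(img, grid)
  expect_length(wells, 3)
  expect_equal(wells[[1]]$well_index, 0L)
  expect_true(all(vapply(wells, function(w)
    all(w$intensities >= 0 & w$intensities <= 1), TRUE)))
  # reassembly reproduces the source pixels
  rebuilt <- img
  for (i in 1:3) {
    r <- grid$well_rects[i, ]
    rebuilt[r$y0 + seq_len(r$height), r$x0 + seq_len(r$width)] <-
      round(wells[[i]]$intensities * 255)
  }
  expect_equal(rebuilt, img)

  uni <- matrix(128L, 40, 40)
  g1 <- well_grid(data.frame(x0 = 0, y0 = 0, width = 40, height = 40))
  w <- extract_wells(uni, g1)
  expect_equal(unique(as.vector(w[[1]]$intensities)), 128 / 255)
})

test_that("grids reject rectangles outside the image, naming the well", {
  img <- matrix(0L, 50, 50)
  g <- well_grid(data.frame(x0 = c(0, 30), y0 = 0, width = 25, height = 60))
  expect_error(extract_wells(img, g), "well 0",
               class = "rootproxy_config_error")
  expect_error(well_grid(data.frame(x0 = 0, y0 = 0, width = 10, height = 10),
                         strip_fraction = 1.5),
               class = "rootproxy_config_error")
})
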