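test_that("generation is byte-deterministic under a fixed seed", {
  spec <- synthetic_root_spec(width = 80, height = 160, length = 100,
                              n_laterals = 3, seed = 99)
  a <- generate_root_well(spec)
  b <- generate_root_well(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$mask, b$truth$mask)
  p1 <- generate_population(5, "control", seed = 4, width = 80L, height = 160L)
  p2 <- generate_population(5, "control", seed = 4, width = 80L, height = 160L)
  expect_identical(p1$truth, p2$truth)
})

test_that("noise-free sharp rendering matches the truth mask exactly", {
  spec <- straight_root_spec(length = 120, width = 80, height = 160,
                             start_x = 40, start_y = 4)
  gw <- generate_root_well(spec)
  expect_identical(gw$image != spec$background, gw$truth$mask)
  # straight, zero curvature: truth depth = start_y + length
  expect_equal(gw$truth$max_depth, 4 + 120)
  expect_equal(gw$truth$primary_length, 120)
  expect_false(gw$truth$truncated)
})

test_that("roots longer than the well truncate at the bottom row", {
  spec <- straight_root_spec(length = 500, width = 80, height = 160,
                             start_y = 4)
  gw <- generate_root_well(spec)
  expect_true(gw$truth$truncated)
  expect_lt(gw$truth$primary_length, 500)
  expect_lte(gw$truth$max_depth, 159)
  expect_gte(gw$truth$max_depth, 154)
})

test_that("plates composite wells at their rectangles and round-trip", {
  grid <- well_grid_row(4, well_width = 60, well_height = 120,
                        x0 = 5, y0 = 5, gap = 6)
  specs <- lapply(1:4, function(i)
    synthetic_root_spec(width = 60L, height = 120L, length = 70,
                        n_laterals = 1, seed = 10 + i))
  plate <- generate_plate(specs, grid)
  expect_length(plate$truths, 4)
  wells <- extract_wells(plate$image, grid)
  for (i in 1:4) {
    gw <- generate_root_well(specs[[i]])
    expect_equal(round(wells[[i]]$intensities * 255), gw$image,
                 ignore_attr = TRUE)
  }
  expect_error(generate_plate(specs[1:2], grid),
               class = "rootproxy_config_error")
})

test_that("population conditions have the intended ordering by construction", {
  ctrl <- generate_population(40, "control", seed = 8,
                              width = 120L, height = 400L)
  inhib <- generate_population(40, "inhibited", seed = 9,
                               width = 120L, height = 400L)
  expect_gt(mean(ctrl$truth$length), mean(inhib$truth$length))
  expect_gt(mean(ctrl$truth$laterals), mean(inhib$truth$laterals))
})

test_that("the fixture writer emits plates plus a consistent truth table", {
  dir <- withr::local_tempdir()
  truth <- write_synthetic_dataset(dir, n_plates = 2, seed = 3)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_length(pngs, 2)
  expect_equal(nrow(truth), 16)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  ondisk <- readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE)
  expect_equal(nrow(ondisk), 16)
  expect_true(all(ondisk$true_length <= 220))
})
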