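# Slide tiling and white-tile rejection.

test_that("grid dimensions follow the floor policy", {
  expect_equal(unname(grid_dimensions(126976, 126976, 2048)), c(62, 62))
  expect_equal(prod(grid_dimensions(126976, 126976, 2048)), 3844)
  expect_equal(unname(grid_dimensions(2048, 2048, 2048)), c(1, 1))
  expect_equal(unname(grid_dimensions(2047, 2047, 2048)), c(0, 0))
  # width drives columns, height drives rows
  expect_equal(unname(grid_dimensions(300, 100, 100)), c(1, 3))
  expect_error(grid_dimensions(0, 10, 10), "must be >= 1")
})

test_that("shannon entropy matches closed forms and its bounds", {
  expect_equal(shannon_entropy(constant_tile(255)), 0)
  expect_equal(shannon_entropy(two_level_tile(0, 255)), 1)
  g <- matrix(0:255, 16, 16)
  expect_equal(shannon_entropy(array(rep(g, 3), c(16, 16, 3))), 8)
  # bounded by log2 of distinct values present, invariant to permutation
  set.seed(42)
  for (k in c(2, 5, 17)) {
    vals <- sample(0:255, k)
    g <- matrix(sample(vals, 400, replace = TRUE), 20, 20)
    tile <- array(rep(g, 3), c(20, 20, 3))
    e <- shannon_entropy(tile)
    expect_lte(e, log2(k) + 1e-12)
    perm <- array(rep(matrix(sample(g), 20, 20), 3), c(20, 20, 3))
    expect_equal(shannon_entropy(perm), e)
  }
  expect_error(shannon_entropy(numeric(0)), "non-empty")
})

test_that("pixel variance is the population variance of the grayscale", {
  expect_equal(pixel_variance(constant_tile(100)), 0)
  expect_equal(pixel_variance(two_level_tile(0, 255)), 127.5^2)
  expect_equal(pixel_variance(array(7, c(1, 1, 3))), 0)  # single pixel
  set.seed(7)
  g <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  tile <- array(rep(g, 3), c(16, 16, 3))
  expect_equal(pixel_variance(tile), mean((g - mean(g))^2))
  perm <- array(rep(matrix(sample(g), 16, 16), 3), c(16, 16, 3))
  expect_equal(pixel_variance(perm), pixel_variance(tile))
})

test_that("informativeness requires both thresholds to pass", {
  cfg <- tile_filter_config()
  expect_false(is_informative(constant_tile(255), cfg))      # white tile
  expect_true(is_informative(make_tile("non_recurring", 128, seed = 5), cfg))
  # high variance but sub-threshold entropy still fails (OR-discard)
  low_entropy <- two_level_tile(0, 255)                      # 1 bit, var huge
  expect_gt(pixel_variance(low_entropy), 500)
  expect_false(is_informative(low_entropy, cfg))
  expect_error(tile_filter_config(entropy_min = 9), "0, 8")
  expect_error(tile_filter_config(tile_size = 0), ">= 1")
})

test_that("tile_slide keeps tissue, rejects white tiles, manifests everything", {
  syn <- make_slide(4, 4, recurring_fraction = 0.25, white_fraction = 0.25,
                    tile_size = 128, seed = 11)
  res <- tile_slide(syn$image, tile_filter_config(tile_size = 128))
  expect_equal(nrow(res$manifest), 16)
  expect_equal(sum(res$manifest$kept), 12)
  expect_length(res$tiles, 12)
  # kept flags align exactly with the generator's ground truth
  truth_white <- syn$truth$class == "white"
  ord <- order(syn$truth$row, syn$truth$col)
  expect_equal(res$manifest$kept, !truth_white[ord])
  # every grid position exactly once, row-major, with origin arithmetic
  expect_equal(res$manifest$row, rep(0:3, each = 4))
  expect_equal(res$manifest$col, rep(0:3, times = 4))
  expect_equal(res$manifest$origin_x, res$manifest$col * 128L)
  expect_equal(res$manifest$origin_y, res$manifest$row * 128L)
  # re-run is byte-identical
  res2 <- tile_slide(syn$image, tile_filter_config(tile_size = 128))
  expect_identical(res$manifest, res2$manifest)
})

test_that("all-tissue slides keep the full grid and tiny slides keep nothing", {
  syn <- make_slide(2, 3, tile_size = 128, seed = 3)
  res <- tile_slide(syn$image, tile_filter_config(tile_size = 128))
  expect_equal(sum(res$manifest$kept), 6)
  expect_warning(small <- tile_slide(constant_tile(200, 64),
                                     tile_filter_config(tile_size = 128)),
                 "zero-tile grid")
  expect_equal(nrow(small$manifest), 0)
  expect_length(small$tiles, 0)
})

test_that("slides round-trip through PNG and pyramidal TIFF readers", {
  syn <- make_slide(2, 2, white_fraction = 0.25, tile_size = 64, seed = 9)
  ref <- tile_slide(syn$image, tile_filter_config(tile_size = 64))

  png_path <- tempfile(fileext = ".png")
  png::writePNG(syn$image / 255, png_path)
  from_png <- tile_slide(png_path, tile_filter_config(tile_size = 64))
  expect_equal(from_png$manifest$kept, ref$manifest$kept)
  expect_equal(from_png$manifest$entropy_bits, ref$manifest$entropy_bits,
               tolerance = 1e-2)  # 8-bit quantization on write

  # two-page TIFF: the larger page is the highest-resolution level
  tif_path <- tempfile(fileext = ".tif")
  low <- resize_tile(syn$image, 32) / 255
  tiff::writeTIFF(list(low, syn$image / 255), tif_path)
  sr <- slide_ref(tif_path)
  expect_equal(c(sr$height_px, sr$width_px), c(128, 128))
  expect_equal(sr$level, 1L)
  expect_error(slide_ref("no/such/file.png"), "cannot read")
})

test_that("manifests and tiles are written to disk in the declared formats", {
  syn <- make_slide(2, 2, tile_size = 64, seed = 2)
  res <- tile_slide(syn$image, tile_filter_config(tile_size = 64))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_manifest(res$manifest, csv)
  write_manifest(res$manifest, json)
  back <- utils::read.csv(csv)
  expect_equal(back$kept, res$manifest$kept)
  expect_equal(nrow(jsonlite::fromJSON(json)), 4)
  dir <- tempfile()
  paths <- write_tiles(res$tiles, dir, "s1")
  expect_true(all(file.exists(file.path(dir, c("s1_r0_c0.png",
                                               "s1_r1_c1.png")))))
  expect_length(paths, 4)
})
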