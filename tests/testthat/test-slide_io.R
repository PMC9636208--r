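test_that("tile iteration partitions the raster row-major without overlap", {
  sl <- list(width_px = 100L, height_px = 100L)
  t64 <- iter_tiles(sl, 64)
  expect_equal(unname(as.matrix(t64)),
               matrix(c(0, 0, 64, 64, 64, 0, 100, 64,
                        0, 64, 64, 100, 64, 64, 100, 100),
                      ncol = 4, byrow = TRUE))
  ## tile >= slide -> single full-frame window
  t1 <- iter_tiles(sl, 128)
  expect_equal(nrow(t1), 1L)
  expect_equal(unlist(t1[1, ], use.names = FALSE), c(0, 0, 100, 100))
  ## coverage + disjointness for random sizes (brute-force pixel counting)
  set.seed(1)
  for (i in 1:20) {
    w <- sample(1:97, 1); h <- sample(1:83, 1); tp <- sample(1:50, 1)
    tiles <- iter_tiles(list(width_px = w, height_px = h), tp)
    cover <- matrix(0L, h, w)
    for (k in seq_len(nrow(tiles)))
      cover[(tiles$y0[k] + 1):tiles$y1[k], (tiles$x0[k] + 1):tiles$x1[k]] <-
        cover[(tiles$y0[k] + 1):tiles$y1[k], (tiles$x0[k] + 1):tiles$x1[k]] + 1L
    expect_true(all(cover == 1L))
  }
})

test_that("masks round-trip losslessly through PNG and TIFF", {
  set.seed(2)
  m <- matrix(runif(40 * 55) > 0.4, 40, 55)
  for (ext in c("png", "tif")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_mask(m, p)
    expect_identical(read_mask(p), m)
  }
  p <- tempfile(fileext = ".png")
  write_mask(matrix(FALSE, 8, 8), p)
  expect_true(all(png::readPNG(p) == 0))
  ## a 3-channel file is not a mask
  p3 <- tempfile(fileext = ".png")
  png::writePNG(array(runif(8 * 8 * 3), dim = c(8, 8, 3)), p3)
  expect_error(read_mask(p3), "single-channel")
})

test_that("slide io resolves um/pixel from override, TIFF tags, or sidecar", {
  px <- array(as.integer((0:(24 * 32 * 3 - 1)) %% 256), dim = c(24, 32, 3))
  s <- wsi(px, 0.452)
  ## PNG + explicit override
  p <- tempfile(fileext = ".png")
  png::writePNG(px / 255, p)
  expect_equal(read_slide(p, um_per_pixel = 0.452)$um_per_pixel, 0.452)
  expect_error(read_slide(p), "um/pixel")
  ## TIFF resolution tags pass through
  pt <- tempfile(fileext = ".tif")
  write_slide(s, pt)
  st <- read_slide(pt)
  expect_equal(st$um_per_pixel, 0.452, tolerance = 1e-6)
  expect_identical(st$pixels, px)
  ## PNG written by the package carries a sidecar
  pp <- tempfile(fileext = ".png")
  write_slide(s, pp)
  expect_equal(read_slide(pp)$um_per_pixel, 0.452)
  ## non-image input
  bad <- tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(read_slide(bad), "decode")
})
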