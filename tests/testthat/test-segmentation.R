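test_that("background estimation returns the high percentile, clamped", {
  expect_equal(estimate_background(flat_slide(c(245, 245, 245))),
               c(245, 245, 245))
  expect_equal(estimate_background(flat_slide(c(0, 0, 0))), c(1, 1, 1))
  ## synthetic slide: glass dominates the brightest percentile. The 99th
  ## percentile sits a few sensor-noise SDs above nominal glass by design.
  sl <- fixture_slide("septal10")
  I0 <- estimate_background(sl$image)
  expect_true(all(I0 >= 244 & I0 <= 252))
})

test_that("optical density follows Beer-Lambert with the eps guard", {
  expect_equal(to_optical_density(c(240, 240, 240), c(240, 240, 240)),
               c(0, 0, 0))
  expect_equal(to_optical_density(c(24, 24, 24), c(240, 240, 240)),
               c(1, 1, 1))
  expect_equal(to_optical_density(c(0, 0, 0), c(240, 240, 240), eps = 0.5),
               rep(2.68124123737559, 3), tolerance = 1e-12)
  ## matrix and array forms agree with the vector form
  m <- rbind(c(10, 200, 240), c(240, 5, 100))
  I0 <- c(240, 245, 250)
  odm <- to_optical_density(m, I0)
  expect_equal(odm[1, ], to_optical_density(m[1, ], I0))
  arr <- array(0, dim = c(1, 2, 3)); arr[1, , ] <- m
  oda <- to_optical_density(arr, I0)
  expect_equal(oda[1, 2, ], to_optical_density(m[2, ], I0))
})

test_that("tissue delineation recovers the silhouette and fills only small holes", {
  expect_message(
    m <- delineate_tissue(flat_slide(c(245, 245, 245)),
                          c(245, 245, 245)), "no tissue")
  expect_false(any(m))
  sl <- fixture_slide("septal10")
  cfg <- segmentation_config()
  I0 <- estimate_background(sl$image, cfg)
  tis <- delineate_tissue(sl$image, I0, cfg)
  dice <- 2 * sum(tis & sl$tissue_truth) / (sum(tis) + sum(sl$tissue_truth))
  expect_gte(dice, 0.95)
  ## no remaining hole smaller than hole_fill_um2 (brute-force enumeration)
  filled <- t(as.matrix(EBImage::fillHull(EBImage::Image(t(tis))))) > 0.5
  holes <- filled & !tis
  if (any(holes)) {
    lab <- EBImage::bwlabel(EBImage::Image(t(holes)))
    sizes <- tabulate(as.integer(lab))
    min_px <- cfg$hole_fill_um2 / sl$image$um_per_pixel^2
    expect_true(all(sizes > min_px))
  } else succeed()
})

test_that("gram-accumulated stain basis matches direct SVD and is orthonormal", {
  set.seed(5)
  for (i in 1:5) {
    od <- matrix(abs(rnorm(500 * 3, 0.3, 0.2)), ncol = 3)
    ## embed the OD rows in a fake slide: intensities I = I0 * 10^-od
    I0 <- c(245, 245, 245)
    px <- round(I0[1] * 10^(-od))
    img <- array(0L, dim = c(50, 10, 3))
    for (ch in 1:3) img[, , ch] <- as.integer(matrix(px[, ch], 50, 10))
    sl <- wsi(img, 0.452)
    mask <- matrix(TRUE, 50, 10)
    b <- fit_stain_axes(sl, mask, I0, segmentation_config(), min_pixels = 300)
    ## oracle: direct SVD of the quantised OD matrix
    odq <- to_optical_density(cbind(as.vector(img[, , 1]),
                                    as.vector(img[, , 2]),
                                    as.vector(img[, , 3])), I0)
    sv <- svd(odq)
    expect_equal(b$s, sv$d, tolerance = 1e-8)
    for (j in 1:3)
      expect_lt(min(sum((b$V[, j] - sv$v[, j])^2),
                    sum((b$V[, j] + sv$v[, j])^2)), 1e-16)
    expect_equal(crossprod(b$V), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("rank-2 OD clouds put v3 in the null space, and tiny masks refuse", {
  ## rows drawn from span{(1,0,0),(0,1,0)} -> v3 = +/- (0,0,1), s3 = 0
  n <- 2000
  mix <- cbind(runif(n, 0.1, 1), runif(n, 0.1, 1), 0)
  px <- round(245 * 10^(-mix))
  img <- array(0L, dim = c(40, 50, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(matrix(px[, ch], 40, 50))
  sl <- wsi(img, 0.452)
  b <- fit_stain_axes(sl, matrix(TRUE, 40, 50), c(245, 245, 245),
                      segmentation_config())
  expect_equal(abs(b$V[, 3]), c(0, 0, 1), tolerance = 1e-6)
  expect_lt(b$s[3] / b$s[1], 1e-6)
  expect_error(fit_stain_axes(sl, matrix(FALSE, 40, 50), c(245, 245, 245),
                              segmentation_config()),
               "too few tissue pixels")
})

test_that("third-axis projection is the signed scalar product", {
  sl <- fixture_slide("septal10")
  cfg <- segmentation_config()
  I0 <- estimate_background(sl$image, cfg)
  tis <- delineate_tissue(sl$image, I0, cfg)
  b <- fit_stain_axes(sl$image, tis, I0, cfg)
  v3 <- b$V[, 3]
  expect_equal(project_third_axis(0.5 * v3, b), 0.5)
  expect_equal(project_third_axis(b$V[, 1] + 2 * b$V[, 2], b), 0,
               tolerance = 1e-12)
  ## collagen projects above the rest of the tissue
  od <- to_optical_density(sl$image$pixels, I0, cfg$eps_intensity)
  proj <- project_third_axis(od, b)
  expect_gt(mean(proj[sl$collagen_truth]),
            mean(proj[tis & !sl$collagen_truth]))
})

test_that("collagen thresholding is nested and behaves at the extremes", {
  sl <- fixture_slide("septal10")
  cfg <- segmentation_config()
  I0 <- estimate_background(sl$image, cfg)
  tis <- delineate_tissue(sl$image, I0, cfg)
  b <- fit_stain_axes(sl$image, tis, I0, cfg)
  od <- to_optical_density(sl$image$pixels, I0, cfg$eps_intensity)
  proj <- project_third_axis(od, b)
  expect_false(any(threshold_collagen(proj, tis, max(proj) + 1)))
  expect_identical(threshold_collagen(proj, tis, -1e9), tis)
  m <- threshold_collagen(proj, tis, cfg$collagen_threshold)
  expect_true(all(tis[m]))
  iou <- sum(m & sl$collagen_truth) / sum(m | sl$collagen_truth)
  expect_gte(iou, 0.80)
})

test_that("segment_slide handles blank slides and reports consistent counts", {
  blank <- flat_slide(c(245, 245, 245), h = 128, w = 128)
  expect_message(res <- segment_slide(blank), "no tissue")
  expect_equal(res$tissue_px, 0L)
  expect_equal(res$collagen_px, 0L)
  sl <- fixture_slide("peri5")
  res <- segment_slide(sl$image)
  expect_equal(res$tissue_px, sum(res$tissue_mask))
  expect_equal(res$collagen_px, sum(res$collagen_mask))
  expect_true(all(res$tissue_mask[res$collagen_mask]))
})
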