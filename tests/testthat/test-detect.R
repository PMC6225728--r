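test_that("blank and malformed inputs are handled", {
  expect_identical(nrow(detect_spots_2d(matrix(0, 32, 32))), 0L)
  expect_error(detect_spots_2d(array(0, c(4, 4, 4))), "2D")
})

test_that("single noiseless spot localized to < 0.1 px; gaussian refine recovers sigma", {
  img <- spot_image(64, 64, cbind(30.4, 17.7), sigma = 1.3)
  s <- detect_spots_2d(img, sigma_px = 1.3, pixel_size = 1)
  expect_identical(nrow(s), 1L)
  expect_lt(abs(s$x_nm - 30.4), 0.1)
  expect_lt(abs(s$y_nm - 17.7), 0.1)
  g <- detect_spots_2d(img, sigma_px = 1.3, pixel_size = 1,
                       refine = "gaussian")
  expect_lt(abs(g$x_nm - 30.4), 0.01)
  expect_lt(abs(g$sigma_nm - 1.3), 0.01)
})

test_that("50 planted spots at default noise: recall and precision >= 0.98", {
  set.seed(6)
  ## 50 spots on a jittered grid, min separation 6 px
  gx <- rep(seq(8, 120, by = 14), each = 9)[1:50]
  gy <- rep(seq(8, 120, by = 14), times = 9)[1:50]
  xy <- cbind(gx, gy) + matrix(runif(100, -2, 2), 50, 2)
  img <- spot_image(128, 128, xy, amp = 100, sigma = 1.3, background = 10)
  noisy <- matrix(rpois(length(img), img), 128, 128) +
    matrix(rnorm(length(img), sd = 2), 128, 128)
  s <- detect_spots_2d(noisy, sigma_px = 1.3, pixel_size = 1)
  d <- sqrt(outer(s$x_nm, xy[, 1], `-`)^2 + outer(s$y_nm, xy[, 2], `-`)^2)
  matched_truth <- apply(d, 2, min) < 2       # 2 px tolerance
  matched_det <- apply(d, 1, min) < 2
  expect_gte(mean(matched_truth), 0.98)       # recall
  expect_gte(mean(matched_det), 0.98)         # precision
})

test_that("detection is translation-equivariant for integer shifts", {
  img <- spot_image(64, 64, cbind(c(20.3, 40.6), c(30.2, 15.8)), sigma = 1.3)
  s0 <- detect_spots_2d(img, sigma_px = 1.3, pixel_size = 1)
  sh <- matrix(0, 64, 64)
  sh[4:64, 6:64] <- img[1:61, 1:59]           # shift down 3, right 5
  s1 <- detect_spots_2d(sh, sigma_px = 1.3, pixel_size = 1)
  expect_identical(nrow(s1), nrow(s0))
  expect_equal(sort(s1$x_nm), sort(s0$x_nm) + 5, tolerance = 1e-6)
  expect_equal(sort(s1$y_nm), sort(s0$y_nm) + 3, tolerance = 1e-6)
})

test_that("lowering the threshold never decreases the detection count", {
  set.seed(7)
  img <- spot_image(64, 64, cbind(c(20, 44), c(30, 16)), amp = 50,
                    sigma = 1.3, background = 5)
  img <- img + matrix(rnorm(64 * 64, sd = 1), 64, 64)
  thresholds <- c(50, 20, 10, 5, 2, 1, 0.5)
  counts <- vapply(thresholds, function(th)
    nrow(detect_spots_2d(img, sigma_px = 1.3, threshold = th,
                         pixel_size = 1)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("3D foci detection honors anisotropic spacing and planted truth", {
  expect_error(detect_foci_3d(array(1, c(8, 8, 4))), "isotropy")
  empty <- detect_foci_3d(array(0, c(8, 8, 4)), pixel_size = 66.3,
                          z_step = 0.5)
  expect_identical(nrow(empty[[1]]$positions), 0L)

  ## 40 planted blobs on a grid, >= 5 voxels apart
  set.seed(8)
  d <- c(48, 48, 20)
  stack <- array(0, d)
  centers <- cbind(rep(seq(6, 42, by = 6), each = 8)[1:40] - 1,
                   rep(seq(6, 42, by = 6), times = 8)[1:40] - 1,
                   rep(c(4, 9, 14), length.out = 40))
  for (k in 1:40) {
    rr <- (centers[k, 1] - 2):(centers[k, 1] + 2) + 1
    cc <- (centers[k, 2] - 2):(centers[k, 2] + 2) + 1
    zz <- (centers[k, 3] - 1):(centers[k, 3] + 1) + 1
    for (r in rr) for (ci in cc) for (z in zz)
      stack[r, ci, z] <- stack[r, ci, z] +
        100 * exp(-((r - 1 - centers[k, 1])^2 + (ci - 1 - centers[k, 2])^2) / 3 -
                    (z - 1 - centers[k, 3])^2 / 1)
  }
  foci <- detect_foci_3d(stack, pixel_size = 66.3, z_step = 0.5,
                         threshold = 10)
  expect_identical(nrow(foci[[1]]$positions), 40L)
  ## positions recovered within (100, 100, 250) nm per axis
  truth_nm <- cbind(centers[, 2] * 66.3, centers[, 1] * 66.3,
                    centers[, 3] * 500)
  p <- foci[[1]]$positions
  for (k in 1:40) {
    dd <- abs(sweep(p, 2, truth_nm[k, ]))
    j <- which.min(rowSums(dd^2))
    expect_lt(dd[j, 1], 100); expect_lt(dd[j, 2], 100); expect_lt(dd[j, 3], 250)
  }
})

test_that("spot diameter: FWHM closed form, override, and median robustness", {
  ## 5 isolated spots with sigma = 1.3 px (86.2 nm at 66.3 nm/px)
  xy <- cbind(c(15, 40, 65, 90, 115), c(20, 45, 20, 45, 20))
  img <- spot_image(64, 128, xy, sigma = 1.3)
  s <- detect_spots_2d(img, sigma_px = 1.3, pixel_size = 66.3,
                       refine = "gaussian")
  dia <- estimate_spot_diameter(s)
  expect_lt(abs(dia - 2 * sqrt(2 * log(2)) * 1.3 * 66.3) /
              (2 * sqrt(2 * log(2)) * 1.3 * 66.3), 0.05)
  expect_identical(estimate_spot_diameter(s, diameter = 250), 250)
  ## minority population at 2*sigma does not move the median
  img2 <- spot_image(64, 128, xy[1:2, ], sigma = 2.6) +
    spot_image(64, 128, xy[3:5, ], sigma = 1.3)
  s2 <- detect_spots_2d(img2, sigma_px = 1.3, pixel_size = 66.3,
                        refine = "gaussian")
  dia2 <- estimate_spot_diameter(s2)
  expect_lt(abs(dia2 / (2 * sqrt(2 * log(2)) * 1.3 * 66.3) - 1), 0.1)
  expect_error(estimate_spot_diameter(s[1:2, ]), "diameter")
})
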