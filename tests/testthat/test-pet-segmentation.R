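test_that("SUV statistics match brute-force scans on noisy fields", {
  set.seed(3)
  vol <- image_volume(array(runif(16^3, 1, 12), c(16, 16, 16)), c(2, 2, 2),
                      "PET", "SUV")
  roi <- array(FALSE, c(16, 16, 16)); roi[4:12, 4:12, 4:12] <- TRUE
  sm <- suv_max(vol, roi_mask(roi, "search"))
  expect_equal(sm$value, max(vol$values[roi]))
  expect_true(roi[sm$index[1], sm$index[2], sm$index[3]])
  expect_equal(vol$values[sm$index[1], sm$index[2], sm$index[3]], sm$value)

  vals <- vol$values[roi]
  expect_equal(mean_suv_isocontour(vol, roi, 0.7),
               mean(vals[vals >= 0.7 * max(vals)]))

  bg <- array(FALSE, c(16, 16, 16)); bg[14:16, 14:16, 14:16] <- TRUE
  expect_equal(background_mean(vol, bg), mean(vol$values[bg]))
  expect_error(background_mean(vol, roi, roi), "overlaps")
})

test_that("isocontour mean handles constant and two-voxel fields", {
  u <- image_volume(array(10, c(4, 4, 4)), c(1, 1, 1), "PET", "SUV")
  roi <- array(TRUE, c(4, 4, 4))
  expect_equal(mean_suv_isocontour(u, roi), 10)
  expect_equal(suv_max(u, roi)$value, 10)

  two <- array(0, c(2, 1, 1)); two[1, 1, 1] <- 10; two[2, 1, 1] <- 6
  v2 <- image_volume(two, c(1, 1, 1), "PET", "SUV")
  expect_equal(mean_suv_isocontour(v2, array(TRUE, c(2, 1, 1)), 0.7), 10)
})

test_that("adaptive threshold is the stated linear combination", {
  expect_equal(homburg_threshold(10, 0, homburg_coefficients(0.5, 0)), 5)
  expect_equal(homburg_threshold(10, 2, homburg_coefficients(0, 1)), 2)
  expect_equal(homburg_threshold(10, 2, homburg_coefficients(0.5, 0.5)), 6)
  expect_error(homburg_threshold(2, 2), "not distinguishable")
  expect_error(homburg_coefficients(-1, 1), "a >= 0")
})

test_that("threshold is monotone and segmentation volume non-increasing in it", {
  sph <- sphere_volume(8, dim = 24, spacing = 1, value = 10, bg = 1)
  roi <- array(FALSE, c(24, 24, 24)); roi[4:21, 4:21, 4:21] <- TRUE
  bg <- array(FALSE, c(24, 24, 24)); bg[1:2, 1:2, 1:2] <- TRUE
  vols <- sapply(c(0.3, 0.5, 0.7, 0.9), function(a) {
    seg <- segment_gtv_pet(sph$vol, roi_mask(roi, "s"), roi_mask(bg, "background"),
                           homburg_coefficients(a, 1 - a))
    c(thr = seg$threshold, vol = seg$volume_cm3)
  })
  expect_true(all(diff(vols["thr", ]) > 0))        # T monotone in a*mSUV70
  expect_true(all(diff(vols["vol", ]) <= 0))
})

test_that("noise-free uniform spheres are segmented exactly", {
  sph <- sphere_volume(8, dim = 24, spacing = 1, value = 10, bg = 1)
  roi <- array(FALSE, c(24, 24, 24)); roi[3:22, 3:22, 3:22] <- TRUE
  bg <- array(FALSE, c(24, 24, 24)); bg[1:2, 1:2, 1:2] <- TRUE
  seg <- segment_gtv_pet(sph$vol, roi_mask(roi, "s"),
                         roi_mask(bg, "background"))
  expect_identical(seg$mask$mask, sph$mask)        # bg < T = 5.5 < 10
  expect_equal(seg$volume_cm3, 4 / 3 * pi * 8^3 / 1000, tolerance = 0.05)
  expect_equal(seg$suvmax, 10)
  expect_equal(seg$threshold, 0.5 * 10 + 0.5 * 1)
})

test_that("only the component containing the hottest voxel is returned", {
  vals <- array(0.5, c(24, 24, 24))
  g <- (seq_len(24) - 0.5)
  d2a <- outer(outer((g - 7)^2, (g - 12)^2, "+"), (g - 12)^2, "+")
  d2b <- outer(outer((g - 18)^2, (g - 12)^2, "+"), (g - 12)^2, "+")
  vals[d2a <= 16] <- 12                            # hotter sphere
  vals[d2b <= 16] <- 8                             # cooler, disjoint
  vol <- image_volume(vals, c(1, 1, 1), "PET", "SUV")
  roi <- array(TRUE, c(24, 24, 24)); roi[, , 1:2] <- FALSE
  bg <- array(FALSE, c(24, 24, 24)); bg[, , 1] <- TRUE
  seg <- segment_gtv_pet(vol, roi_mask(roi, "s"), roi_mask(bg, "background"))
  expect_identical(seg$mask$mask, d2a <= 16 & roi)
  expect_false(any(seg$mask$mask & (d2b <= 16)))
})

test_that("coefficient calibration solves the phantom system", {
  exact <- data.frame(msuv70 = c(10, 20), bg = c(2, 1),
                      threshold = c(0.4 * 10 + 0.6 * 2, 0.4 * 20 + 0.6 * 1))
  cf <- calibrate_coefficients(exact)
  expect_equal(cf$a, 0.4, tolerance = 1e-12)
  expect_equal(cf$b, 0.6, tolerance = 1e-12)

  set.seed(5)
  ms <- runif(30, 5, 25); bgv <- runif(30, 0.5, 3)
  thr <- 0.45 * ms + 0.55 * bgv + rnorm(30, 0, 0.05)
  noisy <- data.frame(msuv70 = ms, bg = bgv, threshold = thr)
  cf2 <- calibrate_coefficients(noisy)
  # independent normal-equations oracle
  ab <- coef(lm(threshold ~ 0 + msuv70 + bg, data = noisy))
  expect_equal(c(cf2$a, cf2$b), unname(ab), tolerance = 1e-10)

  expect_error(calibrate_coefficients(
    data.frame(msuv70 = c(10, 10), bg = c(2, 2), threshold = c(6, 6))),
    "rank-deficient")
})
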