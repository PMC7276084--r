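test_that("noiseless Gaussian fits recover FWHM and center within 2%", {
  img <- spot_image(41, "gaussian", x0 = 21.3, y0 = 20.6,
                    fwhm_px_x = 6, pixel_nm = 20)
  f <- fit_gaussian2d(img, c(21, 21), fit_params(roi_half_width = 10))
  expect_identical(f$status, "accepted")
  expect_lt(abs(f$fwhm_mean - 120) / 120, 0.02)
  expect_lt(abs(f$x0_px - 21.3), 0.05)
  expect_lt(f$frac_uncertainty, 0.01)
})

test_that("anisotropic Gaussian spot: fwhm_mean is the X/Y average", {
  # FWHM_x 180 nm, FWHM_y 240 nm at 20 nm/px -> mean 210 nm
  img <- spot_image(41, "gaussian", x0 = 21, y0 = 21,
                    fwhm_px_x = 9, fwhm_px_y = 12, pixel_nm = 20)
  f <- fit_gaussian2d(img, c(21, 21), fit_params(roi_half_width = 14))
  expect_identical(f$status, "accepted")
  expect_lt(abs(f$fwhm_x - 180) / 180, 0.02)
  expect_lt(abs(f$fwhm_y - 240) / 240, 0.02)
  expect_lt(abs(f$fwhm_mean - 210) / 210, 0.02)
  expect_equal(f$fwhm_mean, (f$fwhm_x + f$fwhm_y) / 2)
})

test_that("noiseless Lorentzian fit recovers a 70-nm punctum within 2%", {
  img <- spot_image(41, "lorentzian", x0 = 21.2, y0 = 20.8,
                    fwhm_px_x = 7, pixel_nm = 10)
  f <- fit_lorentzian2d(img, c(21, 21), fit_params(roi_half_width = 7))
  expect_identical(f$status, "accepted")
  expect_lt(abs(f$fwhm_mean - 70) / 70, 0.02)
})

test_that("a flat image is rejected rather than fit", {
  img <- microscopy_image(matrix(10, 41, 41), 10, "STED")
  f <- fit_lorentzian2d(img, c(21, 21), fit_params())
  expect_identical(f$status, "rejected")
})

test_that("rejection rules fire on constructed negative fixtures", {
  # center outside the ROI: spot planted 12 px away from the seed
  img <- spot_image(61, "lorentzian", x0 = 43, y0 = 31, fwhm_px_x = 5)
  f <- fit_lorentzian2d(img, c(31, 31), fit_params(roi_half_width = 7))
  expect_identical(f$status, "rejected")

  # high noise -> fractional width uncertainty beyond 60%
  set.seed(801)
  base <- spot_image(31, "lorentzian", x0 = 16, y0 = 16, fwhm_px_x = 4,
                     amp = 10, offset = 0)$values
  noisy <- microscopy_image(matrix(rpois(31 * 31, base + 50), 31, 31), 10, "STED")
  f2 <- fit_lorentzian2d(noisy, c(16, 16), fit_params(roi_half_width = 7))
  expect_identical(f2$status, "rejected")
  expect_true(f2$reject_reason %in% c("uncertainty_exceeded", "fit_failed"))

  # inverted contrast drives the amplitude negative
  dip <- spot_image(31, "gaussian", x0 = 16, y0 = 16, fwhm_px_x = 5,
                    amp = -60, offset = 100)
  f3 <- fit_lorentzian2d(dip, c(16, 16), fit_params(roi_half_width = 7))
  expect_identical(f3$status, "rejected")
})

test_that("fits are translation-equivariant and intensity-scale invariant", {
  mk <- function(x0, y0, scale = 1) {
    img <- spot_image(51, "lorentzian", x0 = x0, y0 = y0, fwhm_px_x = 6,
                      amp = 100 * scale, offset = 10 * scale)
    fit_lorentzian2d(img, c(round(x0), round(y0)), fit_params(roi_half_width = 9))
  }
  f1 <- mk(25.4, 26.1)
  f2 <- mk(30.4, 31.1)           # shifted by 5 whole px
  expect_equal(f2$x0_px - f1$x0_px, 5, tolerance = 1e-6)
  expect_equal(f2$fwhm_mean, f1$fwhm_mean, tolerance = 1e-6)
  f3 <- mk(25.4, 26.1, scale = 13)
  expect_equal(f3$fwhm_mean, f1$fwhm_mean, tolerance = 1e-6)
  expect_equal(f3$amplitude / f1$amplitude, 13, tolerance = 1e-6)
})

test_that("segmentation proceeds brightest-first and finds planted spots", {
  img <- matrix(2, 101, 101)
  spots <- data.frame(x = c(25, 75, 50), y = c(25, 75, 50),
                      amp = c(300, 200, 100))
  for (k in 1:3) {
    s <- spot_image(101, "lorentzian", x0 = spots$x[k], y0 = spots$y[k],
                    fwhm_px_x = 4, amp = spots$amp[k], offset = 0)
    img <- img + s$values - 10
  }
  mi <- microscopy_image(pmax(img, 0), 15, "STED")
  fits <- segment_domains_sted(mi, fit_params(roi_half_width = 7))
  acc <- fits[fits$status == "accepted", ]
  expect_gte(nrow(acc), 3)
  # first three accepted fits in decreasing planted brightness
  expect_equal(round(acc$x0_px[1:3]), spots$x)
  expect_equal(round(acc$y0_px[1:3]), spots$y)
})

test_that("the 50%-of-last-20 rule terminates on a blank noise image", {
  set.seed(802)
  blank <- microscopy_image(matrix(rpois(200 * 200, 5), 200, 200), 15, "STED")
  fits <- segment_domains_sted(blank, fit_params(roi_half_width = 7))
  expect_equal(sum(fits$status == "accepted"), 0)
  expect_lte(nrow(fits), 40)   # termination rule, not exhaustion
})

test_that("size distribution excludes rejected fits and summarizes accepted", {
  fits <- rbind(
    data.frame(model = "lorentzian2d", seed_x = 1, seed_y = 1, x0_px = 1,
               y0_px = 1, x0_nm = 1, y0_nm = 1, fwhm_x = 70, fwhm_y = 70,
               fwhm_mean = 70, amplitude = 1, offset = 0,
               frac_uncertainty = 0.1, status = "accepted",
               reject_reason = "none"),
    data.frame(model = "lorentzian2d", seed_x = 2, seed_y = 2, x0_px = 2,
               y0_px = 2, x0_nm = 2, y0_nm = 2, fwhm_x = 500, fwhm_y = 500,
               fwhm_mean = 500, amplitude = 1, offset = 0,
               frac_uncertainty = 0.9, status = "rejected",
               reject_reason = "uncertainty_exceeded"))
  s <- size_distribution(fits)
  expect_equal(s$n, 1)
  expect_equal(s$mean, 70)
  expect_equal(s$median, 70)
  expect_equal(s$sd, 0)
  expect_error(size_distribution(fits[fits$status == "rejected", ]), "accepted")
})

test_that("STED sizes fall below confocal sizes on matched synthetic pairs", {
  ctrs <- layout_domain_centers(9, img_px = 300, pixel_nm = 12,
                                margin_nm = 1000, seed = 21)
  pair <- simulate_image_pair(ctrs, fwhm_true = 57, pixel_nm = 12,
                              img_px = 300, photon_scale = 2000, seed = 21)
  sted <- segment_domains_sted(pair$sted, fit_params(roi_half_width = 7))
  conf <- do.call(rbind, lapply(1:9, function(i) {
    fit_gaussian2d(pair$confocal,
                   round(unlist(pair$ground_truth[i, c("x_px", "y_px")])),
                   fit_params(roi_half_width = 21))
  }))
  ssum <- size_distribution(sted)
  csum <- size_distribution(conf)
  expect_lt(ssum$mean, csum$mean)
  expect_lt(abs(ssum$mean - pair$ground_truth$fwhm_apparent_sted[1]) /
              pair$ground_truth$fwhm_apparent_sted[1], 0.10)
  expect_lt(abs(csum$mean - pair$ground_truth$fwhm_apparent_confocal[1]) /
              pair$ground_truth$fwhm_apparent_confocal[1], 0.10)
})

test_that("image pairs are seed-deterministic and noiseless peaks sit on centers", {
  ctrs <- matrix(c(1800, 1800), ncol = 2)
  p1 <- simulate_image_pair(ctrs, 57, img_px = 300, pixel_nm = 12, seed = 4)
  p2 <- simulate_image_pair(ctrs, 57, img_px = 300, pixel_nm = 12, seed = 4)
  expect_identical(p1$sted$values, p2$sted$values)
  expect_identical(p1$confocal$values, p2$confocal$values)

  pn <- simulate_image_pair(ctrs, 57, img_px = 300, pixel_nm = 12,
                            photon_scale = Inf)
  peak <- arrayInd(which.max(pn$sted$values), dim(pn$sted$values))
  expect_lte(max(abs(peak - pn$ground_truth$x_px[1])), 1)
  expect_error(simulate_image_pair(matrix(c(50, 50), ncol = 2), 57,
                                   img_px = 300, pixel_nm = 12),
               "placement")
})
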