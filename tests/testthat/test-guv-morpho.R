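ring_scene <- function(vesicles, image = c(400L, 400L), pixel = 0.1, seed = 1L) {
  make_guv_scene(guv_scene_config(image_size_px = image, pixel_size_um = pixel,
                                  vesicles = vesicles, seed = seed))
}

test_that("Hough detection finds a single ring within 2 px", {
  sc <- ring_scene(list(guv_vesicle(c(200, 180), radius_um = 5)))
  det <- detect_guvs(sc$membrane, 0.1, c(3, 8), radius_step_um = 0.1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$centre_row_px - 200), 2)
  expect_lt(abs(det$centre_col_px - 180), 2)
  expect_lt(abs(det$radius_um - 5) / 0.1, 2)   # within 2 px
})

test_that("a blank image yields no detections", {
  blank <- matrix(0.1, 200, 200)
  det <- detect_guvs(blank, 0.1, c(3, 8))
  expect_equal(nrow(det), 0L)
})

test_that("two non-overlapping rings are detected 1:1", {
  sc <- ring_scene(list(guv_vesicle(c(110, 110), radius_um = 5),
                        guv_vesicle(c(290, 290), radius_um = 7)))
  det <- detect_guvs(sc$membrane, 0.1, c(3, 9), radius_step_um = 0.1)
  expect_equal(nrow(det), 2L)
  truth <- rbind(c(110, 110, 5), c(290, 290, 7))
  for (k in 1:2) {
    d <- sqrt((det$centre_row_px - truth[k, 1])^2 +
              (det$centre_col_px - truth[k, 2])^2)
    m <- which.min(d)
    expect_lt(d[m], 2)
    expect_lt(abs(det$radius_um[m] - truth[k, 3]) / 0.1, 2)
  }
})

test_that("segmentation centroid is within 1 px; ellipse area within 3%", {
  sc <- ring_scene(list(guv_vesicle(c(210, 190), radius_um = 9)))
  seg <- segment_guv_particles(sc$membrane)
  expect_equal(nrow(seg$rois), 1L)
  expect_lt(abs(seg$rois$centroid_row_px - 210), 1)
  expect_lt(abs(seg$rois$centroid_col_px - 190), 1)
  ## deformed vesicle: filled particle of the membrane footprint, compared
  ## to the analytic outer-membrane ellipse
  sc2 <- ring_scene(list(guv_vesicle(c(200, 200), radius_um = 7,
                                     axis_ratio = 1.5,
                                     membrane_thickness_px = 3)))
  seg2 <- segment_guv_particles(sc2$membrane)
  a <- 1.5 * 70 + 1.5; b <- 70 + 1.5
  expect_lt(abs(seg2$rois$area_px / (pi * a * b) - 1), 0.03)
  ## blank image: no ROIs
  seg0 <- segment_guv_particles(matrix(0.1, 150, 150))
  expect_equal(nrow(seg0$rois), 0L)
})

test_that("area fraction: empty, full, and a painted known fraction", {
  roi <- disc_mask(80L)
  blank <- matrix(0, nrow(roi), ncol(roi))
  expect_error(nanotube_area_fraction(blank, roi & FALSE), "empty ROI")
  af0 <- nanotube_area_fraction(blank, roi)
  expect_equal(af0$fraction_pct, 0)
  expect_false(af0$keep)
  full <- matrix(0, nrow(roi), ncol(roi)); full[roi] <- 1
  af1 <- nanotube_area_fraction(full, roi, sigma = 0, erode = FALSE)
  expect_equal(af1$fraction_pct, 100)
  expect_true(af1$keep)
  ## 7% of ROI pixels painted, noiseless
  rna <- matrix(0, nrow(roi), ncol(roi))
  idx <- which(roi)
  sel <- idx[seq(1L, length(idx), length.out = round(0.07 * length(idx)))]
  rna[sel] <- 1
  af <- nanotube_area_fraction(rna, roi, sigma = 0, erode = FALSE)
  expect_lt(abs(af$fraction_pct - 7), 1)
  expect_true(af$keep)
})

test_that("area fraction is translation-invariant and monotone", {
  roi <- matrix(FALSE, 120, 120); roi[31:90, 31:90] <- TRUE
  rna <- matrix(0, 120, 120); rna[41:60, 41:60] <- 1
  f1 <- nanotube_area_fraction(rna, roi, sigma = 0, erode = FALSE)$fraction_pct
  roi2 <- matrix(FALSE, 120, 120); roi2[21:80, 21:80] <- TRUE
  rna2 <- matrix(0, 120, 120); rna2[31:50, 31:50] <- 1
  f2 <- nanotube_area_fraction(rna2, roi2, sigma = 0, erode = FALSE)$fraction_pct
  expect_equal(f1, f2)
  rna3 <- rna; rna3[70:80, 70:80] <- 1
  f3 <- nanotube_area_fraction(rna3, roi, sigma = 0, erode = FALSE)$fraction_pct
  expect_gt(f3, f1)
})

test_that("radial centre of mass: uniform, delta, scale-invariance, bounds", {
  x <- (1:100 - 0.5) / 100
  expect_equal(radial_com(data.frame(x = x, y = rep(1, 100))), 0.5)
  ## uniform over bin centres 0.01..1.00 at spacing 0.01 (grid mean 0.505)
  x2 <- seq(0.01, 1, by = 0.01)
  expect_equal(radial_com(data.frame(x = x2, y = rep(3, 100))), 0.505)
  y3 <- rep(0, 100); y3[95] <- 2
  expect_equal(radial_com(data.frame(x = x2, y = y3)), 0.95)
  set.seed(5)
  y4 <- runif(100)
  xc <- radial_com(data.frame(x = x2, y = y4))
  expect_equal(radial_com(data.frame(x = x2, y = 7 * y4)), xc)
  expect_gte(xc, min(x2)); expect_lte(xc, max(x2))
  expect_error(radial_com(data.frame(x = x2, y = rep(0, 100))), "all-zero")
})

test_that("circularity: analytic circle, square, and raster behaviour", {
  theta <- seq(0, 2 * pi, length.out = 3000L)[-1L]
  expect_equal(as.numeric(circularity(cbind(cos(theta), sin(theta)))), 1,
               tolerance = 1e-5)
  sq <- cbind(c(0, 7, 7, 0), c(0, 0, 7, 7))
  expect_equal(as.numeric(circularity(sq)), pi / 4, tolerance = 1e-12)
  ## raster disc: close to 1 from below after the isoperimetric clamp
  ## (estimator accuracy is ~1% and improves with radius)
  d <- disc_mask(100L)
  expect_gte(as.numeric(circularity(d)), 0.99)
  expect_lte(as.numeric(circularity(d)), 1)
  ## estimator is echoed; freeman underestimates on smooth shapes
  r_free <- circularity(d, estimator = "freeman")
  expect_equal(attr(r_free, "estimator"), "freeman")
  expect_lt(as.numeric(r_free), as.numeric(circularity(d)))
  ## crofton option is close to truth on an isotropic shape
  expect_equal(as.numeric(circularity(d, estimator = "crofton")), 1,
               tolerance = 0.05)
  expect_error(circularity(matrix(FALSE, 5, 5)), "zero perimeter")
})

test_that("circularity is invariant under rigid motion and uniform scaling", {
  poly <- cbind(c(0, 4, 5, 2, -1), c(0, -1, 3, 5, 2))
  r0 <- as.numeric(circularity(poly))
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  expect_equal(as.numeric(circularity(poly %*% R + 13)), r0, tolerance = 1e-12)
  expect_equal(as.numeric(circularity(poly * 27.5)), r0, tolerance = 1e-12)
  expect_lt(r0, 1)
})

test_that("z-stack circularity averages the slices", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  theta <- seq(0, 2 * pi, length.out = 1000L)[-1L]
  circ <- cbind(cos(theta), sin(theta))
  expect_equal(stack_circularity(list(sq, circ)),
               mean(c(pi / 4, as.numeric(circularity(circ)))),
               tolerance = 1e-9)
})

test_that("angular intensity: constant field, stride, and clipping", {
  img <- matrix(5, 300, 300)
  theta <- seq(0, 2 * pi, length.out = 361L)[-361L]
  bnd <- cbind(150 + 80 * cos(theta), 150 + 80 * sin(theta))
  ai <- angular_intensity(img, bnd, c(150, 150), pixel_size_um = 0.1)
  expect_equal(nrow(ai), 36L)                 # every 10th of 360 points
  expect_true(all(abs(ai$mean_intensity - 5) < 1e-9))
  expect_equal(ai$distance_um, rep(8, 36L), tolerance = 1e-9)
  ## RNA painted along one axis maximizes the aligned rectangles
  img2 <- matrix(0, 300, 300)
  img2[146:154, 150:230] <- 1                 # bright arm towards +col
  ai2 <- angular_intensity(img2, bnd, c(150, 150), pixel_size_um = 0.1,
                           width_um = 1)
  best <- ai2$point_index[which.max(ai2$mean_intensity)]
  ## boundary point 91 is at angle pi/2 (towards +col)
  expect_lte(abs(best - 91), 10)
  ## oracle: the best rectangle's mean matches direct pixel averaging
  u <- c(0, 1); len <- 0.8 * 80; halfw <- 0.5 / 0.1
  rr <- row(img2) - 150; cc <- col(img2) - 150
  inside <- (cc >= 0) & (cc <= len) & (abs(rr) <= halfw)
  expect_equal(max(ai2$mean_intensity), mean(img2[inside]), tolerance = 0.05)
  ## clipping warning when rectangles leave the image
  bnd_big <- cbind(150 + 149 * cos(theta), 150 + 149 * sin(theta))
  expect_warning(
    angular_intensity(img, bnd_big, c(150, 150), pixel_size_um = 0.1,
                      width_um = 35), "clipped")
})

test_that("Welch's t-test matches the numeric t-density oracle", {
  a <- c(1, 2, 3, 4)
  b <- a + 10
  w <- welch_ttest(a, b)
  expect_lt(abs(w$p - oracle_welch_p(a, b)), 1e-10)
  set.seed(8)
  x <- rnorm(12, 0, 1); y <- rnorm(7, 1.2, 2.5)
  w2 <- welch_ttest(x, y)
  expect_lt(abs(w2$p - oracle_welch_p(x, y)), 1e-10)
})

test_that("Welch's t-test: identical groups, symmetry, Student reduction", {
  g <- c(1, 2, 3, 4)
  w <- welch_ttest(g, g)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  set.seed(9)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  expect_equal(welch_ttest(a, b)$p, welch_ttest(b, a)$p, tolerance = 1e-12)
  ## equal-variance equal-n case reproduces Student's t
  st <- t.test(a, b, var.equal = TRUE)
  wt <- welch_ttest(a, b)
  expect_equal(wt$t, unname(st$statistic), tolerance = 0.05)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("bond-occupancy group comparison reproduces the reported order of p", {
  ## summary statistics of the stem-loop occupancy comparison:
  ## 0.73 +/- 0.02 (straight-tube design) vs 0.45 +/- 0.03 (ring-forming
  ## mutant), n = 4 runs each -> p of order 1e-5
  wt <- group_with_moments(0.73, 0.02)
  mut <- group_with_moments(0.45, 0.03)
  w <- welch_ttest(wt, mut)
  expect_lt(w$p, 1e-4)
  expect_gt(w$p, 1e-7)
  ## and the 0.47 +/- 0.12 comparison is weaker, order 1e-2
  mut2 <- group_with_moments(0.47, 0.12)
  w2 <- welch_ttest(wt, mut2)
  expect_gt(w2$p, 1e-3)
  expect_lt(w2$p, 0.1)
})
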