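make_mask <- function(dims, px) {
  m <- matrix(FALSE, dims[1L], dims[2L])
  m[px + 1L] <- TRUE
  m
}

test_that("a 1-px line is its own skeleton", {
  m <- matrix(FALSE, 20, 20)
  m[10, 3:17] <- TRUE
  g <- skeletonize_mask(m)
  expect_identical(g$skeleton, m)
  expect_equal(g$n_components, 1L)
})

test_that("a 5-px-wide bar thins to a 1-px path near the midline", {
  m <- matrix(FALSE, 30, 80)
  m[13:17, 10:70] <- TRUE
  g <- skeletonize_mask(m)
  paths <- trace_longest_path(g)
  expect_length(paths, 1L)
  p <- paths[[1L]]
  ## every skeleton pixel within 2 px of the midline row (0-based row 14)
  expect_true(all(abs(g$pixels$row - 14) <= 2))
  ## the traced path spans most of the bar
  expect_gt(nrow(p), 50)
})

test_that("disjoint blobs give separate components", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:10] <- TRUE
  m[25:32, 25:30] <- TRUE
  g <- skeletonize_mask(m)
  expect_equal(g$n_components, 2L)
  expect_equal(skeletonize_mask(matrix(FALSE, 5, 5))$n_components, 0L)
})

test_that("T-junction: longest path takes the two longest arms", {
  m <- matrix(FALSE, 120, 120)
  m[60, 10:100] <- TRUE       # horizontal arms: 50 px left, 40 px right of junction
  m[29:59, 60] <- TRUE        # vertical arm: 31 px up
  g <- skeletonize_mask(m)
  paths <- trace_longest_path(g)
  p <- paths[[1L]]
  ## longest leaf pair is the full horizontal line (length 90 steps)
  expect_equal(attr(p, "length_px"), 90)
  expect_equal(attr(p, "length_px"), oracle_longest_leaf_path(g))
  ## endpoints are the horizontal extremes
  ends <- p[c(1L, nrow(p)), ]
  expect_setequal(ends[, 2L], c(9L, 99L))
})

test_that("longest path equals the brute-force oracle on random small skeletons", {
  set.seed(81)
  for (case in 1:12) {
    m <- matrix(FALSE, 14, 14)
    ## a few random strokes
    for (s in 1:3) {
      r0 <- sample(2:13, 1L); c0 <- sample(2:13, 1L)
      dr <- sample(-1:1, 1L); dc <- sample(-1:1, 1L)
      if (dr == 0L && dc == 0L) dc <- 1L
      len <- sample(3:9, 1L)
      rr <- pmin(14L, pmax(1L, r0 + dr * (0:len)))
      cc <- pmin(14L, pmax(1L, c0 + dc * (0:len)))
      m[cbind(rr, cc)] <- TRUE
    }
    g <- skeletonize_mask(m)
    if (nrow(g$pixels) > 60L) next
    paths <- trace_longest_path(g)
    for (k in seq_len(g$n_components)) {
      oracle <- oracle_longest_leaf_path(g, k)
      if (is.na(oracle)) next        # cycles / single pixels handled elsewhere
      expect_equal(attr(paths[[k]], "length_px"), oracle, tolerance = 1e-12)
    }
  }
})

test_that("a 1-px ring is traced to within one step of the full cycle", {
  m <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 720)
  px <- unique(cbind(round(20 + 12 * cos(th)), round(20 + 12 * sin(th))))
  m[px] <- TRUE
  g <- skeletonize_mask(m)
  paths <- trace_longest_path(g)
  p <- paths[[1L]]
  expect_true(attr(p, "is_cycle"))
  ## path covers every skeleton pixel (full cycle minus the closing step)
  expect_equal(nrow(p), nrow(g$pixels))
})

test_that("single-pixel components are flagged degenerate", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  p <- trace_longest_path(skeletonize_mask(m))[[1L]]
  expect_true(attr(p, "degenerate"))
  expect_equal(attr(p, "length_px"), 0)
})

test_that("measure_filament: axial and diagonal chain-code identities", {
  horiz <- cbind(0L, 0:100)
  tr <- measure_filament(horiz, 4)
  expect_equal(tr$contour_length_nm, 400)
  expect_equal(tr$end_to_end_nm, 400)
  diag <- cbind(0:100, 0:100)
  tr2 <- measure_filament(diag, 4)
  expect_equal(tr2$contour_length_nm, 100 * sqrt(2) * 4)
  ## kulpa rescales by 0.9481
  tr3 <- measure_filament(horiz, 4, estimator = "kulpa")
  expect_equal(tr3$contour_length_nm, 400 * 0.9481)
  expect_error(measure_filament(horiz[1, , drop = FALSE], 4), "2 pixels")
})

test_that("quarter-circle arc length is recovered within 5%", {
  r <- 200
  th <- seq(0, pi / 2, length.out = 4000)
  px <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
  m <- matrix(FALSE, r + 10, r + 10)
  m[px + 1L] <- TRUE
  df <- trace_mask(m, pixel_size_nm = 1, estimator = "kulpa")
  expect_equal(nrow(df), 1L)
  expect_lt(abs(df$contour_nm / (pi * r / 2) - 1), 0.05)
})

test_that("calibration linearity: doubling pixel size doubles lengths", {
  path <- digital_segment(120, 30)
  a <- measure_filament(path, 2)
  b <- measure_filament(path, 4)
  expect_equal(b$contour_length_nm, 2 * a$contour_length_nm)
  expect_equal(b$end_to_end_nm, 2 * a$end_to_end_nm)
})

test_that("digitized straight-segment length varies < 8% across orientations", {
  lens <- vapply(seq(0, 90, by = 5), function(ang) {
    path <- digital_segment(300, ang)
    chainlen <- measure_filament(path, 1)$contour_length_nm
    chainlen / 300
  }, 0)
  expect_lt((max(lens) - min(lens)) / mean(lens), 0.08)
})

test_that("traced paths of rendered filaments are simple and 8-connected", {
  for (seed in c(12, 55)) {
    ch <- sample_wlc_chain(wlc_params(800, contour_length_nm = 900), seed = seed)
    pts <- ch$points_nm
    pts[, 1L] <- pts[, 1L] - min(pts[, 1L]) + 30
    pts[, 2L] <- pts[, 2L] - min(pts[, 2L]) + 30
    ch$points_nm <- pts
    dims <- ceiling(c(max(pts[, 1L]), max(pts[, 2L])) / 4) + 10L
    cfg <- afm_scene_config(image_size_px = dims, pixel_size_nm = 4,
                            tip_radius_nm = 5)
    g <- skeletonize_mask(render_afm_scene(cfg, list(ch))$mask)
    for (p in trace_longest_path(g)) {
      expect_equal(anyDuplicated(p), 0L)
      d <- abs(diff(p))
      expect_true(all(d <= 1))
      expect_true(all(rowSums(d) >= 1))
    }
  }
})

test_that("cross-section profile recovers tube height and broadened width", {
  ch <- sample_wlc_chain(wlc_params(Inf, contour_length_nm = 600), seed = 1)
  ch$points_nm <- ch$points_nm + 60       # place inside the tile
  cfg <- afm_scene_config(image_size_px = c(200, 200), pixel_size_nm = 4,
                          tube_height_nm = 6, tip_radius_nm = 8)
  sc <- render_afm_scene(cfg, list(ch))
  df <- trace_mask(sc$mask, 4)
  tr <- attr(df, "traces")[[1L]]
  prof <- cross_section_profile(sc$height_nm, tr, 4)
  expect_equal(prof$height_nm, 6, tolerance = 0.01)
  expect_gt(prof$width_fwhm_nm, 2 * 8)    # tip dilation broadens the ridge
})

test_that("flat background yields no ridge and is flagged", {
  img <- matrix(0, 60, 60)
  path <- cbind(30L, 5:54)
  prof <- cross_section_profile(img, path, 4)
  expect_true(is.na(prof$height_nm))
  expect_equal(prof$n_flagged, prof$n_points)
})

test_that("ring metrics: disc, square and annulus", {
  d <- disc_mask(23L)                       # diameter 47 px (centre pixel + 2*23)
  rm <- ring_metrics(d, 1)
  expect_equal(rm$outer_radius_nm, 23.5, tolerance = 1 / 23.5)
  expect_equal(rm$inner_radius_nm, 0)
  sq <- matrix(FALSE, 60, 60); sq[11:50, 11:50] <- TRUE   # side 40
  rs <- ring_metrics(sq, 1)
  expect_equal(rs$outer_radius_nm, 40 * sqrt(2) / 2, tolerance = 1.2 / 28)
  ann <- disc_mask(20L) & !disc_mask(12L, margin = 13L)
  ra <- ring_metrics(ann, 2)                # 2 nm/px
  expect_equal(ra$outer_radius_nm, 2 * 20, tolerance = 2 / 40)
  expect_equal(ra$inner_radius_nm, 2 * 12, tolerance = 2.5 / 24)
  expect_error(ring_metrics(matrix(FALSE, 5, 5)), "empty")
})
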