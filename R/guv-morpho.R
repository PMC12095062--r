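## GUV morphometrics: circle-Hough vesicle detection, blur/threshold
## segmentation, nanotube area fraction, radial intensity profiles and
## their centre of mass, circularity, angular intensity sampling, and
## Welch's t-test.

#' Li's minimum cross-entropy threshold
#'
#' Iterates `t <- (mu_fg - mu_bg) / (log mu_fg - log mu_bg)` to its fixed
#' point (intensities shifted to be positive).
#'
#' @param x numeric matrix or vector of intensities.
#' @return threshold on the original intensity scale.
#' @export
li_threshold <- function(x) {
  v <- as.numeric(x)
  shift <- 0
  if (min(v) <= 0) {           # Li needs positive intensities
    shift <- min(v) - 1e-6 * max(1e-12, diff(range(v)))
    v <- v - shift
  }
  t0 <- mean(v)
  for (i in 1:200) {
    mu_b <- mean(v[v <= t0]); mu_f <- mean(v[v > t0])
    if (!is.finite(mu_b) || !is.finite(mu_f) || mu_b <= 0) break
    t1 <- (mu_f - mu_b) / (log(mu_f) - log(mu_b))
    if (!is.finite(t1) || abs(t1 - t0) < 1e-10) { t0 <- t1; break }
    t0 <- t1
  }
  t0 + shift
}

## ring kernel of radius r px (width w), normalized to sum 1
ring_kernel <- function(r, w = 1.5) {
  k <- 2L * ceiling(r + w) + 1L
  ctr <- ceiling(r + w) + 1L
  d <- sqrt(outer((seq_len(k) - ctr)^2, (seq_len(k) - ctr)^2, `+`))
  m <- (abs(d - r) <= w) * 1
  m / sum(m)
}

#' Detect GUVs with a circle Hough transform
#'
#' Edge pixels (membrane channel above its Otsu threshold) vote via
#' ring-kernel convolution, one accumulator per candidate radius; peaks are
#' extracted greedily with non-maximum suppression (no two detections
#' closer than the larger radius).
#'
#' @param membrane membrane channel matrix.
#' @param pixel_size_um um per pixel.
#' @param radius_range_um `(min, max)` radius to search, um.
#' @param radius_step_um radius grid step (default 0.5 um).
#' @param score_min minimum accumulator score (fraction of the ring
#'   covered by edge pixels) to accept a detection.
#' @param max_detections safety cap.
#' @return data.frame: `centre_row_px`, `centre_col_px` (1-based),
#'   `radius_um`, `score`; empty for a blank image.
#' @export
detect_guvs <- function(membrane, pixel_size_um, radius_range_um,
                        radius_step_um = 0.5, score_min = 0.4,
                        max_detections = 50L) {
  if (diff(range(membrane)) < 1e-9)
    return(data.frame(centre_row_px = integer(), centre_col_px = integer(),
                      radius_um = numeric(), score = numeric()))
  thr <- EBImage::otsu(EBImage::Image(membrane / max(membrane, 1e-12)),
                       range = c(0, 1))
  edges <- (membrane / max(membrane, 1e-12)) > thr
  if (!any(edges)) return(data.frame(centre_row_px = integer(),
                                     centre_col_px = integer(),
                                     radius_um = numeric(), score = numeric()))
  radii_px <- seq(radius_range_um[1L], radius_range_um[2L],
                  by = radius_step_um) / pixel_size_um
  acc <- lapply(radii_px, function(r)
    EBImage::filter2(edges * 1, ring_kernel(r), boundary = 0))
  acc <- simplify2array(acc)          # rows x cols x radii
  out <- list()
  for (k in seq_len(max_detections)) {
    m <- which.max(acc)
    sc <- acc[m]
    if (!is.finite(sc) || sc < score_min) break
    ai <- arrayInd(m, dim(acc))
    r_px <- radii_px[ai[3L]]
    out[[k]] <- data.frame(centre_row_px = ai[1L], centre_col_px = ai[2L],
                           radius_um = r_px * pixel_size_um, score = sc)
    ## suppress the neighbourhood across all radii
    rs <- pmax(1L, ai[1L] - ceiling(r_px)):pmin(dim(acc)[1L], ai[1L] + ceiling(r_px))
    cs <- pmax(1L, ai[2L] - ceiling(r_px)):pmin(dim(acc)[2L], ai[2L] + ceiling(r_px))
    acc[rs, cs, ] <- -Inf
  }
  if (length(out) == 0L) return(data.frame(centre_row_px = integer(),
                                           centre_col_px = integer(),
                                           radius_um = numeric(),
                                           score = numeric()))
  do.call(rbind, out)
}

#' Segment GUVs as filled particles
#'
#' Gaussian blur (sigma = 3) -> Li auto-threshold -> fill holes -> erosion
#' -> connected-component extraction, mirroring a standard
#' blur/threshold/fill/erode/analyze-particles chain.  The Li threshold
#' lands on the outer skirt of the blurred membrane ring, so the filled
#' particle overshoots the vesicle by roughly the blur radius; the erosion
#' radius therefore defaults to `round(sigma)` pixels, which brings the ROI
#' boundary back to the membrane (set `erode_px = 1` for a plain one-pixel
#' erosion).
#'
#' @param membrane membrane channel matrix.
#' @param sigma blur radius, px.
#' @param erode_px erosion radius, px (default `round(sigma)`).
#' @param min_area_px discard components smaller than this.
#' @return list with `labels` (integer matrix, 0 = background) and `rois`
#'   (data.frame: `label`, `area_px`, `centroid_row_px`, `centroid_col_px`;
#'   1-based centroids).
#' @export
segment_guv_particles <- function(membrane, sigma = 3, erode_px = round(sigma),
                                  min_area_px = 25L) {
  img <- EBImage::gblur(EBImage::Image(membrane), sigma = sigma)
  m <- as.matrix(img)
  mask <- m > li_threshold(m)
  if (!any(mask))
    return(list(labels = matrix(0L, nrow(membrane), ncol(membrane)),
                rois = data.frame(label = integer(), area_px = integer(),
                                  centroid_row_px = numeric(),
                                  centroid_col_px = numeric())))
  mask <- EBImage::fillHull(mask * 1) > 0
  brush <- EBImage::makeBrush(2L * max(1L, as.integer(erode_px)) + 1L, "disc")
  mask <- EBImage::erode(mask * 1, brush) > 0
  lab <- EBImage::bwlabel(mask * 1)
  labs <- seq_len(max(lab))
  rois <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(lab == l)
    if (length(idx) < min_area_px) return(NULL)
    r <- (idx - 1L) %% nrow(lab) + 1L
    c <- (idx - 1L) %/% nrow(lab) + 1L
    data.frame(label = l, area_px = length(idx),
               centroid_row_px = mean(r), centroid_col_px = mean(c))
  }))
  if (is.null(rois))
    rois <- data.frame(label = integer(), area_px = integer(),
                       centroid_row_px = numeric(), centroid_col_px = numeric())
  list(labels = matrix(as.integer(lab), nrow(lab)), rois = rois)
}

#' Area fraction of the nanotube network inside a vesicle
#'
#' The RNA channel is blurred, thresholded (Otsu over the ROI) and eroded
#' by one pixel; the area fraction is the percentage of ROI pixels above
#' threshold.  Vesicles are kept only when the fraction exceeds
#' `min_fraction_pct` (the >1% rule).
#'
#' @param rna RNA channel matrix.
#' @param roi_mask logical matrix marking the vesicle interior.
#' @param min_fraction_pct keep/drop threshold, percent (default 1).
#' @param sigma blur radius, px (default 2; 0 disables).
#' @param erode erode the thresholded mask by one pixel (default TRUE).
#' @return list with `fraction_pct` and `keep`.
#' @export
nanotube_area_fraction <- function(rna, roi_mask, min_fraction_pct = 1,
                                   sigma = 2, erode = TRUE) {
  roi <- roi_mask > 0
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  img <- if (sigma > 0) as.matrix(EBImage::gblur(EBImage::Image(rna), sigma = sigma))
  else rna
  rng <- range(img)
  if (diff(rng) < 1e-12) {
    frac <- 0
  } else {
    nv <- (img - rng[1L]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(pmax(0, pmin(1, nv))), range = c(0, 1))
    sel <- nv > thr & roi
    if (erode && any(sel))
      sel <- (EBImage::erode(sel * 1, EBImage::makeBrush(3L, "box")) > 0) & roi
    frac <- 100 * sum(sel) / sum(roi)
  }
  list(fraction_pct = frac, keep = frac > min_fraction_pct)
}

#' Radial intensity profile of a vesicle
#'
#' Mean intensity in `n_bins` bins of normalized radius (bin centres
#' `(i - 0.5) / n_bins`), intensities normalized to maximum 1 (the
#' normalization cancels in [radial_com()] but matches the plotted
#' profiles).
#'
#' @param img intensity matrix (RNA channel).
#' @param centre_px (row, col) centre, 1-based.
#' @param radius_px vesicle radius, px.
#' @param n_bins number of radial bins (default 100).
#' @return object of class `radial_profile`: data.frame `x` (normalized
#'   radius), `y` (mean intensity).
#' @export
radial_profile <- function(img, centre_px, radius_px, n_bins = 100L) {
  rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  rho <- sqrt((rr - centre_px[1L])^2 + (cc - centre_px[2L])^2) / radius_px
  bin <- ceiling(pmax(1e-9, rho) * n_bins)
  ok <- bin >= 1L & bin <= n_bins
  y <- vapply(seq_len(n_bins), function(b) {
    v <- img[ok & bin == b]
    if (length(v)) mean(v) else 0
  }, 0)
  if (max(y) > 0) y <- y / max(y)
  structure(data.frame(x = (seq_len(n_bins) - 0.5) / n_bins, y = y),
            class = c("radial_profile", "data.frame"))
}

#' Radial centre of mass of a profile
#'
#' `x_c = sum(x_i * y_i) / sum(y_i)`: the intensity-weighted mean
#' normalized radius.  Values near 1 indicate cortical (membrane-bound)
#' signal, smaller values a lumen distribution.
#'
#' @param profile a [radial_profile()] (or any data.frame with `x`, `y`).
#' @return `x_c`.
#' @examples
#' radial_com(data.frame(x = (1:100 - 0.5) / 100, y = 1))  # 0.5
#' @export
radial_com <- function(profile) {
  x <- profile$x; y <- profile$y
  stopifnot(length(x) == length(y), !is.unsorted(x), all(y >= 0))
  s <- sum(y)
  if (s <= 0) stop("all-zero profile: radial centre of mass undefined",
                   call. = FALSE)
  sum(x * y) / s
}

## perimeter of a mask from its ordered outer boundary (0-based contour
## from EBImage::ocontour); chain-code weights per estimator, plus a
## half-pixel Minkowski offset (the contour passes through pixel centres,
## the physical boundary lies half a pixel outside)
raster_perimeter <- function(mask, estimator = c("kulpa", "freeman", "crofton")) {
  estimator <- match.arg(estimator)
  m <- mask > 0
  if (estimator == "crofton") {
    ## two-direction Crofton estimate: pi/4 times the intercept count in
    ## the axial directions (exact for isotropically oriented boundaries)
    nh <- sum(abs(diff(m * 1)))
    nv <- sum(abs(diff(t(m) * 1)))
    return(pi / 4 * (nh + nv))
  }
  oc <- EBImage::ocontour(EBImage::Image(m * 1))
  per <- 0
  for (ct in oc) {
    if (nrow(ct) < 2L) next
    d <- abs(diff(rbind(ct, ct[1L, ])))
    diag <- d[, 1L] == 1 & d[, 2L] == 1
    len <- sum(d[, 1L] | d[, 2L]) - sum(diag) + sqrt(2) * sum(diag)
    if (estimator == "kulpa") len <- kulpa_factor * len
    per <- per + len + pi   # half-pixel outward offset, convex correction
  }
  per
}

#' Circularity (isoperimetric shape factor)
#'
#' `R = 4 * pi * A / P^2`: 1 for a circle, less for any other shape.  Raster
#' mode (logical/0-1 matrix input) uses the pixel count as area and a
#' corrected chain-code boundary length as perimeter; analytic mode
#' (polygon input: numeric n x 2 vertex matrix) uses the shoelace area and
#' exact edge lengths.  Raster circularity is estimator-sensitive, so the
#' estimator used is attached to the result.
#'
#' @param x mask matrix, or polygon vertex matrix (closed implicitly).
#' @param estimator raster perimeter estimator: `"kulpa"` (default,
#'   bias-corrected chain code), `"freeman"` (plain 1/sqrt(2) weights) or
#'   `"crofton"`.
#' @return circularity, with attributes `area`, `perimeter`, `estimator`.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 1000L)[-1L]
#' circularity(cbind(cos(theta), sin(theta)))   # ~1 (analytic circle)
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' circularity(sq)                              # pi/4
#' @export
circularity <- function(x, estimator = c("kulpa", "freeman", "crofton")) {
  estimator <- match.arg(estimator)
  if (is.logical(x) || (is.matrix(x) && all(x %in% c(0, 1)) && nrow(x) > 2 && ncol(x) > 2)) {
    m <- x > 0
    A <- sum(m)
    P <- raster_perimeter(m, estimator)
    mode <- "raster"
  } else {
    stopifnot(is.matrix(x), ncol(x) == 2L, nrow(x) >= 3L)
    xx <- x[, 1L]; yy <- x[, 2L]
    xn <- c(xx[-1L], xx[1L]); yn <- c(yy[-1L], yy[1L])
    A <- abs(sum(xx * yn - xn * yy)) / 2
    P <- sum(sqrt((xn - xx)^2 + (yn - yy)^2))
    mode <- "analytic"
    estimator <- "exact"
  }
  if (P <= 0) stop("zero perimeter", call. = FALSE)
  R <- 4 * pi * A / P^2
  ## raster estimates can exceed 1 by estimator error (~1%); the
  ## isoperimetric bound is enforced, the raw value kept as an attribute
  structure(if (mode == "raster") min(R, 1) else R,
            raw = R, area = A, perimeter = P, estimator = estimator,
            mode = mode)
}

#' Mean circularity of a z-stack
#'
#' @param masks list of per-slice masks (or polygons).
#' @param ... passed to [circularity()].
#' @return mean circularity over slices.
#' @export
stack_circularity <- function(masks, ...) {
  mean(vapply(masks, function(m) as.numeric(circularity(m, ...)), 0))
}

#' Angular intensity sampling along the membrane
#'
#' For every `every`-th ordered boundary point, measures the mean intensity
#' of a rectangle drawn from the centroid towards that point, with length
#' `length_frac` (80%) of the centroid-to-membrane distance and a fixed
#' physical width; also reports the centroid-to-membrane distances.
#' Rectangles reaching outside the image are clipped with a warning.
#'
#' @param img intensity matrix (RNA channel).
#' @param boundary_px ordered boundary points, n x 2 (row, col), 1-based.
#' @param centroid_px (row, col) centroid, 1-based; must lie inside.
#' @param pixel_size_um um per pixel.
#' @param width_um rectangle width (default 3 um).
#' @param every sampling stride along the boundary (default 10).
#' @param length_frac rectangle length as a fraction of the
#'   centroid-to-membrane distance (default 0.8).
#' @return data.frame: `point_index`, `distance_um`, `mean_intensity`.
#' @export
angular_intensity <- function(img, boundary_px, centroid_px, pixel_size_um,
                              width_um = 3, every = 10L, length_frac = 0.8) {
  stopifnot(is.matrix(boundary_px), ncol(boundary_px) == 2L)
  sel <- seq(1L, nrow(boundary_px), by = every)
  half_w <- width_um / pixel_size_um / 2
  rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  clipped <- FALSE
  out <- lapply(sel, function(i) {
    p <- boundary_px[i, ]
    v <- p - centroid_px
    d <- sqrt(sum(v^2))
    if (d == 0) return(NULL)
    u <- v / d
    len <- length_frac * d
    ## pixels in the rectangle [0, len] x [-half_w, half_w] along u
    lr <- (rr - centroid_px[1L]) * u[1L] + (cc - centroid_px[2L]) * u[2L]
    lt <- -(rr - centroid_px[1L]) * u[2L] + (cc - centroid_px[2L]) * u[1L]
    inside <- lr >= 0 & lr <= len & abs(lt) <= half_w
    ## clipping check: would the rectangle extend beyond the image?
    ends <- rbind(centroid_px + len * u + half_w * c(-u[2L], u[1L]),
                  centroid_px + len * u - half_w * c(-u[2L], u[1L]))
    if (any(ends < 1) || any(ends[, 1L] > nrow(img)) || any(ends[, 2L] > ncol(img)))
      clipped <<- TRUE
    data.frame(point_index = i, distance_um = d * pixel_size_um,
               mean_intensity = mean(img[inside]))
  })
  if (clipped) warning("rectangle(s) clipped at the image border")
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Welch's two-sample t-test
#'
#' Unpaired, unequal-variance (Welch-corrected) two-tailed t-test.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df` (Welch--Satterthwaite) and `p` (two-tailed).
#' @examples
#' welch_ttest(c(1, 2, 3, 4), c(11, 12, 13, 14))
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    ## degenerate zero-variance case: identical groups give t = 0, p = 1
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both groups have zero variance but different means", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
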