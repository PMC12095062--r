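## AFM-like rendering of filament chains: tip-dilated ridges on a flat
## background, plus the binary masks and ground-truth registry that the
## tracing stage consumes.

#' Configuration of a synthetic AFM scene
#'
#' @param image_size_px integer `(rows, cols)`.
#' @param pixel_size_nm lateral calibration, nm per pixel.
#' @param tube_height_nm apparent ridge height above background, nm
#'   (nanotubes image at 5--6 nm).
#' @param tip_radius_nm radius of the disc used for morphological tip
#'   dilation, nm; 0 disables broadening.
#' @param background_height_nm flat background level, nm.
#' @param noise_sd_nm s.d. of additive Gaussian height noise, nm.
#' @param n_filaments number of filaments a scene simulator should place.
#' @param seed integer seed for noise (and placement, where applicable).
#' @return object of class `afm_scene_config`.
#' @export
afm_scene_config <- function(image_size_px = c(512L, 512L), pixel_size_nm = 4,
                             tube_height_nm = 6, tip_radius_nm = 5,
                             background_height_nm = 0, noise_sd_nm = 0,
                             n_filaments = 1L, seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 8))
  check_positive(pixel_size_nm)
  check_positive(tube_height_nm)
  check_nonneg(tip_radius_nm)
  check_nonneg(noise_sd_nm)
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_nm = pixel_size_nm,
    tube_height_nm = tube_height_nm,
    tip_radius_nm = tip_radius_nm,
    background_height_nm = background_height_nm,
    noise_sd_nm = noise_sd_nm,
    n_filaments = check_count(n_filaments, min = 0L),
    seed = seed
  ), class = "afm_scene_config")
}

## rasterize a polyline (nm coordinates) onto the pixel grid: pixel (r, c)
## covers [(r-1)*px, r*px) x [(c-1)*px, c*px); dense arc sampling marks every
## pixel the curve passes through.
rasterize_chain <- function(points_nm, pixel_size_nm, dims) {
  seg <- diff(points_nm)
  len <- sqrt(rowSums(seg^2))
  step <- 0.25 * pixel_size_nm
  xs <- ys <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    nsub <- max(1L, ceiling(len[i] / step))
    tt <- seq(0, 1, length.out = nsub + 1L)
    xs[[i]] <- points_nm[i, 1L] + tt * seg[i, 1L]
    ys[[i]] <- points_nm[i, 2L] + tt * seg[i, 2L]
  }
  x <- unlist(xs); y <- unlist(ys)
  r <- floor(x / pixel_size_nm) + 1L
  c <- floor(y / pixel_size_nm) + 1L
  if (any(r < 1L | r > dims[1L] | c < 1L | c > dims[2L]))
    stop("chain extends outside the image field of view", call. = FALSE)
  unique(cbind(r, c))
}

disc_brush <- function(radius_px) {
  if (radius_px < 1) return(NULL)
  k <- 2L * as.integer(radius_px) + 1L
  EBImage::makeBrush(k, shape = "disc")
}

#' Render filament chains as an AFM-like height image
#'
#' The height image is `background + tube_height * mask + noise`, where the
#' mask is the union of the rasterized chains dilated with a disc of radius
#' `tip_radius_nm` (a morphological stand-in for tip convolution, sufficient
#' to reproduce the width broadening seen in AFM).  When `noise_sd_nm = 0`
#' the mask equals the tip-dilated union of chain rasterizations exactly.
#'
#' @param config an [afm_scene_config()].
#' @param chains list of `filament_truth` objects (see [sample_wlc_chain()]);
#'   chain coordinates are interpreted as nm positions in the image frame
#'   (row axis = x, col axis = y) and must fall inside the field of view.
#' @return list with `height_nm` (matrix), `mask` (logical matrix), `truth`
#'   (data.frame: id, P_true_nm, L_true_nm, n_points) and `paths_px` (list of
#'   0-based (row, col) backbone pixel matrices, one per chain).
#' @export
render_afm_scene <- function(config, chains) {
  stopifnot(inherits(config, "afm_scene_config"))
  dims <- config$image_size_px
  mask <- matrix(FALSE, dims[1L], dims[2L])
  paths <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    px <- rasterize_chain(chains[[i]]$points_nm[, 1:2, drop = FALSE],
                          config$pixel_size_nm, dims)
    paths[[i]] <- px - 1L          # 0-based, for the ground-truth registry
    mask[px] <- TRUE
  }
  brush <- disc_brush(round(config$tip_radius_nm / config$pixel_size_nm))
  if (!is.null(brush) && any(mask))
    mask <- EBImage::dilate(mask * 1, brush) > 0
  height <- config$background_height_nm + config$tube_height_nm * mask
  if (config$noise_sd_nm > 0)
    height <- height + with_seed(config$seed,
      matrix(rnorm(length(height), 0, config$noise_sd_nm), nrow(height)))
  truth <- data.frame(
    id = vapply(chains, function(ch) ch$id, 1),
    P_true_nm = vapply(chains, function(ch) ch$P_true_nm, 1),
    L_true_nm = vapply(chains, function(ch) ch$L_true_nm, 1),
    n_points = vapply(chains, function(ch) nrow(ch$points_nm), 1L)
  )
  list(height_nm = height, mask = mask, truth = truth, paths_px = paths)
}

#' Simulate a complete AFM scene with randomly placed filaments
#'
#' Samples `config$n_filaments` chains from `params`, places each with a
#' random offset and orientation such that it fits the field of view, and
#' renders the scene.  Placement retries with fresh orientations and, if a
#' chain cannot fit at any orientation, with a freshly sampled chain — the
#' field of view truncates the length distribution exactly as it does in
#' real imaging.
#'
#' @param config an [afm_scene_config()].
#' @param params a [wlc_params()] ensemble description.
#' @param seed integer seed covering sampling and placement.
#' @param max_tries placement attempts per chain before giving up.
#' @return as [render_afm_scene()].
#' @export
simulate_afm_scene <- function(config, params, seed, max_tries = 200L) {
  stopifnot(inherits(config, "afm_scene_config"))
  chains <- sample_wlc_ensemble(params, config$n_filaments, seed)
  ext <- config$image_size_px * config$pixel_size_nm
  margin <- config$tip_radius_nm + 2 * config$pixel_size_nm
  placed <- with_seed(seed + 1L, lapply(chains, function(ch) {
    id0 <- ch$id
    for (k in seq_len(max_tries)) {
      th <- runif(1L, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      pts <- ch$points_nm[, 1:2, drop = FALSE] %*% R
      rng_x <- range(pts[, 1L]); rng_y <- range(pts[, 2L])
      if (diff(rng_x) > ext[1L] - 2 * margin || diff(rng_y) > ext[2L] - 2 * margin) {
        ## too long for the field of view at this orientation: retry a few
        ## times, then resample the chain (field-of-view truncation)
        if (k %% 20L == 0L) {
          sub_seed <- floor(runif(1L, 1, 2^30))
          ch <- sample_wlc_ensemble(params, 1L, sub_seed)[[1L]]
          ch$id <- id0
        }
        next
      }
      off_x <- runif(1L, margin - rng_x[1L], ext[1L] - margin - rng_x[2L])
      off_y <- runif(1L, margin - rng_y[1L], ext[2L] - margin - rng_y[2L])
      ch$points_nm <- cbind(pts[, 1L] + off_x, pts[, 2L] + off_y)
      return(ch)
    }
    stop("could not place a filament inside the field of view", call. = FALSE)
  }))
  render_afm_scene(config, placed)
}

#' Write an AFM scene to disk
#'
#' Height image as 16-bit grayscale TIFF (intensities scaled to the data
#' range recorded in the sidecar JSON), mask as PNG, ground truth as CSV.
#'
#' @param scene result of [render_afm_scene()].
#' @param dir output directory (created if needed).
#' @param basename file name stem.
#' @return invisibly, the paths written.
#' @export
write_afm_scene <- function(scene, dir, basename = "afm_scene") {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("png", quietly = TRUE))
    stop("writing scenes requires the 'tiff' and 'png' packages", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- scene$height_nm
  lo <- min(h); hi <- max(h)
  scaled <- if (hi > lo) (h - lo) / (hi - lo) else h * 0
  paths <- c(
    height = file.path(dir, paste0(basename, "_height.tif")),
    mask = file.path(dir, paste0(basename, "_mask.png")),
    truth = file.path(dir, paste0(basename, "_truth.csv")),
    meta = file.path(dir, paste0(basename, "_meta.json"))
  )
  tiff::writeTIFF(scaled, paths[["height"]], bits.per.sample = 16L)
  png::writePNG(scene$mask * 1, paths[["mask"]])
  write.csv(scene$truth, paths[["truth"]], row.names = FALSE)
  jsonlite::write_json(list(height_min_nm = lo, height_max_nm = hi),
                       paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
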