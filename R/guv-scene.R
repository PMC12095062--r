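## Synthetic two-channel GUV scenes: a membrane annulus per vesicle (with
## optional ellipse and low-order radial Fourier deformation) and an RNA
## channel realizing lumen, cortex or network localization, with full
## ground truth.

#' Describe one synthetic vesicle
#'
#' Deformation model: `radius(theta) = r_e(theta) * (1 + a2*cos(2*theta +
#' phi2) + a3*cos(3*theta + phi3))` where `r_e` is the polar radius of an
#' axis-aligned ellipse with axis ratio `axis_ratio >= 1` (semi-major
#' `axis_ratio * radius_um` along the row axis, semi-minor `radius_um`).
#'
#' @param centre_px (row, col) centre, 1-based pixels.
#' @param radius_um base radius, um.
#' @param axis_ratio ellipse axis ratio (>= 1; 1 = circle).
#' @param a2,a3,phi2,phi3 radial Fourier amplitudes and phases.
#' @param membrane_thickness_px membrane annulus thickness, px.
#' @param rna_mode one of `"none"`, `"lumen"`, `"cortex"`, `"network"`.
#' @param rna_intensity peak RNA channel intensity.
#' @return a list describing the vesicle.
#' @export
guv_vesicle <- function(centre_px, radius_um, axis_ratio = 1,
                        a2 = 0, a3 = 0, phi2 = 0, phi3 = 0,
                        membrane_thickness_px = 3L, rna_mode = "none",
                        rna_intensity = 1) {
  stopifnot(length(centre_px) == 2L, axis_ratio >= 1,
            rna_mode %in% c("none", "lumen", "cortex", "network"))
  check_positive(radius_um)
  list(centre_px = centre_px, radius_um = radius_um, axis_ratio = axis_ratio,
       a2 = a2, a3 = a3, phi2 = phi2, phi3 = phi3,
       membrane_thickness_px = membrane_thickness_px,
       rna_mode = rna_mode, rna_intensity = rna_intensity)
}

#' Configuration of a synthetic GUV scene
#'
#' @param image_size_px (rows, cols).
#' @param pixel_size_um lateral calibration, um per pixel.
#' @param vesicles list of [guv_vesicle()] descriptions.
#' @param membrane_background,rna_background uniform background levels of
#'   the two channels (membrane peak intensity is 1); confocal images have
#'   a nonzero background mode, which auto-thresholds rely on.
#' @param noise_sd s.d. of additive Gaussian noise on both channels.
#' @param overlap_tol tolerated fractional overlap of vesicle interiors
#'   (0 = any overlap is a placement error).
#' @param seed integer seed.
#' @return object of class `guv_scene_config`.
#' @export
guv_scene_config <- function(image_size_px = c(512L, 512L),
                             pixel_size_um = 0.2, vesicles = list(),
                             membrane_background = 0.1,
                             rna_background = 0.05,
                             noise_sd = 0, overlap_tol = 0, seed = 1L) {
  check_positive(pixel_size_um)
  check_nonneg(noise_sd)
  check_nonneg(membrane_background)
  check_nonneg(rna_background)
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    vesicles = vesicles,
    membrane_background = membrane_background,
    rna_background = rna_background,
    noise_sd = noise_sd,
    overlap_tol = overlap_tol,
    seed = seed
  ), class = "guv_scene_config")
}

## polar boundary radius (px) of a vesicle at angles theta (from row axis)
vesicle_radius_px <- function(v, theta, pixel_size_um) {
  r0 <- v$radius_um / pixel_size_um
  a <- v$axis_ratio * r0; b <- r0
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  re * (1 + v$a2 * cos(2 * theta + v$phi2) + v$a3 * cos(3 * theta + v$phi3))
}

#' Render a synthetic two-channel GUV scene
#'
#' The membrane channel shows an annulus per vesicle; the RNA channel
#' realizes each vesicle's `rna_mode`: `"none"` (pure background),
#' `"lumen"` (uniform interior fill), `"cortex"` (a shell hugging the inner
#' membrane face), or `"network"` (short filament strokes painted in the
#' lumen).  Vesicle interiors overlapping beyond `overlap_tol` raise a
#' placement error.
#'
#' @param config a [guv_scene_config()].
#' @return list with `membrane`, `rna` (matrices), and `truth` (data.frame:
#'   one row per vesicle with centre, radius, deformation, mode, interior
#'   area and painted RNA pixel count).
#' @export
make_guv_scene <- function(config) {
  stopifnot(inherits(config, "guv_scene_config"))
  dims <- config$image_size_px
  membrane <- matrix(config$membrane_background, dims[1L], dims[2L])
  rna <- matrix(config$rna_background, dims[1L], dims[2L])
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  interiors <- vector("list", length(config$vesicles))
  rows <- vector("list", length(config$vesicles))
  for (k in seq_along(config$vesicles)) {
    v <- config$vesicles[[k]]
    dr <- rr - v$centre_px[1L]
    dc <- cc - v$centre_px[2L]
    rho <- sqrt(dr^2 + dc^2)
    theta <- atan2(dc, dr)
    rb <- vesicle_radius_px(v, theta, config$pixel_size_um)
    half_t <- v$membrane_thickness_px / 2
    ring <- abs(rho - rb) <= half_t
    membrane[ring] <- 1
    interior <- rho < rb - half_t
    interiors[[k]] <- interior
    painted <- 0L
    if (v$rna_mode == "lumen") {
      rna[interior] <- rna[interior] + v$rna_intensity
      painted <- sum(interior)
    } else if (v$rna_mode == "cortex") {
      shell <- rho < rb - half_t & rho >= rb - half_t - 3
      rna[shell] <- rna[shell] + v$rna_intensity
      painted <- sum(shell)
    } else if (v$rna_mode == "network") {
      net <- with_seed(config$seed + k, {
        m <- matrix(FALSE, dims[1L], dims[2L])
        r0_px <- v$radius_um / config$pixel_size_um
        n_strokes <- max(3L, round(r0_px / 4))
        for (s in seq_len(n_strokes)) {
          len <- runif(1L, 0.5, 1.4) * r0_px
          ang0 <- runif(1L, 0, 2 * pi)
          start_rho <- runif(1L, 0, 0.5 * r0_px)
          start_ang <- runif(1L, 0, 2 * pi)
          p0 <- v$centre_px + start_rho * c(cos(start_ang), sin(start_ang))
          npx <- max(2L, ceiling(len))
          tt <- seq(0, len, length.out = npx)
          pr <- round(p0[1L] + tt * cos(ang0))
          pc <- round(p0[2L] + tt * sin(ang0))
          ok <- pr >= 1L & pr <= dims[1L] & pc >= 1L & pc <= dims[2L]
          m[cbind(pr[ok], pc[ok])] <- TRUE
        }
        m & interior
      })
      rna[net] <- rna[net] + v$rna_intensity
      painted <- sum(net)
    }
    rows[[k]] <- data.frame(
      id = k, centre_row_px = v$centre_px[1L], centre_col_px = v$centre_px[2L],
      radius_um = v$radius_um, axis_ratio = v$axis_ratio,
      a2 = v$a2, a3 = v$a3, rna_mode = v$rna_mode,
      interior_px = sum(interior), rna_painted_px = painted)
  }
  ## placement check: pairwise interior overlap
  if (length(interiors) > 1L) {
    for (i in seq_len(length(interiors) - 1L)) for (j in (i + 1L):length(interiors)) {
      ov <- sum(interiors[[i]] & interiors[[j]])
      lim <- config$overlap_tol * min(sum(interiors[[i]]), sum(interiors[[j]]))
      if (ov > lim)
        stop(sprintf("vesicles %d and %d overlap beyond tolerance", i, j),
             call. = FALSE)
    }
  }
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed, list(
      m = matrix(rnorm(length(membrane), 0, config$noise_sd), dims[1L]),
      r = matrix(rnorm(length(rna), 0, config$noise_sd), dims[1L])))
    membrane <- membrane + noise$m
    rna <- rna + noise$r
  }
  list(membrane = membrane, rna = rna, truth = do.call(rbind, rows))
}
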