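## End-to-end pipelines and presets: simulate -> render -> trace -> filter
## -> fit, reproducible from a single seed, plus report helpers.

#' Named AFM filament presets
#'
#' Study-condition presets for the synthetic AFM pipeline.  Ground-truth
#' persistence lengths and contour-length distributions follow the AFM
#' estimates for the wild-type and double-stranded-loop-out nanotube
#' designs: `"wt-afm"` has P = 3.4 um with contour lengths
#' lognormal(mean 970.9 nm, s.d. 735.1 nm), `"dsov-afm"` has P = 0.8 um
#' with lognormal(mean 706.1 nm, s.d. 563.8 nm); both are truncated at the
#' 200 nm detection limit and discretized at 5 nm.
#'
#' @param name `"wt-afm"` or `"dsov-afm"`.
#' @return list with `params` ([wlc_params()]) and `scene`
#'   ([afm_scene_config()] template: 4 nm pixels, 6 nm tube height, 5 nm
#'   tip radius, noiseless).
#' @export
afm_preset <- function(name = c("wt-afm", "dsov-afm")) {
  name <- match.arg(name)
  pars <- switch(name,
    "wt-afm" = wlc_params(3400, step_nm = 5, length_mean_nm = 970.9,
                          length_sd_nm = 735.1, truncation_min_nm = 200),
    "dsov-afm" = wlc_params(800, step_nm = 5, length_mean_nm = 706.1,
                            length_sd_nm = 563.8, truncation_min_nm = 200))
  list(name = name,
       params = pars,
       scene = afm_scene_config(pixel_size_nm = 4, tube_height_nm = 6,
                                tip_radius_nm = 5, noise_sd_nm = 0))
}

## render one chain in its own minimal image tile and trace it back
trace_one_filament <- function(chain, scene, estimator, mask_source = "truth") {
  px <- scene$pixel_size_nm
  margin <- scene$tip_radius_nm + 3 * px
  pts <- chain$points_nm[, 1:2, drop = FALSE]
  pts[, 1L] <- pts[, 1L] - min(pts[, 1L]) + margin
  pts[, 2L] <- pts[, 2L] - min(pts[, 2L]) + margin
  chain$points_nm <- pts
  dims <- ceiling(c(max(pts[, 1L]) + margin, max(pts[, 2L]) + margin) / px)
  cfg <- afm_scene_config(image_size_px = pmax(dims, 8L), pixel_size_nm = px,
                          tube_height_nm = scene$tube_height_nm,
                          tip_radius_nm = scene$tip_radius_nm,
                          background_height_nm = scene$background_height_nm,
                          noise_sd_nm = scene$noise_sd_nm,
                          n_filaments = 1L, seed = scene$seed + chain$id)
  sc <- render_afm_scene(cfg, list(chain))
  mask <- if (mask_source == "truth") sc$mask
  else {
    h <- sc$height_nm
    nv <- (h - min(h)) / max(1e-12, diff(range(h)))
    nv > EBImage::otsu(EBImage::Image(nv), range = c(0, 1))
  }
  tm <- trace_mask(mask, px, estimator = estimator)
  if (nrow(tm) == 0L) return(NULL)
  tm[which.max(tm$n_pixels), , drop = FALSE]
}

#' Run the full AFM persistence-length pipeline on a preset
#'
#' Samples `n_filaments` chains, renders each as a noiseless (or noisy)
#' AFM tile, skeletonizes and traces the rendered mask, measures contour
#' and end-to-end length, filters detections under `min_length_nm`, fits
#' the worm-like-chain relation (`s = 1`) and applies one pass of residual
#' masking.
#'
#' @param preset an [afm_preset()] (or its name).
#' @param n_filaments chains per run (default 300).
#' @param seed integer seed.
#' @param estimator chain-code length estimator for tracing; the default
#'   `"kulpa"` removes digitization bias (see [measure_filament()]).
#' @param mask_source `"truth"` (generator masks) or `"otsu"` (threshold
#'   the rendered height image).
#' @param min_length_nm detection filter (default 200 nm).
#' @return list of class `afm_pipeline_result`: `fit` (masked [fit_wlc()]
#'   result), `records`, `mean_contour_nm`, `preset`, `seed`.
#' @export
run_afm_pipeline <- function(preset = "wt-afm", n_filaments = 300L, seed = 1L,
                             estimator = "kulpa",
                             mask_source = c("truth", "otsu"),
                             min_length_nm = 200) {
  if (is.character(preset)) preset <- afm_preset(preset)
  mask_source <- match.arg(mask_source)
  chains <- sample_wlc_ensemble(preset$params, n_filaments, seed)
  scene <- preset$scene
  scene$seed <- seed
  rows <- lapply(chains, trace_one_filament, scene = scene,
                 estimator = estimator, mask_source = mask_source)
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rec <- filament_records(rows$contour_nm, rows$end_to_end_nm^2, source = "afm")
  rec <- filter_records(rec, min_length_nm)
  fit <- mask_and_refit(fit_wlc(rec, s = 1))
  structure(list(fit = fit, records = rec,
                 mean_contour_nm = mean(rec$L_nm),
                 preset = preset, seed = seed,
                 n_traced = nrow(rows)),
            class = "afm_pipeline_result")
}

#' @export
print.afm_pipeline_result <- function(x, ...) {
  cat(sprintf("<afm_pipeline_result> preset %s, seed %s: P = %.3g um (n = %d records)\n",
              x$preset$name, format(x$seed), x$fit$P_nm / 1000, x$fit$n_used))
  invisible(x)
}

#' Median recovered persistence length over seeds
#'
#' Runs [run_afm_pipeline()] for each seed and reports the median fitted
#' persistence length -- the summary used for stochastic recovery checks.
#'
#' @param preset preset (name or [afm_preset()] object).
#' @param seeds integer vector of seeds (>= 5 recommended).
#' @param n_filaments chains per seed.
#' @param ... passed to [run_afm_pipeline()].
#' @return list: `median_P_nm`, `median_P_um`, `per_seed` (data.frame).
#' @export
recover_persistence_length <- function(preset, seeds, n_filaments = 300L, ...) {
  runs <- lapply(seeds, function(s)
    run_afm_pipeline(preset, n_filaments = n_filaments, seed = s, ...))
  per_seed <- data.frame(
    seed = seeds,
    P_nm = vapply(runs, function(r) r$fit$P_nm, 0),
    n_used = vapply(runs, function(r) r$fit$n_used, 0L),
    mean_contour_nm = vapply(runs, function(r) r$mean_contour_nm, 0))
  list(median_P_nm = median(per_seed$P_nm),
       median_P_um = median(per_seed$P_nm) / 1000,
       per_seed = per_seed)
}

#' Flexibility ratio of a nanotube population
#'
#' Ratio of persistence length to mean contour length, reported to two
#' significant figures (e.g. P = 3.4 um over a 970.9 nm mean length gives
#' 3.5; P = 0.8 um over 706.1 nm gives 1.1).
#'
#' @param P_um persistence length, um.
#' @param mean_L_nm mean contour length, nm.
#' @return the ratio, 2 significant figures.
#' @export
flexibility_ratio <- function(P_um, mean_L_nm) {
  check_positive(P_um)
  check_positive(mean_L_nm)
  signif(P_um * 1000 / mean_L_nm, 2)
}
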