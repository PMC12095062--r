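## Persistence-length inference: fit the worm-like-chain end-to-end relation
## to (contour length, squared end-to-end) records, with length filtering
## and one-pass residual masking.

#' Build a table of filament records
#'
#' @param L_nm contour lengths, nm.
#' @param R2_nm2 squared end-to-end distances, nm^2.
#' @param source record provenance label(s), e.g. `"afm"` or `"sim:12"`.
#' @param clamp physical bound handling: rasterized traces of near-straight
#'   filaments can report `R2` marginally above `L^2` (the corrected length
#'   estimator is unbiased only on average over orientations); excesses up to
#'   15% are clamped to `L^2` when `clamp = TRUE`, larger ones are an error.
#' @return data.frame with columns `L_nm`, `R2_nm2`, `source`.
#' @export
filament_records <- function(L_nm, R2_nm2, source = "afm", clamp = TRUE) {
  stopifnot(length(L_nm) == length(R2_nm2))
  if (any(!is.finite(L_nm)) || any(!is.finite(R2_nm2)))
    stop("records must be finite", call. = FALSE)
  if (any(L_nm <= 0) || any(R2_nm2 < 0))
    stop("records must satisfy L > 0 and R2 >= 0", call. = FALSE)
  excess <- R2_nm2 / L_nm^2
  if (any(excess > 1.15))
    stop("records violate R2 <= L^2 by more than 15%", call. = FALSE)
  if (any(excess > 1)) {
    if (!clamp) stop("records violate R2 <= L^2", call. = FALSE)
    R2_nm2 <- pmin(R2_nm2, L_nm^2)
  }
  data.frame(L_nm = L_nm, R2_nm2 = R2_nm2,
             source = rep_len(source, length(L_nm)))
}

#' Filter out short detections
#'
#' Detections below the minimum length are excluded (reducing the impact of
#' limited imaging resolution); the threshold itself is kept, i.e. "under
#' 200 nm" is read strictly.
#'
#' @param records data.frame from [filament_records()].
#' @param min_length_nm threshold (default 200 nm).
#' @return the retained records (possibly empty).
#' @export
filter_records <- function(records, min_length_nm = 200) {
  records[records$L_nm >= min_length_nm, , drop = FALSE]
}

## Relative conditional s.d. of R^2 given L for the calibrated chain
## ensemble, up to a constant factor: cv(x) = x / (1 + x/5) with x = L/(sP).
## The shape was measured by brute-force sampling of the 2D ensemble
## (2000 chains per L over L/P in [0.06, 5]); the overall constant cancels
## in weighted least squares.
wlc_cv_rel <- function(x) x / (1 + 0.2 * x)

run_nls <- function(records, start_P, s, weights = NULL, upper_P) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-10)
  dat <- records
  dat$s0 <- s
  fml <- R2_nm2 ~ 2 * s0 * P * L_nm *
    (1 - (s0 * P / L_nm) * (1 - exp(-L_nm / (s0 * P))))
  fit <- tryCatch({
    if (is.null(weights))
      minpack.lm::nlsLM(fml, data = dat, start = list(P = start_P),
                        lower = 1e-6, upper = upper_P, control = ctl)
    else {
      dat$.fit_w <- weights   # nls evaluates `weights` inside `data`
      minpack.lm::nlsLM(fml, data = dat, start = list(P = start_P),
                        weights = .fit_w, lower = 1e-6, upper = upper_P,
                        control = ctl)
    }
  }, error = function(e)
    stop("worm-like-chain fit did not converge: ", conditionMessage(e),
         call. = FALSE))
  fit
}

#' Fit the worm-like-chain end-to-end relation
#'
#' Nonlinear least squares of squared end-to-end distance on contour length
#' using [wlc_r2_theory()].  Because the conditional spread of `R^2` grows
#' steeply with `L`, the default fit is variance-weighted: a pilot
#' unweighted pass estimates `P`, weights `1/sigma_i^2` with
#' `sigma_i = E[R^2] * cv(L_i/P)` (see the package vignette) are then frozen
#' and a single weighted pass refits.  `weighting = "none"` gives the plain
#' unweighted fit.
#'
#' The surface parameter `s` is fixed at 1 by default.  `fix_s = FALSE`
#' frees it, but `s` and `P` enter the relation only through their product,
#' so only `s * P` is identifiable: the free mode fits that product and
#' reports it with `s` normalized to 1.
#'
#' @param records data.frame with `L_nm` and `R2_nm2` columns.
#' @param s surface parameter (default 1).
#' @param fix_s keep `s` fixed (default) or fit it jointly.
#' @param weighting `"variance-model"` (default) or `"none"`.
#' @param P0 optional starting value, nm; default `max(L)/4`.
#' @return object of class `wlc_fit`: `P_nm`, `stderr_nm` (from the fit
#'   covariance), `s`, `n_used`, `mask` (records kept; all `TRUE` here, see
#'   [mask_and_refit()]), `residual_sd` (s.d. of raw residuals),
#'   `stiff_limit` (`TRUE` when the fit ran into its upper bound, i.e. the
#'   data carry no curvature information), `weighting`, `records`.
#' @examples
#' L <- seq(200, 3000, by = 200)
#' rec <- filament_records(L, wlc_r2_theory(L, 2000))
#' fit_wlc(rec)$P_nm    # 2000 to machine precision
#' @export
fit_wlc <- function(records, s = 1, fix_s = TRUE,
                    weighting = c("variance-model", "none"), P0 = NULL) {
  weighting <- match.arg(weighting)
  if (nrow(records) < 5L)
    stop("need at least 5 records to fit", call. = FALSE)
  if (length(unique(records$L_nm)) < 2L)
    stop("records must span more than one distinct contour length",
         call. = FALSE)
  if (!fix_s) s <- 1              # fit the identifiable product s * P
  upper_P <- 10 * max(records$L_nm)
  start <- if (is.null(P0)) max(records$L_nm) / 4 else P0
  start <- min(max(start, 1), 0.99 * upper_P)

  pilot <- run_nls(records, start, s, weights = NULL, upper_P = upper_P)
  P_hat <- coef(pilot)[["P"]]
  s_hat <- s
  final <- pilot
  sigma <- NULL
  if (weighting == "variance-model") {
    P_w <- min(max(P_hat, 10), 5 * max(records$L_nm))
    mu <- wlc_r2_theory(records$L_nm, P_w, s_hat)
    sigma <- pmax(mu * wlc_cv_rel(records$L_nm / (s_hat * P_w)),
                  1e-8 * max(records$R2_nm2))
    final <- run_nls(records, P_hat, s, weights = 1 / sigma^2,
                     upper_P = upper_P)
    P_hat <- coef(final)[["P"]]
  }
  resid_raw <- records$R2_nm2 - wlc_r2_theory(records$L_nm, P_hat, s_hat)
  se <- tryCatch(sqrt(diag(vcov(final)))[["P"]], error = function(e) NA_real_)
  structure(list(
    P_nm = P_hat,
    stderr_nm = se,
    s = s_hat,
    n_used = nrow(records),
    mask = rep(TRUE, nrow(records)),
    residual_sd = sd(resid_raw),
    stiff_limit = P_hat >= 0.95 * upper_P,
    weighting = weighting,
    sigma_model = sigma,
    records = records
  ), class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit> P = %.4g nm (s.e. %.3g), s = %.3g, n = %d%s\n",
              x$P_nm, x$stderr_nm, x$s, x$n_used,
              if (x$stiff_limit) " [stiff-limit]" else ""))
  invisible(x)
}

#' Mask residual outliers and refit once
#'
#' Records whose raw fit residual exceeds one residual standard deviation in
#' magnitude are removed and the relation is refit a single time (matching
#' the one-pass masking of the original analysis); `iterate = TRUE` repeats
#' until the mask stabilizes.  If all residuals are identical (noiseless
#' data), nothing is masked.
#'
#' @param fit a [fit_wlc()] result.
#' @param sd_multiple masking threshold in residual s.d. units (default 1).
#' @param iterate iterate mask + refit to convergence (off by default).
#' @param max_iter safety cap for `iterate = TRUE`.
#' @return a new `wlc_fit` whose `mask` marks the kept records (relative to
#'   the records of the input fit).
#' @export
mask_and_refit <- function(fit, sd_multiple = 1, iterate = FALSE,
                           max_iter = 20L) {
  stopifnot(inherits(fit, "wlc_fit"))
  records <- fit$records
  mask <- rep(TRUE, nrow(records))
  current <- fit
  for (i in seq_len(if (iterate) max_iter else 1L)) {
    r <- records$R2_nm2 - wlc_r2_theory(records$L_nm, current$P_nm, current$s)
    sd0 <- sd(r[mask])
    ## numerically zero residual spread (noiseless data): nothing to mask
    if (!is.finite(sd0) || sd0 <= 1e-8 * max(abs(records$R2_nm2))) break
    new_mask <- abs(r) <= sd_multiple * sd0
    if (!any(new_mask))
      stop("residual masking removed all records", call. = FALSE)
    if (identical(new_mask, mask) && i > 1L) break
    changed <- !identical(new_mask, mask)
    mask <- new_mask
    refit <- fit_wlc(records[mask, , drop = FALSE], s = fit$s,
                     weighting = fit$weighting, P0 = current$P_nm)
    current <- refit
    if (!changed) break
  }
  current$mask <- mask
  current$n_used <- sum(mask)
  current$records <- records
  current
}

#' Indices of the middle fraction of nanotube layers
#'
#' Drops `ceiling((1 - fraction)/2 * n)` layers at each end: for 100 layers
#' at the default 0.8, layers 11 to 90 are kept (exactly 80 layers).
#'
#' @param n number of layers.
#' @param fraction fraction retained (default 0.8).
#' @return integer vector of retained layer indices.
#' @export
middle_layer_indices <- function(n, fraction = 0.8) {
  stopifnot(fraction > 0, fraction <= 1, n >= 2)
  drop <- ceiling((1 - fraction) / 2 * n)
  seq(drop + 1L, n - drop)
}

#' Per-frame persistence length from layer centroids
#'
#' For each trajectory frame, restricts to the middle fraction of layers
#' (dropping `ceiling((1 - middle_fraction)/2 * n)` layers at each end, so
#' 100 layers at the default keep layers 11--90), forms every layer pair
#' `(i < j)` with `L` the summed consecutive centroid distances and `R^2`
#' the squared direct distance, and fits the worm-like-chain relation with
#' residual masking, frame by frame.
#'
#' @param centroid_frames list of per-frame layer-centroid matrices (rows =
#'   layers, ordered along the tube axis), or a 3-d array
#'   `[layer, coordinate, frame]`.
#' @param middle_fraction fraction of layers retained (default 0.8).
#' @param min_length_nm optional contour-length filter applied to layer
#'   pairs (default 0: simulated pairs are not length-filtered).
#' @param s,weighting passed to [fit_wlc()].
#' @return data.frame with one row per frame: `frame`, `P_nm`, `stderr_nm`,
#'   `n_used`, `residual_sd`, `stiff_limit`.  Frames that cannot be fit are
#'   reported as `NA` with a warning.
#' @export
per_frame_persistence <- function(centroid_frames, middle_fraction = 0.8,
                                  min_length_nm = 0, s = 1,
                                  weighting = "variance-model") {
  if (is.array(centroid_frames) && length(dim(centroid_frames)) == 3L)
    centroid_frames <- lapply(seq_len(dim(centroid_frames)[3L]),
                              function(k) centroid_frames[, , k])
  stopifnot(middle_fraction > 0, middle_fraction <= 1)
  out <- vector("list", length(centroid_frames))
  for (f in seq_along(centroid_frames)) {
    cen <- centroid_frames[[f]]
    n <- nrow(cen)
    if (n < 10L) {
      warning(sprintf("frame %d skipped: fewer than 10 layers", f))
      out[[f]] <- data.frame(frame = f, P_nm = NA_real_, stderr_nm = NA_real_,
                             n_used = 0L, residual_sd = NA_real_,
                             stiff_limit = NA)
      next
    }
    cen <- cen[middle_layer_indices(n, middle_fraction), , drop = FALSE]
    m <- nrow(cen)
    seg <- sqrt(rowSums(diff(cen)^2))
    cum <- c(0, cumsum(seg))
    ij <- t(utils::combn(m, 2L))
    L <- cum[ij[, 2L]] - cum[ij[, 1L]]
    R2 <- rowSums((cen[ij[, 2L], , drop = FALSE] -
                   cen[ij[, 1L], , drop = FALSE])^2)
    rec <- filament_records(L, R2, source = sprintf("sim:%d", f))
    rec <- filter_records(rec, min_length_nm)
    row <- tryCatch({
      fit <- mask_and_refit(fit_wlc(rec, s = s, weighting = weighting))
      data.frame(frame = f, P_nm = fit$P_nm, stderr_nm = fit$stderr_nm,
                 n_used = fit$n_used, residual_sd = fit$residual_sd,
                 stiff_limit = fit$stiff_limit)
    }, error = function(e) {
      warning(sprintf("frame %d skipped: %s", f, conditionMessage(e)))
      data.frame(frame = f, P_nm = NA_real_, stderr_nm = NA_real_,
                 n_used = 0L, residual_sd = NA_real_, stiff_limit = NA)
    })
    out[[f]] <- row
  }
  do.call(rbind, out)
}

#' Planned frame step indices of a trajectory
#'
#' @param total_steps total simulation steps (default 1e9).
#' @param save_every saving cadence in steps (default 5e5).
#' @return numeric vector of the step index of every saved frame.
#' @examples
#' length(frame_schedule())   # 2000 frames
#' @export
frame_schedule <- function(total_steps = 1e9, save_every = 5e5) {
  check_positive(total_steps)
  check_positive(save_every)
  seq(save_every, total_steps, by = save_every)
}

#' Select the final fraction of simulation frames
#'
#' Keeps frames whose step index is at least `(1 - fraction) * total_steps`
#' (inclusive), e.g. the last 10% of a 1e9-step run are frames with
#' `t >= 9e8`.
#'
#' @param frames data.frame with a `step` column, or a numeric vector of
#'   step indices.
#' @param fraction final fraction to keep (default 0.1).
#' @param total_steps total steps of the run (default 1e9).
#' @return the selected subset, same type as the input.
#' @export
select_final_fraction <- function(frames, fraction = 0.1, total_steps = 1e9) {
  stopifnot(fraction >= 0, fraction <= 1)
  cutoff <- (1 - fraction) * total_steps
  if (is.data.frame(frames)) frames[frames$step >= cutoff, , drop = FALSE]
  else frames[frames >= cutoff]
}
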