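## Structural statistics of coarse-grained trajectories: rigid-body
## alignment and mean structure, per-nucleotide RMSF, designed-bond
## occupancy, inter-duplex angles, kissing-loop quality filtering, layer
## centroids and simulation-time conversion.

## Kabsch rotation: proper rotation R minimizing |X R - Y|
kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## accept a nanotube_trajectory, a list of frames (lists with $pos or bare
## matrices), and return a list of position matrices
frame_positions <- function(trajectory) {
  frames <- if (inherits(trajectory, "nanotube_trajectory")) trajectory$frames
  else trajectory
  lapply(frames, function(f) if (is.list(f)) f$pos else f)
}

#' Rigid-body alignment and mean structure of a trajectory
#'
#' Superposes every frame onto a reference by translation + proper rotation
#' (Kabsch), averages the aligned positions, and identifies the frame
#' closest to the mean (the "centroid structure").  The reference is the
#' first frame by default; `reference = "mean"` runs a second pass aligned
#' to the first-pass mean.
#'
#' @param trajectory a `nanotube_trajectory`, a list of frames from
#'   [read_oxdna_trajectory()], or a list of n x 3 position matrices.
#' @param reference `"first"` (default) or `"mean"`.
#' @return list with `aligned` (list of aligned position matrices), `mean`
#'   (n x 3), `rotations` (list of 3 x 3), `rmsd` (per-frame RMSD to the
#'   mean), `centroid_frame` (index of the frame closest to the mean).
#' @export
align_and_mean <- function(trajectory, reference = c("first", "mean")) {
  reference <- match.arg(reference)
  frames <- frame_positions(trajectory)
  if (length(frames) < 2L)
    stop("alignment needs at least 2 frames", call. = FALSE)
  align_to <- function(ref) {
    ctr <- colMeans(ref)
    refc <- sweep(ref, 2L, ctr)
    lapply(frames, function(p) {
      pc <- sweep(p, 2L, colMeans(p))
      R <- kabsch_rotation(pc, refc)
      out <- sweep(pc %*% R, 2L, ctr, `+`)   # back into the reference frame
      attr(out, "rotation") <- R
      out
    })
  }
  ref <- frames[[1L]]
  if (qr(sweep(ref, 2L, colMeans(ref)))$rank < 2L)
    warning("reference frame is degenerate (collinear points); alignment may be ill-defined")
  aligned <- align_to(ref)
  mn <- Reduce(`+`, aligned) / length(aligned)
  if (reference == "mean") {
    aligned <- align_to(mn)
    mn <- Reduce(`+`, aligned) / length(aligned)
  }
  rmsd <- vapply(aligned, function(p) sqrt(mean(rowSums((p - mn)^2))), 0)
  list(aligned = lapply(aligned, function(p) { attributes(p)["rotation"] <- NULL; p }),
       mean = mn,
       rotations = lapply(aligned, attr, "rotation"),
       rmsd = rmsd,
       centroid_frame = which.min(rmsd))
}

#' Per-nucleotide root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean_frames |x_i - xbar_i|^2)` over aligned frames.
#'
#' @param aligned list of aligned position matrices (from
#'   [align_and_mean()]`$aligned`), or an `align_and_mean()` result.
#' @param mean_structure the mean structure; taken from the result object if
#'   omitted.
#' @return numeric vector, one RMSF per nucleotide (same units as input).
#' @export
compute_rmsf <- function(aligned, mean_structure = NULL) {
  if (is.list(aligned) && !is.null(aligned$aligned)) {
    mean_structure <- aligned$mean
    aligned <- aligned$aligned
  }
  if (length(aligned) < 2L)
    stop("RMSF is undefined for a single frame", call. = FALSE)
  if (is.null(mean_structure))
    mean_structure <- Reduce(`+`, aligned) / length(aligned)
  acc <- Reduce(`+`, lapply(aligned, function(p) rowSums((p - mean_structure)^2)))
  sqrt(acc / length(aligned))
}

## distances of registry pairs in one frame
pair_distances <- function(pos, reg) {
  sqrt(rowSums((pos[reg$i + 1L, , drop = FALSE] -
                pos[reg$j + 1L, , drop = FALSE])^2))
}

#' Designed-bond occupancy of a registry region
#'
#' Occupancy is the fraction, over frames x designed pairs of the region,
#' of pairs whose inter-nucleotide distance is below the cutoff -- a
#' distance proxy for energy-based bond calls, exact on generator
#' trajectories.  Pairs are averaged first, then frames (the run occupancy
#' is the frame mean of the per-frame pair fraction, identical to the
#' overall fraction for a fixed region size).
#'
#' @param trajectory frames (as accepted by [align_and_mean()]).
#' @param registry designed-bond registry (data.frame with `i`, `j`,
#'   `region`; 0-based).
#' @param region region label to evaluate (default: all pairs).
#' @param distance_cutoff bond-call distance, same units as the positions;
#'   defaults to [default_bond_cutoff()] when the trajectory carries its
#'   assembly.
#' @return occupancy in `[0, 1]`, with attribute `per_frame`.
#' @export
bond_occupancy <- function(trajectory, registry, region = NULL,
                           distance_cutoff = NULL) {
  if (is.null(distance_cutoff)) {
    if (inherits(trajectory, "nanotube_trajectory"))
      distance_cutoff <- default_bond_cutoff(trajectory$assembly)
    else stop("`distance_cutoff` must be given when the trajectory carries no assembly",
              call. = FALSE)
  }
  reg <- if (is.null(region)) registry
  else registry[registry$region == region, , drop = FALSE]
  if (nrow(reg) == 0L)
    stop(sprintf("region %s has no designed pairs",
                 if (is.null(region)) "<all>" else region), call. = FALSE)
  frames <- frame_positions(trajectory)
  per_frame <- vapply(frames, function(pos)
    mean(pair_distances(pos, reg) < distance_cutoff), 0)
  structure(mean(per_frame), per_frame = per_frame)
}

#' Angle between two duplex axes
#'
#' Each duplex axis is the principal direction (best-fit line) of its
#' nucleotide positions, oriented along the 5'-to-3' order of the supplied
#' ids so that parallel duplexes give 0 degrees; the unsigned angle in
#' `[0, 180]` degrees is returned and is symmetric in its arguments.
#'
#' @param pos n x 3 position matrix of one frame.
#' @param ids_a,ids_b 0-based nucleotide ids of the two duplexes (at least
#'   4 each), in strand order.
#' @return angle beta in degrees.
#' @export
duplex_angle_beta <- function(pos, ids_a, ids_b) {
  axis_of <- function(ids) {
    if (length(ids) < 4L)
      stop("each duplex needs at least 4 nucleotides", call. = FALSE)
    x <- pos[ids + 1L, , drop = FALSE]
    xc <- scale(x, scale = FALSE)
    s <- svd(xc)
    if (s$d[1L] < 1e-9)
      stop("degenerate duplex point cloud", call. = FALSE)
    v <- s$v[, 1L]
    ## orient along the 5'->3' order of the ids
    if (sum((x[nrow(x), ] - x[1L, ]) * v) < 0) v <- -v
    v
  }
  ca <- sum(axis_of(ids_a) * axis_of(ids_b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Filter simulation runs by internal kissing-loop quality
#'
#' A run passes if every internal kissing loop maintains, on average over
#' frames, at least `min_mean_bonds` of its `designed` designed bonds
#' (bond call as in [bond_occupancy()]).  Runs are returned in input order.
#'
#' @param runs list of trajectories (as accepted by [bond_occupancy()]).
#' @param registry designed-bond registry with `category == "internal_KL"`
#'   pairs grouped by `kl_id`.
#' @param min_mean_bonds acceptance threshold (default 11).
#' @param designed designed bonds per kissing loop (default 12).
#' @param distance_cutoff bond-call distance (default from the first run's
#'   assembly).
#' @return integer indices of the accepted runs, with attribute
#'   `mean_bonds` (matrix: run x kissing loop).
#' @export
kl_quality_filter <- function(runs, registry, min_mean_bonds = 11,
                              designed = 12, distance_cutoff = NULL) {
  kl <- registry[registry$category == "internal_KL", , drop = FALSE]
  if (nrow(kl) == 0L)
    stop("registry has no internal_KL pairs", call. = FALSE)
  if (is.null(distance_cutoff)) {
    if (inherits(runs[[1L]], "nanotube_trajectory"))
      distance_cutoff <- default_bond_cutoff(runs[[1L]]$assembly)
    else stop("`distance_cutoff` must be given", call. = FALSE)
  }
  ids <- sort(unique(kl$kl_id))
  mean_bonds <- t(vapply(runs, function(run) {
    frames <- frame_positions(run)
    per_kl <- vapply(ids, function(id) {
      reg <- kl[kl$kl_id == id, , drop = FALSE]
      counts <- vapply(frames, function(pos)
        sum(pair_distances(pos, reg) < distance_cutoff), 0)
      mean(counts)
    }, 0)
    per_kl
  }, numeric(length(ids))))
  if (length(ids) == 1L) mean_bonds <- matrix(mean_bonds, ncol = 1L)
  accepted <- which(apply(mean_bonds >= min_mean_bonds, 1L, all))
  structure(accepted, mean_bonds = mean_bonds)
}

#' Convert simulation steps to physical time
#'
#' One oxDNA reduced time unit is 3.03 ps, so a step of `dt` reduced units
#' is `dt * 3030` fs: at the standard `dt = 0.003`, a step is 9.09 fs, and
#' 1e9 steps correspond to 9.09 us by direct unit conversion.
#'
#' @param dt_sim_units integration step in reduced units (default 0.003).
#' @param steps number of simulation steps.
#' @param time_unit_ps physical duration of one reduced time unit
#'   (default 3.03 ps).
#' @return list with `timestep_fs` and `total_time_us`.
#' @examples
#' convert_time(steps = 1e9)   # 9.09 fs, 9.09 us
#' @export
convert_time <- function(dt_sim_units = 0.003, steps = 0,
                         time_unit_ps = 3.03) {
  check_positive(dt_sim_units)
  check_nonneg(steps)
  timestep_fs <- dt_sim_units * time_unit_ps * 1000
  list(timestep_fs = timestep_fs,
       total_time_us = steps * timestep_fs * 1e-9)
}

#' Layer centroids of one frame
#'
#' @param pos n x 3 position matrix.
#' @param layer_map layer index (1-based) per nucleotide, covering all rows.
#' @return matrix with one centroid row per layer, in layer order.
#' @export
layer_centroids <- function(pos, layer_map) {
  if (length(layer_map) != nrow(pos))
    stop("layer map must cover all nucleotides", call. = FALSE)
  layers <- sort(unique(layer_map))
  counts <- tabulate(match(layer_map, layers))
  if (any(counts == 0L)) stop("empty layer", call. = FALSE)
  out <- rowsum(pos, group = layer_map, reorder = TRUE) / counts
  rownames(out) <- NULL
  out
}

#' Layer centroids of every frame of a trajectory
#'
#' @param trajectory frames (as accepted by [align_and_mean()]).
#' @param layer_map layer index per nucleotide; taken from the assembly for
#'   a `nanotube_trajectory`.
#' @return list of per-frame centroid matrices (input to
#'   [per_frame_persistence()]).
#' @export
trajectory_layer_centroids <- function(trajectory, layer_map = NULL) {
  if (is.null(layer_map)) {
    if (inherits(trajectory, "nanotube_trajectory"))
      layer_map <- trajectory$assembly$layer_map
    else stop("`layer_map` required", call. = FALSE)
  }
  lapply(frame_positions(trajectory), layer_centroids, layer_map = layer_map)
}
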