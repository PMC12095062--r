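## Synthetic coarse-grained nanotube trajectories: the tube axis fluctuates
## as a discrete worm-like chain of layer centroids, nucleotides rigidly
## decorate each layer, and designed bonds can break stochastically.  Output
## is written in the classic oxDNA text dialect with step indices in the
## frame headers.

## rotate layer-local coordinates into the frame whose z axis is `tangent`
layer_rotation <- function(tangent) {
  t <- unit3(tangent)
  fr <- frame_about(t)
  cbind(fr$e1, fr$e2, t)   # columns: new x, y, z
}

#' Generate a synthetic nanotube trajectory
#'
#' Each frame draws an independent worm-like-chain realization of the tube
#' axis (segment length = layer rise, persistence length `bend_P_nm`),
#' decorates every layer rigidly with the assembly's nucleotides (local
#' frames parallel-transported along the axis), optionally adds isotropic
#' Gaussian jitter per nucleotide, and optionally breaks designed bonds:
#' each registry pair is broken independently per frame with probability
#' `bond_break_rate`, displacing the `j` partner by `break_offset_nm`.
#' With `frozen = TRUE` (zero-temperature switch) every frame is the ideal
#' straight assembly.
#'
#' @param assembly a [build_tile_assembly()] result.
#' @param bend_P_nm bending persistence length of the tube axis, nm.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @param save_every_steps saving cadence; frame k carries step index
#'   `k * save_every_steps` (default 5e5).
#' @param jitter_sd_nm per-nucleotide isotropic positional noise, nm.
#' @param bond_break_rate per-frame probability that a designed pair is
#'   broken (default 0).
#' @param break_offset_nm displacement applied to broken partners, nm; the
#'   default comfortably exceeds [default_bond_cutoff()] for the default
#'   tile geometry.
#' @param frozen zero-temperature switch: all frames identical and straight.
#' @param dir,basename when `dir` is non-`NULL`, write `<basename>.top` and
#'   `<basename>.dat` there (positions in oxDNA simulation units).
#' @return object of class `nanotube_trajectory`: list with `frames`
#'   (positions in nm per frame), `steps`, `axis_truth` (per-frame true
#'   layer-axis points, nm), `broken` (per-frame integer vectors of broken
#'   registry rows), `assembly`, and `paths` (files written, or `NULL`).
#' @export
generate_nanotube_trajectory <- function(assembly, bend_P_nm, n_frames, seed,
                                         save_every_steps = 5e5,
                                         jitter_sd_nm = 0,
                                         bond_break_rate = 0,
                                         break_offset_nm = 12,
                                         frozen = FALSE,
                                         dir = NULL, basename = "nanotube") {
  stopifnot(inherits(assembly, "tile_assembly"))
  check_positive(bend_P_nm)
  n_frames <- check_count(n_frames)
  check_nonneg(jitter_sd_nm)
  stopifnot(bond_break_rate >= 0, bond_break_rate <= 1)
  spec <- assembly$spec
  nl <- spec$n_layers
  rise <- spec$layer_rise_nm
  ## layer-local nucleotide coordinates relative to the ideal layer axis
  ## point (the straight assembly's axis is x = y = 0)
  axis0 <- cbind(0, 0, (seq_len(nl) - 1L) * rise)
  local <- assembly$positions_nm
  local[, 3L] <- local[, 3L] - axis0[assembly$layer_map, 3L]

  frames <- vector("list", n_frames)
  axis_truth <- vector("list", n_frames)
  broken <- vector("list", n_frames)
  reg <- assembly$registry
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      if (frozen) {
        axis <- axis0
        pos <- assembly$positions_nm
        broken[[f]] <- integer(0)
      } else {
        axis <- sample_chain_points(bend_P_nm, nl * rise, rise, 3L)[seq_len(nl), , drop = FALSE]
        ## per-layer tangents (parallel transport of the layer frames)
        pos <- matrix(0, nrow(local), 3L)
        for (l in seq_len(nl)) {
          tang <- if (l == 1L) axis[2L, ] - axis[1L, ]
          else if (l == nl) axis[nl, ] - axis[nl - 1L, ]
          else axis[l + 1L, ] - axis[l - 1L, ]
          R <- layer_rotation(tang)
          sl <- which(assembly$layer_map == l)
          pos[sl, ] <- local[sl, , drop = FALSE] %*% t(R) +
            matrix(axis[l, ], length(sl), 3L, byrow = TRUE)
        }
        if (jitter_sd_nm > 0)
          pos <- pos + matrix(rnorm(length(pos), 0, jitter_sd_nm), nrow(pos))
        if (bond_break_rate > 0) {
          hit <- which(runif(nrow(reg)) < bond_break_rate)
          broken[[f]] <- hit
          if (length(hit)) {
            jj <- reg$j[hit] + 1L
            off <- pos[jj, , drop = FALSE] - axis[assembly$layer_map[jj], , drop = FALSE]
            nrm <- sqrt(rowSums(off^2)); nrm[nrm == 0] <- 1
            pos[jj, ] <- pos[jj, ] + off / nrm * break_offset_nm
          }
        } else broken[[f]] <- integer(0)
      }
      frames[[f]] <- pos
      axis_truth[[f]] <- axis
    }
  })
  steps <- save_every_steps * seq_len(n_frames)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    top_path <- file.path(dir, paste0(basename, ".top"))
    dat_path <- file.path(dir, paste0(basename, ".dat"))
    write_oxdna_topology(assembly$topology, top_path)
    box <- rep(2 * max(abs(unlist(frames))) / oxdna_length_nm + 10, 3L)
    con <- file(dat_path, open = "w")
    for (f in seq_len(n_frames))
      write_oxdna_configuration(con, steps[f], frames[[f]] / oxdna_length_nm,
                                assembly$base_vectors,
                                assembly$normal_vectors, box = box)
    close(con)
    paths <- c(topology = top_path, trajectory = dat_path)
  }
  structure(list(
    frames = frames, steps = steps, axis_truth = axis_truth, broken = broken,
    assembly = assembly, bend_P_nm = bend_P_nm,
    save_every_steps = save_every_steps, paths = paths
  ), class = "nanotube_trajectory")
}

#' @export
print.nanotube_trajectory <- function(x, ...) {
  cat(sprintf("<nanotube_trajectory> %d frames, %d nt, bend P = %g nm\n",
              length(x$frames), x$assembly$n_nucleotides, x$bend_P_nm))
  invisible(x)
}
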