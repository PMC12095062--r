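## Filament tracing: topology-preserving thinning of binary masks, skeleton
## graphs with sqrt(2)-weighted diagonal steps, longest-path resolution of
## branches, and calibrated measurements.
##
## Conventions: pixel coordinates in results are 0-based (row, col) with the
## y-down image convention; physical lengths are nm.

## shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs + dr, cs + dc] <- m[rs, cs, drop = FALSE]
  out
}

## neighbour order p2..p9 (N, NE, E, SE, S, SW, W, NW) in (dr, dc);
## "north" = decreasing row
zs_offsets <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                   c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Skeletonize a binary mask
#'
#' Zhang--Suen thinning: iterative two-subpass deletion of contour pixels
#' until stable, preserving 8-connectivity.  A mask that is already one
#' pixel wide is returned unchanged; an empty mask yields an empty graph.
#'
#' @param mask logical (or 0/1) matrix.
#' @return a `skeleton_graph`: list with `pixels` (data.frame `row`, `col`,
#'   0-based), `edges` (data.frame `from`, `to`, `weight`; weights 1 for
#'   axial and `sqrt(2)` for diagonal steps), `component` (integer label per
#'   pixel), `n_components`, `skeleton` (logical matrix) and `dims`.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask > 0
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- lapply(zs_offsets, function(o) shift_mat(m, -o[1L], -o[2L]))
      B <- Reduce(`+`, nb)
      ## A = number of 0->1 transitions around the ring p2..p9,p2
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8L) 1L else i + 1L
        A <- A + (!nb[[i]] & nb[[j]])
      }
      if (pass == 1L)
        conds <- !(nb[[1L]] & nb[[3L]] & nb[[5L]]) & !(nb[[3L]] & nb[[5L]] & nb[[7L]])
      else
        conds <- !(nb[[1L]] & nb[[3L]] & nb[[7L]]) & !(nb[[1L]] & nb[[5L]] & nb[[7L]])
      del <- m & B >= 2 & B <= 6 & A == 1L & conds
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skeleton_graph_from_matrix(m)
}

## build the weighted 8-connectivity graph of skeleton pixels
skeleton_graph_from_matrix <- function(skel) {
  idx <- which(skel)
  dims <- dim(skel)
  if (length(idx) == 0L) {
    return(structure(list(
      pixels = data.frame(row = integer(), col = integer()),
      edges = data.frame(from = integer(), to = integer(), weight = numeric()),
      component = integer(), n_components = 0L,
      skeleton = skel, dims = dims), class = "skeleton_graph"))
  }
  r <- ((idx - 1L) %% dims[1L]) + 1L
  c <- ((idx - 1L) %/% dims[1L]) + 1L
  id <- matrix(0L, dims[1L], dims[2L])
  id[idx] <- seq_along(idx)
  ef <- et <- integer(0); ew <- numeric(0); er <- logical(0)
  at <- function(rr, cc) {
    ok <- rr >= 1L & rr <= dims[1L] & cc >= 1L & cc <= dims[2L]
    ok[ok] <- skel[cbind(rr[ok], cc[ok])]
    ok
  }
  for (o in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    rr <- r + o[1L]; cc <- c + o[2L]
    ok <- at(rr, cc)
    diag <- all(o != 0L)
    ## diagonal steps that shortcut a staircase corner stay in the graph:
    ## chain-code paths through digitized curves rely on them, but they are
    ## marked so cycle traversal can ignore them
    redundant <- if (diag) at(r + o[1L], c) | at(r, c + o[2L]) else rep(FALSE, length(ok))
    if (!any(ok)) next
    ef <- c(ef, id[cbind(r[ok], c[ok])])
    et <- c(et, id[cbind(rr[ok], cc[ok])])
    ew <- c(ew, rep(if (diag) sqrt(2) else 1, sum(ok)))
    er <- c(er, redundant[ok])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et),
    directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  g <- igraph::set_edge_attr(g, "weight", value = ew)
  g <- igraph::set_edge_attr(g, "corner_shortcut", value = er)
  comp <- igraph::components(g)
  structure(list(
    pixels = data.frame(row = r - 1L, col = c - 1L),
    edges = data.frame(from = ef, to = et, weight = ew),
    component = as.integer(comp$membership),
    n_components = comp$no,
    skeleton = skel, dims = dims,
    graph = g
  ), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph>", nrow(x$pixels), "pixels,", nrow(x$edges), "edges,",
      x$n_components, "component(s)\n")
  invisible(x)
}

## lexicographic order key of a 0-based pixel
pix_key <- function(px, dims) px[, 1L] * dims[2L] + px[, 2L]

#' Trace the longest path of each skeleton component
#'
#' For branched components the returned path is the weighted-longest
#' leaf-to-leaf path (exact search over all leaf pairs, path weights 1 and
#' `sqrt(2)`); ties are broken towards the lexicographically smallest
#' (row, col) endpoint.  Pure cycles (no leaves) are traversed starting at
#' the lexicographically smallest pixel, covering the cycle up to its final
#' closing step.  A single-pixel component yields a zero-length path flagged
#' `degenerate` for downstream rejection.
#'
#' @param graph a `skeleton_graph` from [skeletonize_mask()].
#' @return list with one element per component (in component order): a
#'   matrix of 0-based (row, col) pixels in path order, with attributes
#'   `length_px` (weighted length), `is_cycle` and `degenerate`.
#' @export
trace_longest_path <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  lapply(seq_len(graph$n_components), function(k) {
    vk <- which(graph$component == k)
    trace_component(graph, vk)
  })
}

trace_component <- function(graph, vk) {
  px <- as.matrix(graph$pixels[vk, , drop = FALSE])
  if (length(vk) == 1L) {
    out <- px
    attr(out, "length_px") <- 0
    attr(out, "is_cycle") <- FALSE
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sub <- igraph::induced_subgraph(graph$graph, vk)
  deg <- igraph::degree(sub)
  keys <- pix_key(px, graph$dims)
  finish <- function(vpath, is_cycle, len) {
    out <- px[vpath, , drop = FALSE]
    ## orient deterministically: start at the lexicographically smaller end
    if (keys[vpath[1L]] > keys[vpath[length(vpath)]])
      out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    attr(out, "length_px") <- len
    attr(out, "is_cycle") <- is_cycle
    attr(out, "degenerate") <- FALSE
    out
  }
  leaves <- which(deg == 1L)
  if (length(leaves) >= 2L) {
    d <- igraph::distances(sub, v = leaves, to = leaves)
    best <- which(d == max(d), arr.ind = TRUE)
    ## tie-break: smallest endpoint key, then smallest other end
    ord <- order(pmin(keys[leaves[best[, 1L]]], keys[leaves[best[, 2L]]]),
                 pmax(keys[leaves[best[, 1L]]], keys[leaves[best[, 2L]]]))
    b <- best[ord[1L], ]
    sp <- igraph::shortest_paths(sub, from = leaves[b[1L]], to = leaves[b[2L]],
                                 output = "vpath")$vpath[[1L]]
    return(finish(as.integer(sp), FALSE, max(d)))
  }
  if (length(leaves) == 1L) {
    d <- igraph::distances(sub, v = leaves)
    far <- which.max(d)
    sp <- igraph::shortest_paths(sub, from = leaves, to = far,
                                 output = "vpath")$vpath[[1L]]
    return(finish(as.integer(sp), FALSE, max(d)))
  }
  ## no leaves: cycle traversal from the lexicographically smallest pixel.
  ## Corner-shortcut diagonals are dropped first so the cycle is chordless
  ## and deleting one edge forces the long way around.
  ring <- igraph::delete_edges(
    sub, which(igraph::edge_attr(sub, "corner_shortcut")))
  v0 <- which.min(keys)
  nb <- as.integer(igraph::neighbors(ring, v0))
  u <- nb[which.min(keys[nb])]
  eid <- igraph::get_edge_ids(ring, c(v0, u))
  w_vu <- igraph::edge_attr(ring, "weight", eid)
  cut <- igraph::delete_edges(ring, eid)
  sp <- igraph::shortest_paths(cut, from = v0, to = u, output = "vpath")$vpath[[1L]]
  len <- igraph::distances(cut, v = v0, to = u)[1L, 1L]
  finish(as.integer(sp), TRUE, len + w_vu)
}

## chain-code step-length estimators for digitized curves: "freeman" weights
## axial steps 1 and diagonal steps sqrt(2); "kulpa" rescales both by 0.9481,
## removing the mean overestimation of digitized straight segments.
kulpa_factor <- 0.9481

chain_code_length <- function(path, estimator = c("freeman", "kulpa")) {
  estimator <- match.arg(estimator)
  if (nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  if (any(d > 1L))
    stop("path pixels must be 8-adjacent", call. = FALSE)
  diag <- d[, 1L] == 1L & d[, 2L] == 1L
  len <- sum(!diag) + sqrt(2) * sum(diag)
  if (estimator == "kulpa") len <- kulpa_factor * len
  len
}

#' Measure a traced filament path
#'
#' Contour length is the weighted chain-code length of the pixel path
#' (axial steps 1 px, diagonal steps `sqrt(2)` px) times the pixel size;
#' `estimator = "kulpa"` applies the Kulpa correction factor 0.9481, which
#' removes the systematic overestimation of digitized straight segments
#' (about +5.5% averaged over orientations for the plain weights).
#' End-to-end distance is the Euclidean distance between the path endpoints.
#'
#' @param path matrix of 0-based (row, col) pixels, consecutive rows
#'   8-adjacent (as returned by [trace_longest_path()]).
#' @param pixel_size_nm lateral calibration, nm per pixel.
#' @param estimator `"freeman"` (plain 1 / sqrt(2) weights, default) or
#'   `"kulpa"`.
#' @return object of class `filament_trace`: list with `ordered_path`,
#'   `pixel_size_nm`, `contour_length_nm`, `end_to_end_nm`, `n_pixels`,
#'   `estimator`, `is_cycle`.
#' @examples
#' path <- cbind(0L, 0:100)              # horizontal, 101 px
#' measure_filament(path, 4)$contour_length_nm   # 400 nm
#' @export
measure_filament <- function(path, pixel_size_nm, estimator = c("freeman", "kulpa")) {
  estimator <- match.arg(estimator)
  check_positive(pixel_size_nm)
  if (is.null(dim(path)) || nrow(path) < 2L)
    stop("path must contain at least 2 pixels", call. = FALSE)
  if (anyDuplicated(path))
    stop("path pixels must be pairwise distinct", call. = FALSE)
  contour <- chain_code_length(path, estimator) * pixel_size_nm
  ee <- sqrt(sum((path[nrow(path), ] - path[1L, ])^2)) * pixel_size_nm
  structure(list(
    ordered_path = path,
    pixel_size_nm = pixel_size_nm,
    contour_length_nm = contour,
    end_to_end_nm = ee,
    n_pixels = nrow(path),
    estimator = estimator,
    is_cycle = isTRUE(attr(path, "is_cycle"))
  ), class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("<filament_trace> %d px, contour %.1f nm, end-to-end %.1f nm (%s)\n",
              x$n_pixels, x$contour_length_nm, x$end_to_end_nm, x$estimator))
  invisible(x)
}

#' Trace and measure every filament in a binary mask
#'
#' Convenience wrapper: thin the mask, trace the longest path per connected
#' component, and measure each.  Components flagged as cycles are dropped by
#' default (`exclude_cycles`), as are paths shorter than `min_pixels`.
#'
#' @param mask logical matrix (from the generator or from thresholding).
#' @param pixel_size_nm nm per pixel.
#' @param estimator passed to [measure_filament()].
#' @param min_pixels minimum path length in pixels.
#' @param exclude_cycles drop closed-ring detections from the output.
#' @return data.frame with one row per retained filament: `id`,
#'   `contour_nm`, `end_to_end_nm`, `n_pixels`, `is_cycle`; the traces
#'   themselves are attached as attribute `"traces"`.
#' @export
trace_mask <- function(mask, pixel_size_nm, estimator = c("freeman", "kulpa"),
                       min_pixels = 2L, exclude_cycles = TRUE) {
  estimator <- match.arg(estimator)
  graph <- skeletonize_mask(mask)
  paths <- trace_longest_path(graph)
  traces <- list()
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (isTRUE(attr(p, "degenerate")) || nrow(p) < min_pixels) next
    if (exclude_cycles && isTRUE(attr(p, "is_cycle"))) next
    tr <- measure_filament(p, pixel_size_nm, estimator)
    traces[[length(traces) + 1L]] <- tr
    rows[[length(rows) + 1L]] <- data.frame(
      id = i, contour_nm = tr$contour_length_nm,
      end_to_end_nm = tr$end_to_end_nm, n_pixels = tr$n_pixels,
      is_cycle = tr$is_cycle)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(id = integer(), contour_nm = numeric(),
                  end_to_end_nm = numeric(), n_pixels = integer(),
                  is_cycle = logical())
  attr(out, "traces") <- traces
  out
}

## bilinear interpolation of a matrix at fractional 0-based (row, col)
bilinear_at <- function(img, r, c) {
  r <- r + 1; c <- c + 1
  r0 <- pmax(1L, pmin(nrow(img) - 1L, floor(r))); c0 <- pmax(1L, pmin(ncol(img) - 1L, floor(c)))
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Height and width profile across a traced filament
#'
#' Samples the intensity profile perpendicular to the path at regularly
#' spaced points.  At each point the local background is the median of the
#' outer quarter of the profile, the height is the profile peak minus the
#' background, and the width is the full width at half maximum (linear
#' interpolation of the half-height crossings).  The medians over sampled
#' points are reported; points without a resolvable ridge (height below
#' `min_height_nm`) are flagged and excluded from the medians.
#'
#' @param height_img height image (nm) the trace was derived from.
#' @param trace a `filament_trace` (or 0-based pixel path matrix).
#' @param pixel_size_nm nm per pixel.
#' @param spacing_px distance between sampled path points, px.
#' @param half_width_px half-extent of the perpendicular profile, px.
#' @param min_height_nm ridge detection threshold, nm.
#' @return list with `height_nm`, `width_fwhm_nm` (medians; `NA` if no point
#'   had a ridge), `n_points`, `n_flagged`, and the per-point data.frame
#'   `profile`.
#' @export
cross_section_profile <- function(height_img, trace, pixel_size_nm,
                                  spacing_px = 4L, half_width_px = 10L,
                                  min_height_nm = 0.5) {
  path <- if (inherits(trace, "filament_trace")) trace$ordered_path else trace
  if (nrow(path) <= spacing_px)
    stop("trace shorter than the sampling spacing", call. = FALSE)
  idx <- seq(1L + spacing_px, nrow(path) - spacing_px, by = spacing_px)
  offs <- seq(-half_width_px, half_width_px, by = 0.5)
  rows <- lapply(idx, function(i) {
    tang <- path[min(nrow(path), i + spacing_px), ] - path[max(1L, i - spacing_px), ]
    tl <- sqrt(sum(tang^2)); if (tl == 0) return(NULL)
    nrm <- c(-tang[2L], tang[1L]) / tl
    rr <- path[i, 1L] + offs * nrm[1L]
    cc <- path[i, 2L] + offs * nrm[2L]
    ok <- rr >= 0 & rr <= nrow(height_img) - 1L & cc >= 0 & cc <= ncol(height_img) - 1L
    if (sum(ok) < length(offs) * 0.8) return(NULL)
    prof <- bilinear_at(height_img, rr[ok], cc[ok])
    outer_q <- c(head(prof, ceiling(length(prof) / 8)),
                 tail(prof, ceiling(length(prof) / 8)))
    bg <- median(outer_q)
    pk <- which.max(prof)
    h <- prof[pk] - bg
    if (h < min_height_nm)
      return(data.frame(height_nm = h, width_fwhm_nm = NA_real_, flagged = TRUE))
    half <- bg + h / 2
    above <- prof >= half
    lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- pk; while (hi < length(prof) && above[hi + 1L]) hi <- hi + 1L
    x <- offs[ok] * pixel_size_nm
    xl <- if (lo > 1L)
      x[lo - 1L] + (x[lo] - x[lo - 1L]) * (half - prof[lo - 1L]) / (prof[lo] - prof[lo - 1L])
    else x[lo]
    xr <- if (hi < length(prof))
      x[hi] + (x[hi + 1L] - x[hi]) * (half - prof[hi]) / (prof[hi + 1L] - prof[hi])
    else x[hi]
    data.frame(height_nm = h, width_fwhm_nm = xr - xl, flagged = FALSE)
  })
  prof <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(prof) || nrow(prof) == 0L)
    stop("no usable profile points along the trace", call. = FALSE)
  ok <- !prof$flagged
  list(height_nm = if (any(ok)) median(prof$height_nm[ok]) else NA_real_,
       width_fwhm_nm = if (any(ok)) median(prof$width_fwhm_nm[ok]) else NA_real_,
       n_points = nrow(prof), n_flagged = sum(prof$flagged), profile = prof)
}

#' Outer and inner radius of a ring-like mask component
#'
#' Radii are half the maximum Feret (caliper) diameter, computed on the
#' convex hull of pixel centres plus one pixel of extent; the inner radius
#' uses the enclosed hole (0 if the component has no hole).
#'
#' @param mask logical matrix containing a single connected component.
#' @param pixel_size_nm nm per pixel.
#' @return list with `outer_radius_nm` and `inner_radius_nm`.
#' @export
ring_metrics <- function(mask, pixel_size_nm = 1) {
  m <- mask > 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  lab <- EBImage::bwlabel(m)
  if (max(lab) != 1L)
    stop("mask must contain exactly one connected component", call. = FALSE)
  feret_px <- function(mm) {
    idx <- which(mm)
    r <- ((idx - 1L) %% nrow(mm)); c <- ((idx - 1L) %/% nrow(mm))
    pts <- cbind(r, c)
    if (nrow(pts) == 1L) return(1)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    d2 <- as.matrix(stats::dist(hull))
    max(d2) + 1
  }
  outer <- feret_px(m) / 2 * pixel_size_nm
  filled <- EBImage::fillHull(m * 1) > 0
  hole <- filled & !m
  inner <- if (any(hole)) feret_px(hole) / 2 * pixel_size_nm else 0
  list(outer_radius_nm = outer, inner_radius_nm = inner)
}
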