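## Idealized geometry of RNA origami tiles and their cylindrical-lattice
## assembly into nanotubes, with the designed-bond registry (intra-tile
## stems, internal kissing loops, and corner-to-corner external kissing
## loops between layers).

#' Geometry of a nanotube-forming RNA origami tile
#'
#' The tile folds into `n_duplexes` parallel duplexes with an intrinsic
#' curvature `alpha` between the outer duplexes; `tiles_per_layer * alpha`
#' must close a full ring (e.g. 3 tiles at 120 degrees).  External kissing
#' loops sit at the labelled corners and pair corner-to-corner only:
#' a with a' and b with b'.
#'
#' @param n_duplexes duplexes per tile (default 3).
#' @param intrinsic_curvature_deg intrinsic curvature alpha, degrees.
#' @param tile_dims_nm tile bounding dimensions (length, width, height), nm.
#' @param connectors corner labels.
#' @return object of class `tile_geometry`.
#' @export
tile_geometry <- function(n_duplexes = 3L, intrinsic_curvature_deg = 120,
                          tile_dims_nm = c(11, 5, 2.5),
                          connectors = c("a", "b", "a'", "b'")) {
  structure(list(
    n_duplexes = check_count(n_duplexes),
    intrinsic_curvature_deg = check_positive(intrinsic_curvature_deg),
    tile_dims_nm = tile_dims_nm,
    connectors = connectors
  ), class = "tile_geometry")
}

#' Specification of a nanotube assembly
#'
#' @param n_layers number of tile layers along the tube axis.
#' @param tiles_per_layer tiles closing one ring (default 3).
#' @param nt_per_tile nucleotides per tile; must be a multiple of 6 (two
#'   strand segments per duplex) and at least 72 so that every kissing loop
#'   can hold its 12 designed bonds.  The default 300 makes a 100-layer
#'   assembly 90,000 nucleotides.
#' @param layer_rise_nm axial rise per layer, nm (default 11: the tile
#'   length runs along the axis, so 100 layers span about 1.1 um).
#' @param outer_diameter_nm tube outer diameter, nm (default 11).
#' @param seed integer seed (used by stochastic consumers of the spec).
#' @return object of class `assembly_spec`.
#' @export
assembly_spec <- function(n_layers, tiles_per_layer = 3L, nt_per_tile = 300L,
                          layer_rise_nm = 11, outer_diameter_nm = 11,
                          seed = 1L) {
  nt_per_tile <- check_count(nt_per_tile, min = 72L)
  if (nt_per_tile %% 6L != 0L)
    stop("`nt_per_tile` must be a multiple of 6", call. = FALSE)
  structure(list(
    n_layers = check_count(n_layers),
    tiles_per_layer = check_count(tiles_per_layer),
    nt_per_tile = nt_per_tile,
    layer_rise_nm = check_positive(layer_rise_nm),
    outer_diameter_nm = check_positive(outer_diameter_nm),
    seed = seed
  ), class = "assembly_spec")
}

#' Build an idealized nanotube assembly
#'
#' Places `n_layers * tiles_per_layer` tiles on a cylindrical lattice.  Each
#' tile occupies an `alpha`-degree azimuthal patch of the tube wall and the
#' full layer rise in z; its three duplexes (two antiparallel strand
#' segments each, radially offset by 1 nm) run along the tube axis in a
#' serpentine single-strand routing.  The designed-bond registry records:
#'
#' * `stem` pairs -- base pairs between the two segments of each duplex;
#' * `internal_KL` -- two kissing loops of 12 designed bonds each per tile,
#'   joining neighbouring duplexes; the first carries the region label
#'   `"stem_loop"` (the mid-helix stem-loop tracked in bond-occupancy
#'   comparisons), the second `"internal_KL_2"`;
#' * `external_KL` -- the corner-to-corner pairs a--a' and b--b' joining
#'   each tile to the tile directly above (2 per tile per layer interface,
#'   regions `"corner_a"` / `"corner_b"`).
#'
#' All designed partners are spatially adjacent in the ideal geometry (see
#' [default_bond_cutoff()]).
#'
#' @param spec an [assembly_spec()].
#' @param geom a [tile_geometry()].
#' @return object of class `tile_assembly`: `positions_nm` (n x 3), unit
#'   `base_vectors` and `normal_vectors`, `topology` (data.frame per
#'   nucleotide: `strand`, `base`, `neighbor3`, `neighbor5`; 0-based
#'   indices, -1 for termini), `registry` (data.frame: `i`, `j`, `category`,
#'   `region`, `kl_id`; 0-based), `layer_map` (layer per nucleotide,
#'   1-based), `tile_map`, `spec`, `geom`.
#' @examples
#' asm <- build_tile_assembly(assembly_spec(2, nt_per_tile = 72))
#' nrow(asm$positions_nm)   # 2 layers x 3 tiles x 72 nt
#' @export
build_tile_assembly <- function(spec, geom = tile_geometry()) {
  stopifnot(inherits(spec, "assembly_spec"), inherits(geom, "tile_geometry"))
  if (abs(spec$tiles_per_layer * geom$intrinsic_curvature_deg - 360) > 1e-9)
    stop("tiles_per_layer x intrinsic curvature must equal 360 degrees",
         call. = FALSE)
  nl <- spec$n_layers; tpl <- spec$tiles_per_layer; npt <- spec$nt_per_tile
  n_tiles <- nl * tpl
  n_nt <- n_tiles * npt
  radius <- spec$outer_diameter_nm / 2
  alpha <- geom$intrinsic_curvature_deg * pi / 180
  ps <- npt %/% 6L                      # positions per strand segment
  zspan <- spec$layer_rise_nm - 1       # 1 nm gap at each layer interface

  ## within-tile layout, identical for every tile:
  ## segment 0..5, duplex = seg %/% 2, side = seg %% 2;
  ## odd segments run backwards in z (serpentine / antiparallel pairing)
  k <- seq_len(npt) - 1L
  seg <- k %/% ps
  q <- k %% ps
  dupx <- seg %/% 2L
  side <- seg %% 2L
  zfrac <- ifelse(seg %% 2L == 0L, q, ps - 1L - q) / (ps - 1L)
  phi_off <- (0.15 + 0.35 * dupx) * alpha
  r_nt <- radius - 1 * side
  z_nt <- (zfrac - 0.5) * zspan

  pos <- matrix(0, n_nt, 3L)
  bvec <- matrix(0, n_nt, 3L)
  nvec <- matrix(0, n_nt, 3L)
  layer_map <- integer(n_nt)
  tile_map <- integer(n_nt)
  idx <- 0L
  for (l in seq_len(nl)) {
    zc <- (l - 1L) * spec$layer_rise_nm
    for (p in seq_len(tpl)) {
      phi <- (p - 1L) * alpha + phi_off
      sl <- idx + seq_len(npt)
      pos[sl, ] <- cbind(r_nt * cos(phi), r_nt * sin(phi), zc + z_nt)
      bvec[sl, ] <- cbind(-cos(phi), -sin(phi), 0)   # bases point inwards
      nvec[sl, ] <- matrix(c(0, 0, 1), npt, 3L, byrow = TRUE)
      layer_map[sl] <- l
      tile_map[sl] <- (l - 1L) * tpl + p
      idx <- idx + npt
    }
  }

  ## topology: one single-stranded RNA molecule per tile
  within <- (seq_len(n_nt) - 1L) %% npt
  strand <- (seq_len(n_nt) - 1L) %/% npt + 1L
  n3 <- ifelse(within == 0L, -1L, seq_len(n_nt) - 2L)
  n5 <- ifelse(within == npt - 1L, -1L, seq_len(n_nt))
  bases <- c("A", "C", "G", "U")[(seq_len(n_nt) - 1L) %% 4L + 1L]
  topo <- data.frame(strand = strand, base = bases,
                     neighbor3 = n3, neighbor5 = n5)

  registry <- build_bond_registry(nl, tpl, npt, ps)
  structure(list(
    positions_nm = pos, base_vectors = bvec, normal_vectors = nvec,
    topology = topo, registry = registry,
    layer_map = layer_map, tile_map = tile_map,
    spec = spec, geom = geom,
    n_tiles = n_tiles, n_nucleotides = n_nt
  ), class = "tile_assembly")
}

## designed-bond registry (0-based nucleotide indices); ps = positions per
## strand segment.  Pairings follow the serpentine layout of
## build_tile_assembly so that partners share the same z within a tile.
## Index windows (stems at q = 2.., kissing loops centred, corners at the
## segment ends) are chosen so that for ps >= 32 (nt_per_tile >= 192) no
## nucleotide belongs to two designed pairs, which makes stochastic
## bond-breaking exactly pair-local; smaller tiles may share nucleotides
## between pairs.
build_bond_registry <- function(nl, tpl, npt, ps) {
  kl_size <- 12L
  stem_n <- min(8L, max(2L, ps %/% 4L))
  rows <- list()
  tile_base <- function(l, p) ((l - 1L) * tpl + (p - 1L)) * npt
  kl_id <- 0L
  mid <- (ps - kl_size) %/% 2L
  qs <- 1L + seq_len(stem_n)            # stem window q = 2..stem_n+1
  qk <- mid + seq_len(kl_size) - 1L     # kissing-loop window
  for (l in seq_len(nl)) for (p in seq_len(tpl)) {
    b <- tile_base(l, p)
    for (d in 0:2) rows[[length(rows) + 1L]] <- data.frame(
      i = b + 2L * d * ps + qs,
      j = b + (2L * d + 1L) * ps + (ps - 1L - qs),
      category = "stem", region = sprintf("stem_d%d", d),
      kl_id = NA_integer_)
    kl_id <- kl_id + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      i = b + ps + qk,
      j = b + 2L * ps + (ps - 1L - qk),
      category = "internal_KL", region = "stem_loop", kl_id = kl_id)
    kl_id <- kl_id + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      i = b + 3L * ps + qk,
      j = b + 4L * ps + (ps - 1L - qk),
      category = "internal_KL", region = "internal_KL_2", kl_id = kl_id)
  }
  ## external kissing loops: corner a = top of duplex 0, corner b = top of
  ## duplex 2; a'/b' are the matching bottoms on the tile directly above
  for (l in seq_len(nl - 1L)) for (p in seq_len(tpl)) {
    b_lo <- tile_base(l, p); b_hi <- tile_base(l + 1L, p)
    rows[[length(rows) + 1L]] <- data.frame(
      i = c(b_lo + ps - 1L, b_lo + 5L * ps - 1L),
      j = c(b_hi, b_hi + 4L * ps),
      category = "external_KL",
      region = c("corner_a", "corner_b"), kl_id = NA_integer_)
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out[, c("i", "j")]), all(out$i != out$j))
  rownames(out) <- NULL
  out
}

#' Distance cutoff that calls every designed bond bonded in the ideal
#' geometry
#'
#' The bond call used by [bond_occupancy()] is a distance criterion (an
#' engine-independent proxy for energy-based calls).  This helper returns
#' the maximum designed-pair distance of the ideal assembly plus a 0.5 nm
#' margin, so that unperturbed generator frames have occupancy 1.
#'
#' @param assembly a [build_tile_assembly()] result.
#' @return cutoff distance, nm.
#' @export
default_bond_cutoff <- function(assembly) {
  reg <- assembly$registry
  d <- sqrt(rowSums((assembly$positions_nm[reg$i + 1L, , drop = FALSE] -
                     assembly$positions_nm[reg$j + 1L, , drop = FALSE])^2))
  max(d) + 0.5
}

#' @export
print.tile_assembly <- function(x, ...) {
  cat(sprintf("<tile_assembly> %d layers x %d tiles = %d tiles, %d nt, %d designed bonds\n",
              x$spec$n_layers, x$spec$tiles_per_layer, x$n_tiles,
              x$n_nucleotides, nrow(x$registry)))
  invisible(x)
}
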