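## Reader/writer for the classic oxDNA text dialect: a topology file
## ("N_nt N_strands" header, then per-nucleotide strand / base / 3' / 5'
## neighbour) and a trajectory of configurations ("t = ...", "b = ...",
## "E = ..." header lines, then one row of position, base vector, normal
## vector and zeroed velocities per nucleotide).  Positions are in oxDNA
## simulation length units (1 unit = 0.8518 nm).

#' oxDNA length unit in nanometres
#' @format A single number, 0.8518.
#' @export
oxdna_length_nm <- 0.8518

#' Write a topology file (classic oxDNA dialect)
#'
#' @param topology data.frame with columns `strand`, `base`, `neighbor3`,
#'   `neighbor5` (0-based nucleotide indices, -1 for termini).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_oxdna_topology <- function(topology, path) {
  n <- nrow(topology)
  lines <- c(sprintf("%d %d", n, length(unique(topology$strand))),
             sprintf("%d %s %d %d", topology$strand, topology$base,
                     topology$neighbor3, topology$neighbor5))
  writeLines(lines, path)
  invisible(path)
}

#' Read a topology file (classic oxDNA dialect)
#'
#' Checks mutual consistency of the 3'/5' neighbour links.
#'
#' @param path topology file.
#' @return data.frame as for [write_oxdna_topology()], with attributes
#'   `n_nucleotides` and `n_strands`.
#' @export
read_oxdna_topology <- function(path) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1L], quiet = TRUE)
  n <- as.integer(hdr[1L]); ns <- as.integer(hdr[2L])
  if (length(lines) < n + 1L)
    stop(sprintf("topology truncated: header declares %d nucleotides, found %d (line %d)",
                 n, length(lines) - 1L, length(lines)), call. = FALSE)
  fields <- strsplit(trimws(lines[2:(n + 1L)]), "\\s+")
  topo <- data.frame(
    strand = as.integer(vapply(fields, `[`, "", 1L)),
    base = vapply(fields, `[`, "", 2L),
    neighbor3 = as.integer(vapply(fields, `[`, "", 3L)),
    neighbor5 = as.integer(vapply(fields, `[`, "", 4L)))
  if (length(unique(topo$strand)) != ns)
    stop("strand count does not match header", call. = FALSE)
  i0 <- seq_len(n) - 1L
  has5 <- topo$neighbor5 >= 0L
  if (!all(topo$neighbor3[match(topo$neighbor5[has5], i0)] == i0[has5]))
    stop("inconsistent 3'/5' neighbour links", call. = FALSE)
  attr(topo, "n_nucleotides") <- n
  attr(topo, "n_strands") <- ns
  topo
}

format_configuration <- function(t, box, energy, pos, bvec, nvec) {
  body <- sprintf(
    "%.12g %.12g %.12g %.8g %.8g %.8g %.8g %.8g %.8g 0 0 0 0 0 0",
    pos[, 1L], pos[, 2L], pos[, 3L],
    bvec[, 1L], bvec[, 2L], bvec[, 3L],
    nvec[, 1L], nvec[, 2L], nvec[, 3L])
  c(sprintf("t = %.0f", t),
    sprintf("b = %.8g %.8g %.8g", box[1L], box[2L], box[3L]),
    sprintf("E = %.6g %.6g %.6g", energy[1L], energy[2L], energy[3L]),
    body)
}

#' Append one configuration to a trajectory file
#'
#' @param con writable connection (or path, opened and closed per call).
#' @param t step index.
#' @param pos,bvec,nvec n x 3 matrices: positions (simulation units), base
#'   vectors and base-normal vectors (unit norm).
#' @param box box dimensions, simulation units.
#' @param energy three energy fields of the header (zeros by default).
#' @return invisibly, `NULL`.
#' @export
write_oxdna_configuration <- function(con, t, pos, bvec, nvec,
                                      box = c(100, 100, 100),
                                      energy = c(0, 0, 0)) {
  lines <- format_configuration(t, box, energy, pos, bvec, nvec)
  if (is.character(con)) {
    fh <- file(con, open = "a"); on.exit(close(fh))
    writeLines(lines, fh)
  } else writeLines(lines, con)
  invisible(NULL)
}

parse_frame <- function(lines, n, frame_idx) {
  if (length(lines) < n + 3L || !startsWith(lines[1L], "t"))
    stop(sprintf("trajectory frame %d is truncated or malformed", frame_idx),
         call. = FALSE)
  t <- as.numeric(sub("^t\\s*=\\s*", "", lines[1L]))
  box <- scan(text = sub("^b\\s*=\\s*", "", lines[2L]), quiet = TRUE)
  energy <- scan(text = sub("^E\\s*=\\s*", "", lines[3L]), quiet = TRUE)
  vals <- scan(text = lines[4:(n + 3L)], quiet = TRUE)
  m <- matrix(vals, nrow = n, byrow = TRUE)
  if (ncol(m) < 9L)
    stop(sprintf("trajectory frame %d has too few columns", frame_idx),
         call. = FALSE)
  list(t = t, box = box, energy = energy,
       pos = m[, 1:3, drop = FALSE],
       bvec = m[, 4:6, drop = FALSE],
       nvec = m[, 7:9, drop = FALSE])
}

#' Stream configurations from a trajectory file
#'
#' Reads one frame at a time (never holding more than one frame in memory
#' when a callback is supplied).  Frame headers carry the step index `t`.
#'
#' @param path trajectory (`.dat`) file.
#' @param topology topology data.frame (for the nucleotide count), or the
#'   count itself.
#' @param callback optional `function(frame, index)`; when supplied, frames
#'   are passed to it one by one and only `callback`'s results are kept.
#' @return list of frames (or of callback results); each frame is a list
#'   `t`, `box`, `energy`, `pos`, `bvec`, `nvec`.
#' @export
read_oxdna_trajectory <- function(path, topology, callback = NULL) {
  n <- if (is.data.frame(topology)) nrow(topology) else as.integer(topology)
  con <- file(path, open = "r")
  on.exit(close(con))
  out <- list()
  idx <- 0L
  repeat {
    lines <- readLines(con, n = n + 3L)
    if (length(lines) == 0L) break
    idx <- idx + 1L
    frame <- parse_frame(lines, n, idx)
    out[[idx]] <- if (is.null(callback)) frame else callback(frame, idx)
  }
  out
}
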