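## Independent oracles used across the suite.

## Closed-form mean squared end-to-end distance of a worm-like chain,
## written independently of the package implementation.
oracle_wlc_r2 <- function(L, P, s = 1) {
  x <- L / (s * P)
  (s * P)^2 * 2 * (x - 1 + exp(-x))
}

## Brute-force longest-of-geodesics over all leaf pairs of a skeleton
## component: Floyd-Warshall on the dense weighted adjacency (independent
## of the path search the tracer uses), then the maximum over leaf pairs.
oracle_longest_leaf_path <- function(graph, component = 1L) {
  vk <- which(graph$component == component)
  n <- length(vk)
  if (n < 2L) return(NA_real_)
  idx <- setNames(seq_len(n), vk)
  D <- matrix(Inf, n, n); diag(D) <- 0
  deg <- integer(n)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    a <- idx[as.character(e$from[k])]; b <- idx[as.character(e$to[k])]
    if (is.na(a) || is.na(b)) next
    D[a, b] <- D[b, a] <- min(D[a, b], e$weight[k])
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
  }
  for (m in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n))
    if (D[a, m] + D[m, b] < D[a, b]) D[a, b] <- D[a, m] + D[m, b]
  leaves <- which(deg == 1L)
  if (length(leaves) < 2L) return(NA_real_)
  max(D[leaves, leaves])
}

## Two-tailed Welch p-value by numeric integration of the t density.
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

## Ramanujan's second approximation of the ellipse perimeter (error far
## below the tolerances it is used at).
oracle_ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

## Bresenham-style digital straight segment as a 0-based pixel path
## (one pixel per major-axis step, the standard 8-connected digitization).
digital_segment <- function(length_px, angle_deg) {
  th <- angle_deg * pi / 180
  if (angle_deg <= 45) {
    m <- round(length_px * cos(th))
    cbind(0:m, round((0:m) * tan(th)))
  } else {
    m <- round(length_px * sin(th))
    cbind(round((0:m) / tan(th)), 0:m)
  }
}

## Filled disc mask of radius r centred in a (2r + 2m + 1)^2 image.
disc_mask <- function(r, margin = 5L) {
  n <- 2L * (r + margin) + 1L
  ctr <- r + margin + 1L
  m <- matrix(FALSE, n, n)
  (row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2
}

## A vector with exact sample mean m and sample s.d. s (n = 4).
group_with_moments <- function(m, s) {
  v <- c(-1.5, -0.5, 0.5, 1.5)
  m + s * v / sd(v)
}
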