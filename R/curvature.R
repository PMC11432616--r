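#' Outer and inner curvature-line lengths from an isoline stack
#'
#' Reconstructs the maximum-length (outer curvature) and minimum-length
#' (inner curvature) wall paths of a bent vessel segment. Every isoline (and
#' optionally the inlet/outlet boundary rings as first and last layers) is
#' resampled to `samples_per_contour` nodes equally spaced in arc length,
#' consecutive layers are brought into angular correspondence (consistent
#' orientation, then the cyclic shift minimizing the summed squared distance
#' to the previous layer), and the resulting layered graph of corresponding
#' generator chains is scanned for its extremal path lengths: the outer path
#' is the longest generator chain, the inner path the shortest. Ties are
#' broken towards the smallest node index.
#'
#' @param isolines an [extract_isolines()] result (levels ordered inlet to
#'   outlet).
#' @param samples_per_contour candidate nodes per contour (>= 8).
#' @param end_rings optional list of two closed polylines (inlet ring,
#'   outlet ring) included as first and last layers.
#' @return list with elements `outer` and `inner`, each of class
#'   `curvature_path` with fields `kind`, `points` (one node per layer) and
#'   `length` (mm).
#' @export
extremal_paths <- function(isolines, samples_per_contour = 64L,
                           end_rings = NULL) {
  if (samples_per_contour < 8L) stop("samples_per_contour must be >= 8")
  layers <- isolines$contours
  if (length(layers) < 2L) stop("need at least 2 isolines")
  if (any(vapply(layers, function(p) is.null(p) || nrow(p) == 0L, logical(1))))
    stop("empty contour in isoline set")
  if (!is.null(end_rings))
    layers <- c(end_rings[1L], layers, end_rings[2L])
  K <- as.integer(samples_per_contour)
  L <- length(layers)
  cents <- t(vapply(layers, function(p) polyline_centroid(p, closed = TRUE),
                    numeric(3)))
  # consistent orientation: polygon normal along the local sweep direction
  for (l in seq_len(L)) {
    lo <- max(1L, l - 1L)
    hi <- min(L, l + 1L)
    sweep_dir <- cents[hi, ] - cents[lo, ]
    if (sum(polygon_vector_area(layers[[l]]) * sweep_dir) < 0)
      layers[[l]] <- layers[[l]][rev(seq_len(nrow(layers[[l]]))), ,
                                 drop = FALSE]
  }
  # angular correspondence: best integer cyclic shift against the previous
  # layer, refined to a continuous (fractional-sample) phase so the
  # correspondence does not wander azimuthally between layers
  nodes <- vector("list", L)
  nodes[[1L]] <- resample_closed(layers[[1L]], K)
  for (l in 2:L) {
    prev <- nodes[[l - 1L]]
    cost_at <- function(sigma)
      sum((resample_closed(layers[[l]], K, phase = sigma / K) - prev)^2)
    cost <- vapply(0:(K - 1L), cost_at, numeric(1))
    sh0 <- which.min(cost) - 1L
    opt <- stats::optimize(cost_at, interval = c(sh0 - 1, sh0 + 1),
                           tol = 1e-4)
    sigma <- if (opt$objective < cost[sh0 + 1L]) opt$minimum else sh0
    nodes[[l]] <- resample_closed(layers[[l]], K, phase = sigma / K)
  }
  # generator chain lengths
  lens <- numeric(K)
  for (l in 2:L) {
    d <- sqrt(rowSums((nodes[[l]] - nodes[[l - 1L]])^2))
    lens <- lens + d
  }
  j_out <- which.max(lens)  # which.max/min take the first (smallest index) tie
  j_in <- which.min(lens)
  path_of <- function(j, kind) {
    pts <- t(vapply(nodes, function(m) m[j, ], numeric(3)))
    structure(list(kind = kind, points = pts, length = path_length(pts)),
              class = "curvature_path")
  }
  list(outer = path_of(j_out, "outer"), inner = path_of(j_in, "inner"))
}

#' @export
print.curvature_path <- function(x, ...) {
  cat(sprintf("<curvature_path> %s: %d points, length %.2f mm\n",
              x$kind, nrow(x$points), x$length))
  invisible(x)
}

#' Length of an open polyline
#'
#' Sum of consecutive Euclidean distances.
#' @param points numeric matrix, one 3D point per row (>= 2 rows).
#' @return length in the units of `points`.
#' @export
path_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  sum(sqrt(rowSums((points[-1L, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}
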