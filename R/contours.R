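# Level-set contours of a per-vertex scalar on a triangle mesh.
#
# Returns the polylines where `vals == level`, built by linear interpolation
# on mesh edges and chained across faces. Interior crossings chain into
# closed cycles; chains that run into an open mesh boundary come back as
# open polylines (closed = FALSE). Shared by isoline extraction and
# cross-section computation.
level_contours <- function(vertices, faces, vals, level) {
  if (any(vals == level)) level <- level + 1e-12  # deterministic tie-break
  fa <- matrix(vals[faces] > level, ncol = 3L)
  ns <- rowSums(fa)
  cross_f <- which(ns == 1L | ns == 2L)
  if (length(cross_f) == 0L) return(list())
  fsub <- faces[cross_f, , drop = FALSE]
  asub <- fa[cross_f, , drop = FALSE]
  nseg <- length(cross_f)
  # each crossing face has exactly two crossing edges
  ek1_lo <- ek1_hi <- ek2_lo <- ek2_hi <- integer(nseg)
  filled <- integer(nseg)
  for (pr in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
    crossed <- asub[, pr[1]] != asub[, pr[2]]
    if (!any(crossed)) next
    rows <- which(crossed)
    a <- fsub[rows, pr[1]]
    b <- fsub[rows, pr[2]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    first <- filled[rows] == 0L
    ek1_lo[rows[first]] <- lo[first]; ek1_hi[rows[first]] <- hi[first]
    ek2_lo[rows[!first]] <- lo[!first]; ek2_hi[rows[!first]] <- hi[!first]
    filled[rows] <- filled[rows] + 1L
  }
  nv <- nrow(vertices)
  id1 <- (ek1_lo - 1) * nv + ek1_hi  # unique numeric key per undirected edge
  id2 <- (ek2_lo - 1) * nv + ek2_hi
  keys <- unique(c(id1, id2))
  lo <- c(ek1_lo, ek2_lo)[match(keys, c(id1, id2))]
  hi <- c(ek1_hi, ek2_hi)[match(keys, c(id1, id2))]
  tt <- (level - vals[lo]) / (vals[hi] - vals[lo])
  pts <- vertices[lo, , drop = FALSE] +
    tt * (vertices[hi, , drop = FALSE] - vertices[lo, , drop = FALSE])
  seg_a <- match(id1, keys)
  seg_b <- match(id2, keys)
  nb <- vector("list", length(keys))
  for (s in seq_len(nseg)) {
    nb[[seg_a[s]]] <- c(nb[[seg_a[s]]], seg_b[s])
    nb[[seg_b[s]]] <- c(nb[[seg_b[s]]], seg_a[s])
  }
  deg <- lengths(nb)
  seen <- logical(length(keys))
  out <- list()
  # open chains first: start from degree-1 nodes
  for (s in which(deg == 1L)) {
    if (seen[s]) next
    chain <- walk_chain(nb, seen, s)
    seen <- chain$seen
    out[[length(out) + 1L]] <- list(points = pts[chain$nodes, , drop = FALSE],
                                    closed = FALSE)
  }
  for (s in which(!seen & deg == 2L)) {
    if (seen[s]) next
    chain <- walk_chain(nb, seen, s)
    seen <- chain$seen
    out[[length(out) + 1L]] <- list(points = pts[chain$nodes, , drop = FALSE],
                                    closed = chain$closed)
  }
  out
}

walk_chain <- function(nb, seen, start) {
  nodes <- integer(0)
  prev <- 0L
  cur <- start
  closed <- FALSE
  repeat {
    seen[cur] <- TRUE
    nodes <- c(nodes, cur)
    nxt <- nb[[cur]]
    nxt <- nxt[nxt != prev]
    if (length(nxt) > 1L) nxt <- nxt[1L]
    if (length(nxt) == 0L) break
    if (nxt == start) { closed <- TRUE; break }
    if (seen[nxt]) break
    prev <- cur
    cur <- nxt
  }
  list(nodes = nodes, seen = seen, closed = closed)
}

closed_polyline_length <- function(p) {
  sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2)))
}

# Resample a closed polyline to n points equally spaced in arc length.
# `phase` (fraction of the total perimeter, may be negative) offsets the
# starting point from the first vertex.
resample_closed <- function(points, n, phase = 0) {
  p <- rbind(points, points[1L, , drop = FALSE])
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- ((seq_len(n) - 1L) / n + phase) %% 1 * total
  interp_polyline(p, s, target)
}

# Linear interpolation of polyline `p` (arc-length table `s`) at `target`.
interp_polyline <- function(p, s, target) {
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(s) - 1L)
  den <- s[idx + 1L] - s[idx]
  den[den == 0] <- 1
  w <- (target - s[idx]) / den
  p[idx, , drop = FALSE] + w * (p[idx + 1L, , drop = FALSE] - p[idx, , drop = FALSE])
}

# Vector area (sum of cross products) of a closed polyline; its direction is
# the average normal of the enclosed surface.
polygon_vector_area <- function(points) {
  ctr <- colMeans(points)
  q <- sweep(points, 2, ctr)
  qn <- q[c(2:nrow(q), 1L), , drop = FALSE]
  0.5 * c(sum(q[, 2] * qn[, 3] - q[, 3] * qn[, 2]),
          sum(q[, 3] * qn[, 1] - q[, 1] * qn[, 3]),
          sum(q[, 1] * qn[, 2] - q[, 2] * qn[, 1]))
}
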