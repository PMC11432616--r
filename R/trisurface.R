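#' Triangulated surface in world millimetres
#'
#' `tri_surface()` builds the package's central mesh container: a vertex
#' matrix in world millimetres, a face matrix of vertex-index triples, and the
#' ordered boundary loops of the open edges. All geometric stages (harmonic
#' field, centerline, curvature lines, axes) operate on this type.
#'
#' With `clean = TRUE` the mesh is tidied before validation: vertices closer
#' than `merge_tol` are merged, degenerate (zero-area or repeated-index)
#' triangles are dropped, and unreferenced vertices are removed. The mesh must
#' be edge-manifold after cleanup: every edge is shared by one face (boundary)
#' or two faces (interior). A closed surface has zero boundary loops; an open
#' tube has at least two.
#'
#' @param vertices numeric matrix, one 3D point (mm) per row.
#' @param faces integer matrix, one triangle per row (1-based vertex indices).
#' @param clean logical; merge duplicate vertices and drop degenerate faces.
#' @param merge_tol vertex merge tolerance in mm.
#' @return An object of class `tri_surface` with fields `vertices`, `faces`,
#'   and `boundary_loops` (list of ordered closed vertex cycles).
#' @export
tri_surface <- function(vertices, faces, clean = FALSE, merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite values")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (clean) {
    cl <- clean_mesh(vertices, faces, merge_tol = merge_tol)
    vertices <- cl$vertices
    faces <- cl$faces
  }
  check_edge_manifold(faces)
  loops <- boundary_loops(faces)
  structure(list(vertices = vertices, faces = faces, boundary_loops = loops),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d faces, %d boundary loop(s)\n",
              nrow(x$vertices), nrow(x$faces), length(x$boundary_loops)))
  cat(sprintf("  area %.2f mm^2", surface_area(x)))
  if (length(x$boundary_loops) == 0L)
    cat(sprintf(", enclosed volume %.2f mm^3", abs(mesh_volume(x))))
  cat("\n")
  invisible(x)
}

# Merge near-duplicate vertices on a tolerance grid, drop degenerate faces,
# drop unreferenced vertices.
clean_mesh <- function(vertices, faces, merge_tol = 1e-6) {
  key <- paste(round(vertices[, 1] / merge_tol),
               round(vertices[, 2] / merge_tol),
               round(vertices[, 3] / merge_tol))
  first <- match(key, key)             # representative index per group
  keep <- sort(unique(first))
  remap <- match(first, keep)          # old index -> new index
  vertices <- vertices[keep, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  # drop faces with repeated vertices or (numerically) zero area
  rep_idx <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!rep_idx, , drop = FALSE]
  if (nrow(faces) > 0L) {
    a <- triangle_areas(vertices, faces)
    faces <- faces[a > 1e-12, , drop = FALSE]
  }
  used <- sort(unique(as.vector(faces)))
  vertices <- vertices[used, , drop = FALSE]
  faces <- matrix(match(faces, used), ncol = 3L)
  storage.mode(faces) <- "integer"
  list(vertices = vertices, faces = faces)
}

# Undirected edge table: one row per face edge, columns (lo, hi, face).
face_edge_table <- function(faces) {
  m <- nrow(faces)
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  cbind(lo = pmin(e[, 1], e[, 2]), hi = pmax(e[, 1], e[, 2]),
        face = rep(seq_len(m), 3L))
}

edge_key <- function(lo, hi) paste(lo, hi)

check_edge_manifold <- function(faces) {
  if (nrow(faces) == 0L) return(invisible(TRUE))
  et <- face_edge_table(faces)
  cnt <- table(edge_key(et[, 1], et[, 2]))
  bad <- names(cnt)[cnt > 2L]
  if (length(bad) > 0L)
    stop("mesh is not edge-manifold; offending edges: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  invisible(TRUE)
}

# Boundary edges (used by exactly one face) chained into ordered closed loops.
boundary_loops <- function(faces) {
  if (nrow(faces) == 0L) return(list())
  et <- face_edge_table(faces)
  key <- edge_key(et[, 1], et[, 2])
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(list())
  idx <- match(bkey, key)
  be <- et[idx, c(1, 2), drop = FALSE]
  # adjacency between boundary vertices
  verts <- sort(unique(as.vector(be)))
  nb <- vector("list", length(verts))
  vi <- function(v) match(v, verts)
  for (i in seq_len(nrow(be))) {
    a <- vi(be[i, 1]); b <- vi(be[i, 2])
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  deg <- lengths(nb)
  if (any(deg != 2L))
    stop("boundary is not a disjoint union of closed loops")
  seen <- logical(length(verts))
  loops <- list()
  for (s in seq_along(verts)) {
    if (seen[s]) next
    loop <- integer(0)
    prev <- 0L
    cur <- s
    repeat {
      seen[cur] <- TRUE
      loop <- c(loop, verts[cur])
      nxt <- nb[[cur]]
      nxt <- nxt[nxt != prev]
      if (length(nxt) == 2L) nxt <- nxt[1L]  # first step: pick a direction
      if (nxt == s) break
      prev <- cur
      cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

triangle_areas <- function(vertices, faces) {
  u <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  v <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param surface a [tri_surface()].
#' @return numeric scalar.
#' @export
surface_area <- function(surface) {
  sum(triangle_areas(surface$vertices, surface$faces))
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedra; the sign reflects face
#' orientation (positive for consistently outward-facing normals).
#' @param surface a [tri_surface()].
#' @return numeric scalar.
#' @export
mesh_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

face_centroids <- function(surface) {
  (surface$vertices[surface$faces[, 1], , drop = FALSE] +
   surface$vertices[surface$faces[, 2], , drop = FALSE] +
   surface$vertices[surface$faces[, 3], , drop = FALSE]) / 3
}

#' Area-weighted centroid of a surface patch
#' @param surface a [tri_surface()].
#' @return length-3 numeric vector (mm).
#' @export
surface_centroid <- function(surface) {
  a <- triangle_areas(surface$vertices, surface$faces)
  ctr <- face_centroids(surface)
  colSums(ctr * a) / sum(a)
}

# Arc-length-weighted centroid of a polyline (closed = TRUE wraps around).
polyline_centroid <- function(points, closed = FALSE) {
  p <- points
  if (closed) p <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
  if (sum(seg) == 0) return(colMeans(points))
  colSums(mid * seg) / sum(seg)
}

# Ordered polyline (matrix) of a boundary loop.
loop_points <- function(surface, loop_id) {
  surface$vertices[surface$boundary_loops[[loop_id]], , drop = FALSE]
}

loop_centroid <- function(surface, loop_id) {
  polyline_centroid(loop_points(surface, loop_id), closed = TRUE)
}

#' Apply a rigid (or affine) transform to a surface
#'
#' @param surface a [tri_surface()].
#' @param rotation 3x3 matrix applied to the vertices.
#' @param translation length-3 vector added after rotation.
#' @return transformed `tri_surface` (same connectivity).
#' @export
transform_surface <- function(surface, rotation = diag(3), translation = c(0, 0, 0)) {
  out <- surface
  out$vertices <- sweep(surface$vertices %*% t(rotation), 2, translation, "+")
  out
}
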