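#' Clip a surface with a plane
#'
#' Keeps the part of the mesh on the positive side of the plane through
#' `point` with normal `normal` (i.e. `(v - point) . normal > 0`), cutting
#' crossing triangles exactly at the plane. Used to open a closed
#' mask-derived aorta surface at the sinotubular junction and at the distal
#' end of the analyzed segment, creating the inlet/outlet rings the
#' heat-conduction solve needs.
#'
#' @param surface a [tri_surface()].
#' @param point length-3 point on the plane (mm).
#' @param normal length-3 plane normal; the kept side is along `normal`.
#' @return clipped [tri_surface()].
#' @export
clip_surface <- function(surface, point, normal) {
  v <- surface$vertices
  f <- surface$faces
  n <- as.numeric(normal) / sqrt(sum(normal^2))
  vals <- as.numeric(v %*% n) - sum(point * n)
  if (any(vals == 0)) vals[vals == 0] <- 1e-12
  pos <- vals > 0
  fpos <- matrix(pos[f], ncol = 3L)
  np <- rowSums(fpos)
  keep <- f[np == 3L, , drop = FALSE]
  crossing <- which(np == 1L | np == 2L)
  new_pts <- list()
  new_faces <- list()
  cut_cache <- new.env(parent = emptyenv())
  n_base <- nrow(v)
  cut_point <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- get0(key, envir = cut_cache)
    if (!is.null(hit)) return(hit)
    t <- vals[a] / (vals[a] - vals[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    new_pts[[length(new_pts) + 1L]] <<- p
    idx <- n_base + length(new_pts)
    assign(key, idx, envir = cut_cache)
    idx
  }
  for (fi in crossing) {
    tri <- f[fi, ]
    inside <- pos[tri]
    # rotate so the odd vertex comes first, preserving orientation
    odd <- if (sum(inside) == 1L) which(inside) else which(!inside)
    ord <- ((odd - 1L + 0:2) %% 3L) + 1L
    a <- tri[ord[1L]]; b <- tri[ord[2L]]; c3 <- tri[ord[3L]]
    eab <- cut_point(a, b)
    eac <- cut_point(a, c3)
    if (sum(inside) == 1L) {
      new_faces[[length(new_faces) + 1L]] <- c(a, eab, eac)
    } else {
      new_faces[[length(new_faces) + 1L]] <- c(b, c3, eac)
      new_faces[[length(new_faces) + 1L]] <- c(b, eac, eab)
    }
  }
  verts <- rbind(v, do.call(rbind, new_pts))
  faces <- rbind(keep, do.call(rbind, new_faces))
  tri_surface(verts, faces, clean = TRUE)
}
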