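#' Segmentation label volume
#'
#' A 3D integer label grid together with the 4x4 affine mapping continuous
#' 0-based voxel indices to world millimetres, and a name-to-integer label
#' map for the segmented structures (e.g. aorta, left ventricle, left
#' atrium).
#'
#' @param voxels 3D integer array of labels (0 = background).
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world mm.
#' @param label_map named integer vector mapping structure names to labels.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(voxels, affine, label_map) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("label_map must be a named integer vector")
  lm <- as.integer(label_map)
  names(lm) <- names(label_map)
  structure(list(voxels = voxels, affine = affine, label_map = lm),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels; labels: %s\n",
              d[1], d[2], d[3],
              paste(sprintf("%s=%d", names(x$label_map), x$label_map),
                    collapse = ", ")))
  invisible(x)
}

#' Read a NIfTI label volume
#'
#' Loads a `.nii`/`.nii.gz` segmentation and attaches the caller's label map.
#' The world frame is the NIfTI sform/qform (RAS, millimetres), applied to
#' 0-based voxel indices.
#'
#' @param path NIfTI file path.
#' @param label_map named integer vector (structure name to label value).
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path, label_map) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  vox <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  label_volume(vox, aff, label_map)
}

#' Write a label volume to NIfTI
#' @param vol a [label_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

label_value <- function(vol, label) {
  if (is.character(label)) {
    if (!label %in% names(vol$label_map))
      stop("label not in label_map: ", label)
    vol$label_map[[label]]
  } else as.integer(label)
}

voxel_to_world <- function(idx0, affine) {
  # idx0: n x 3 matrix of 0-based continuous voxel indices
  h <- cbind(idx0, 1) %*% t(affine)
  h[, 1:3, drop = FALSE] / h[, 4]
}

#' Extract a structure surface from a label volume
#'
#' Binarizes one label, extracts the 0.5 level set of the resulting indicator
#' field with a marching-tetrahedra decomposition of the voxel lattice, maps
#' vertices through the affine to world millimetres, and applies
#' volume-preserving Taubin smoothing to suppress the voxel staircase
#' (the tetrahedral lattice cut produces a fine staircase, so the default of
#' 30 iteration pairs is deliberately generous; enclosed volume stays within
#' about 0.5 percent). If the
#' label touches the grid border the surface is left open there (a warning is
#' issued), which is how tubular masks acquire their inlet/outlet boundary
#' loops.
#'
#' @param vol a [label_volume()].
#' @param label structure name (in `label_map`) or integer label value.
#' @param smoothing_iters Taubin iterations (default 30; 0 disables).
#' @return a [tri_surface()] in world mm.
#' @export
mask_to_surface <- function(vol, label, smoothing_iters = 30L) {
  lv <- label_value(vol, label)
  mask <- vol$voxels == lv
  if (!any(mask)) stop("label is empty in volume: ", label)
  d <- dim(mask)
  touches <- any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
  if (touches)
    warning("label touches the grid border; extracted surface may be open")
  res <- marching_tetrahedra_cpp(as.numeric(mask), dim(mask), 0.5)
  # C++ indices are 0-based voxel offsets of the array cell corners
  verts <- voxel_to_world(res$vertices, vol$affine)
  surf <- tri_surface(verts, res$faces, clean = TRUE)
  if (smoothing_iters > 0L)
    surf <- taubin_smooth(surf, iterations = smoothing_iters)
  surf
}

#' Volume-preserving Taubin mesh smoothing
#'
#' Alternates umbrella-operator shrink (`lambda`) and inflate (`mu`) passes.
#' Boundary-loop vertices are held fixed so that open inlets/outlets keep
#' their rings. Defaults keep the enclosed volume of closed surfaces within
#' about 2 percent.
#'
#' @param surface a [tri_surface()].
#' @param iterations number of lambda/mu pass pairs.
#' @param lambda positive smoothing step.
#' @param mu negative inflation step.
#' @return smoothed `tri_surface` (same connectivity).
#' @export
taubin_smooth <- function(surface, iterations = 10L, lambda = 0.5, mu = -0.53) {
  v <- surface$vertices
  f <- surface$faces
  et <- face_edge_table(f)
  key <- edge_key(et[, 1], et[, 2])
  uniq <- !duplicated(key)
  e <- et[uniq, 1:2, drop = FALSE]
  n <- nrow(v)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  fixed <- unique(unlist(surface$boundary_loops))
  step <- function(v, w) {
    upd <- as.matrix(A %*% v) / deg - v
    if (length(fixed) > 0L) upd[fixed, ] <- 0
    v + w * upd
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  out <- surface
  out$vertices <- v
  out
}

#' Interface patch between two adjacent structures
#'
#' Collects the voxel faces (6-connectivity) shared by two labels,
#' triangulates them in world coordinates, and returns the open patch with
#' its area-weighted centroid. Used for the mitral (left ventricle / left
#' atrium) and LVOT (left ventricle / aorta) separating surfaces whose
#' centroids anchor the cardiac axes.
#'
#' @param vol a [label_volume()].
#' @param label_a,label_b structure names or label values.
#' @return list of class `interface_surface` with fields `parent_labels`,
#'   `patch` (a [tri_surface()]), and `centroid` (mm).
#' @export
interface_surface <- function(vol, label_a, label_b) {
  la <- label_value(vol, label_a)
  lb <- label_value(vol, label_b)
  vox <- vol$voxels
  d <- dim(vox)
  if (!any(vox == la)) stop("label is empty in volume: ", label_a)
  if (!any(vox == lb)) stop("label is empty in volume: ", label_b)
  quads <- list()
  # for each axis, find adjacent voxel pairs (la|lb) and emit the shared face
  for (axis in 1:3) {
    n <- d[axis]
    idx_lo <- slice_index(d, axis, 1:(n - 1))
    idx_hi <- slice_index(d, axis, 2:n)
    a_lo <- vox[idx_lo] == la & vox[idx_hi] == lb
    a_hi <- vox[idx_lo] == lb & vox[idx_hi] == la
    hit <- which(a_lo | a_hi)
    if (length(hit) == 0L) next
    # voxel (0-based) index of the lower voxel of each adjacent pair
    sub <- arrayInd(idx_lo[hit], d) - 1L
    # shared face sits at +1 along `axis` from the lower voxel centre; in
    # index space the voxel centre is the integer coordinate itself
    quads[[axis]] <- face_quads(sub, axis)
  }
  if (length(quads) == 0L || all(vapply(quads, is.null, logical(1))))
    stop("no shared interface between labels: ", label_a, ", ", label_b)
  corners <- do.call(rbind, quads)
  # corners: 4 consecutive rows per quad, voxel-index coordinates
  world <- voxel_to_world(corners, vol$affine)
  nq <- nrow(world) / 4L
  base <- (seq_len(nq) - 1L) * 4L
  faces <- rbind(cbind(base + 1L, base + 2L, base + 3L),
                 cbind(base + 1L, base + 3L, base + 4L))
  patch <- tri_surface(world, faces, clean = TRUE)
  structure(list(parent_labels = c(as.character(label_a), as.character(label_b)),
                 patch = patch,
                 centroid = surface_centroid(patch)),
            class = "interface_surface")
}

#' @export
print.interface_surface <- function(x, ...) {
  cat(sprintf("<interface_surface> %s | %s: area %.2f mm^2, centroid (%.2f, %.2f, %.2f)\n",
              x$parent_labels[1], x$parent_labels[2], surface_area(x$patch),
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# linear indices of all voxels whose `axis` coordinate lies in `range`
slice_index <- function(d, axis, range) {
  ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ii[[axis]] <- range
  grid <- expand.grid(ii[[1]], ii[[2]], ii[[3]])
  as.vector(grid[, 1] + d[1] * (grid[, 2] - 1L) + d[1] * d[2] * (grid[, 3] - 1L))
}

# corner coordinates (voxel index space, 0-based centres) of the square face
# between voxel `sub` and its +1 neighbour along `axis`
face_quads <- function(sub, axis) {
  u <- c(0, 0, 0)
  u[axis] <- 0.5
  ax2 <- setdiff(1:3, axis)
  e1 <- c(0, 0, 0); e1[ax2[1]] <- 0.5
  e2 <- c(0, 0, 0); e2[ax2[2]] <- 0.5
  ctr <- sweep(sub, 2, u, "+")
  rbind_interleave(
    sweep(ctr, 2, -e1 - e2, "+"),
    sweep(ctr, 2,  e1 - e2, "+"),
    sweep(ctr, 2,  e1 + e2, "+"),
    sweep(ctr, 2, -e1 + e2, "+"))
}

rbind_interleave <- function(...) {
  mats <- list(...)
  n <- nrow(mats[[1]])
  k <- length(mats)
  out <- matrix(0, n * k, ncol(mats[[1]]))
  for (i in seq_len(k)) out[seq(i, n * k, by = k), ] <- mats[[i]]
  out
}
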