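#' Solve the heat-conduction problem on an open tubular surface
#'
#' Solves the Laplace equation on the mesh with Dirichlet conditions fixing
#' the vessel inlet ring at a value ("temperature") of 1 and the outlet ring
#' at 0. The discretization is the intrinsic cotangent-weight finite-element
#' Laplacian, so isoline geometry converges under mesh refinement. The inlet
#' (outlet) boundary loop is the loop whose centroid is nearest the supplied
#' inlet (outlet) seed; any further boundary loops are left free (natural
#' boundary conditions).
#'
#' @param surface a [tri_surface()] with at least 2 boundary loops.
#' @param inlet_seed,outlet_seed [landmark()]s (or length-3 points) near the
#'   inlet and outlet rings.
#' @return object of class `harmonic_field` with fields `surface`, `values`
#'   (one scalar per vertex in `[0, 1]`), `inlet_loop`, `outlet_loop`.
#' @export
solve_harmonic <- function(surface, inlet_seed, outlet_seed) {
  loops <- surface$boundary_loops
  if (length(loops) < 2L)
    stop("not an open tube: surface has ", length(loops), " boundary loop(s)")
  p_in <- seed_position(inlet_seed)
  p_out <- seed_position(outlet_seed)
  cents <- t(vapply(seq_along(loops), function(i) loop_centroid(surface, i),
                    numeric(3)))
  d_in <- sqrt(rowSums(sweep(cents, 2, p_in)^2))
  d_out <- sqrt(rowSums(sweep(cents, 2, p_out)^2))
  inlet_loop <- which.min(d_in)
  outlet_loop <- which.min(d_out)
  if (inlet_loop == outlet_loop)
    stop("inlet and outlet seeds are nearest the same boundary loop")
  n <- nrow(surface$vertices)
  L <- cotan_laplacian(surface)
  vals <- rep(NA_real_, n)
  vals[loops[[inlet_loop]]] <- 1
  vals[loops[[outlet_loop]]] <- 0
  fixed <- which(!is.na(vals))
  free <- setdiff(seq_len(n), fixed)
  rhs <- -L[free, fixed, drop = FALSE] %*% vals[fixed]
  sol <- Matrix::solve(L[free, free], rhs)
  vals[free] <- as.numeric(sol)
  res <- as.numeric(L[free, , drop = FALSE] %*% vals)
  if (sqrt(sum(res^2)) > 1e-8 * max(1, sqrt(length(res))))
    warning("harmonic solve residual larger than expected: ",
            format(sqrt(sum(res^2))))
  structure(list(surface = surface, values = vals,
                 inlet_loop = inlet_loop, outlet_loop = outlet_loop),
            class = "harmonic_field")
}

seed_position <- function(x) {
  if (inherits(x, "landmark")) x$position else as.numeric(x)
}

#' @export
print.harmonic_field <- function(x, ...) {
  cat(sprintf("<harmonic_field> %d vertices; range [%.3g, %.3g]; inlet loop %d, outlet loop %d\n",
              length(x$values), min(x$values), max(x$values),
              x$inlet_loop, x$outlet_loop))
  invisible(x)
}

# Cotangent-weight FEM stiffness matrix (positive semi-definite).
cotan_laplacian <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  n <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    dot / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-300)
  }
  c1 <- cot_at(i1, i2, i3)  # opposite edge (i2, i3)
  c2 <- cot_at(i2, i3, i1)  # opposite edge (i3, i1)
  c3 <- cot_at(i3, i1, i2)  # opposite edge (i1, i2)
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  xx <- -0.5 * c(c1, c1, c2, c2, c3, c3)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::Diagonal(n, -Matrix::rowSums(W)) + W
}

#' Extract equidistant isolines of a harmonic field
#'
#' Computes the closed contours of the field at `n_levels` equally spaced
#' levels strictly inside (0, 1): `k / (n_levels + 1)` for
#' `k = n_levels, ..., 1` (decreasing, inlet to outlet). Contour points are
#' linearly interpolated on mesh edges crossing each level and chained into a
#' closed polyline; if a level yields several closed components (e.g. across
#' a bulge) the longest is kept with a warning.
#'
#' @param field a [solve_harmonic()] result.
#' @param n_levels number of levels (>= 2).
#' @return object of class `isoline_set`: fields `levels` (decreasing) and
#'   `contours` (list of closed polylines, n x 3 mm, one per level).
#' @export
extract_isolines <- function(field, n_levels = 100L) {
  if (n_levels < 2L) stop("n_levels must be >= 2")
  levels <- seq(n_levels, 1L) / (n_levels + 1)
  contours <- lapply(levels, function(t) contour_at_level(field, t))
  structure(list(levels = levels, contours = contours),
            class = "isoline_set")
}

#' @export
print.isoline_set <- function(x, ...) {
  cat(sprintf("<isoline_set> %d levels in [%.4g, %.4g]\n",
              length(x$levels), min(x$levels), max(x$levels)))
  invisible(x)
}

# One closed contour polyline at a single level.
contour_at_level <- function(field, level) {
  comps <- level_contours(field$surface$vertices, field$surface$faces,
                          field$values, level)
  if (length(comps) == 0L)
    stop(sprintf("no contour found at level %.6g", level))
  if (any(!vapply(comps, `[[`, logical(1), "closed")))
    stop(sprintf("open contour at level %.6g (chaining failure)", level))
  if (length(comps) > 1L) {
    lens <- vapply(comps, function(cmp) closed_polyline_length(cmp$points),
                   numeric(1))
    warning(sprintf("level %.4g has %d contour components; keeping the longest",
                    level, length(comps)))
    comps <- comps[which.max(lens)]
  }
  comps[[1]]$points
}
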