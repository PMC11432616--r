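#' Vessel centerline from harmonic-field isolines
#'
#' Builds the raw centerline as the arc-length-weighted centroids of the
#' isolines ordered from inlet (level near 1) to outlet (level near 0),
#' prepended and appended with the inlet and outlet boundary-ring centroids.
#' The polyline is then smoothed over an arc-length window and resampled to
#' a uniform arc-length step.
#'
#' Two smoothers are available. The default, `"quadratic"`, fits a local
#' quadratic polynomial in arc length (Savitzky-Golay style) around every
#' point: it suppresses centroid noise while reproducing circular arcs
#' without the inward bias a plain moving average has, which matters because
#' the tortuosity index is small and sensitive to systematic length loss.
#' `"moving_average"` is the classical centered moving average (its window
#' shrinks symmetrically near the ends, so the endpoints stay fixed).
#'
#' @param field a [solve_harmonic()] result.
#' @param isolines an [extract_isolines()] result for the same field.
#' @param smooth_window smoothing window (mm of arc length).
#' @param resample_step resampled point spacing (mm).
#' @param smooth_method `"quadratic"` (default) or `"moving_average"`.
#' @return object of class `centerline` with fields `points` (n x 3 mm),
#'   `arc_length` (strictly increasing, starting at 0), and
#'   `cross_section_area` (per point, mm^2; `NA` until
#'   [cross_section_areas()] fills it).
#' @export
compute_centerline <- function(field, isolines, smooth_window = 10,
                               resample_step = 0.5,
                               smooth_method = c("quadratic",
                                                 "moving_average")) {
  smooth_method <- match.arg(smooth_method)
  if (length(isolines$contours) < 2L) stop("fewer than 2 isolines")
  if (resample_step <= 0) stop("resample_step must be positive")
  cents <- t(vapply(isolines$contours,
                    function(p) polyline_centroid(p, closed = TRUE),
                    numeric(3)))
  p0 <- loop_centroid(field$surface, field$inlet_loop)
  p1 <- loop_centroid(field$surface, field$outlet_loop)
  raw <- rbind(p0, cents, p1)
  sm <- smooth_polyline(raw, smooth_window, method = smooth_method)
  rs <- resample_polyline(sm, resample_step)
  new_centerline(rs)
}

new_centerline <- function(points, areas = NULL) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  if (any(seg <= 0)) stop("centerline has coincident consecutive points")
  if (is.null(areas)) areas <- rep(NA_real_, nrow(points))
  structure(list(points = points, arc_length = arc,
                 cross_section_area = areas),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm", nrow(x$points),
              max(x$arc_length)))
  if (any(!is.na(x$cross_section_area)))
    cat(sprintf(", mean diameter %.2f mm",
                mean(equivalent_diameter(
                  x$cross_section_area[!is.na(x$cross_section_area)]))))
  cat("\n")
  invisible(x)
}

# Arc-length-windowed polyline smoothing. "quadratic" fits a local degree-2
# polynomial per coordinate (unbiased on circular arcs); "moving_average" is
# the centered mean with a window truncated symmetrically near the ends (so
# endpoints are fixed points of the filter).
smooth_polyline <- function(points, window,
                            method = c("quadratic", "moving_average")) {
  method <- match.arg(method)
  if (window <= 0 || nrow(points) < 3L) return(points)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  out <- points
  for (i in seq_len(nrow(points))) {
    if (method == "moving_average") {
      half <- min(window / 2, s[i], total - s[i])
      sel <- which(abs(s - s[i]) <= half + 1e-12)
      out[i, ] <- colMeans(points[sel, , drop = FALSE])
    } else {
      sel <- which(abs(s - s[i]) <= window / 2 + 1e-12)
      if (length(sel) < 4L) next  # too few points to fit; keep the point
      ds <- s[sel] - s[i]
      X <- cbind(1, ds, ds^2)
      beta <- qr.coef(qr(X), points[sel, , drop = FALSE])
      out[i, ] <- beta[1L, ]
    }
  }
  out
}

# Uniform arc-length resampling; keeps the exact endpoints.
resample_polyline <- function(points, step) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, by = step)
  if (total - target[length(target)] > 1e-9) target <- c(target, total)
  interp_polyline(points, s, target)
}

#' Fill per-point cross-section areas of a centerline
#'
#' At each centerline point, intersects the vessel surface with the plane
#' orthogonal to the local tangent, keeps the closed intersection loop that
#' winds around the centerline point, and computes its planar polygon area.
#' Points where no closed enclosing loop exists (typically at the very ends
#' of an open tube) are marked `NA`.
#'
#' @param centerline a [compute_centerline()] result.
#' @param surface the vessel [tri_surface()].
#' @return the centerline with `cross_section_area` filled.
#' @export
cross_section_areas <- function(centerline, surface) {
  pts <- centerline$points
  n <- nrow(pts)
  tang <- polyline_tangents(pts)
  areas <- rep(NA_real_, n)
  v <- surface$vertices
  f <- surface$faces
  for (i in seq_len(n)) {
    vals <- as.numeric(v %*% tang[i, ]) - sum(pts[i, ] * tang[i, ])
    comps <- level_contours(v, f, vals, 0)
    closed <- Filter(function(cmp) cmp$closed, comps)
    if (length(closed) == 0L) next
    areas[i] <- enclosing_loop_area(closed, pts[i, ], tang[i, ])
  }
  n_missing <- sum(is.na(areas))
  if (n_missing > 0L)
    message(sprintf("cross_section_areas: %d of %d sections missing (no closed enclosing loop)",
                    n_missing, n))
  centerline$cross_section_area <- areas
  centerline
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  d <- rbind(pts[2L, ] - pts[1L, ],
             pts[3:n, , drop = FALSE] - pts[1:(n - 2L), , drop = FALSE],
             pts[n, ] - pts[n - 1L, ])
  d / sqrt(rowSums(d^2))
}

# Among closed plane-intersection loops, pick the one winding around `p` and
# return its planar area (NA if none encloses p).
enclosing_loop_area <- function(loops, p, normal) {
  e1 <- orthonormal_basis(normal)
  best_area <- NA_real_
  best_dist <- Inf
  for (cmp in loops) {
    q <- sweep(cmp$points, 2, p)
    u <- as.numeric(q %*% e1$u)
    w <- as.numeric(q %*% e1$v)
    ang <- atan2(w, u)
    dang <- diff(c(ang, ang[1L]))
    dang <- (dang + pi) %% (2 * pi) - pi
    winding <- sum(dang) / (2 * pi)
    if (abs(winding) < 0.5) next
    un <- c(u[-1L], u[1L])
    wn <- c(w[-1L], w[1L])
    area <- abs(sum(u * wn - un * w)) / 2
    dist <- sqrt(sum((colMeans(cmp$points) - p)^2))
    if (dist < best_dist) {
      best_dist <- dist
      best_area <- area
    }
  }
  best_area
}

orthonormal_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' Equivalent circular diameter from a cross-section area
#'
#' Treats the lumen cross-section as circular: `D = 2 * sqrt(A / pi)`.
#'
#' @param area cross-section area(s), mm^2 (must be positive).
#' @return diameter(s), mm.
#' @export
equivalent_diameter <- function(area) {
  if (any(!is.na(area) & area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' Length, tortuosity, and mean diameter of a centerline segment
#'
#' The tortuosity index is `T = L / D - 1`, where `L` is the centerline
#' length of the segment and `D` the straight-line distance between its
#' endpoints. The mean diameter averages the equivalent diameters of the
#' cross-sections falling inside the segment (requires
#' [cross_section_areas()] to have been run for a non-`NA` value).
#'
#' @param centerline a [compute_centerline()] result.
#' @param s_start,s_end segment bounds in arc length (mm),
#'   `0 <= s_start < s_end <= total length`.
#' @return object of class `segment_metrics`: `length_L`,
#'   `endpoint_distance_D`, `tortuosity_T`, `mean_diameter`.
#' @export
segment_metrics <- function(centerline, s_start = 0,
                            s_end = max(centerline$arc_length)) {
  s <- centerline$arc_length
  total <- max(s)
  if (s_start < 0 || s_end > total + 1e-9 || s_start >= s_end)
    stop("require 0 <= s_start < s_end <= total arc length")
  s_end <- min(s_end, total)
  ends <- interp_polyline(centerline$points, s, c(s_start, s_end))
  L <- s_end - s_start
  D <- sqrt(sum((ends[2L, ] - ends[1L, ])^2))
  if (D <= 1e-12) stop("segment endpoints coincide (D = 0)")
  inside <- s >= s_start - 1e-9 & s <= s_end + 1e-9
  a <- centerline$cross_section_area[inside]
  a <- a[!is.na(a)]
  md <- if (length(a) > 0L) mean(equivalent_diameter(a)) else NA_real_
  structure(list(length_L = L, endpoint_distance_D = D,
                 tortuosity_T = L / D - 1, mean_diameter = md),
            class = "segment_metrics")
}

#' @export
print.segment_metrics <- function(x, ...) {
  cat(sprintf("<segment_metrics> L %.2f mm, D %.2f mm, T %.4f, mean diameter %s mm\n",
              x$length_L, x$endpoint_distance_D, x$tortuosity_T,
              ifelse(is.na(x$mean_diameter), "NA",
                     sprintf("%.2f", x$mean_diameter))))
  invisible(x)
}

#' Export a centerline as CSV
#'
#' Columns: `s` (arc length, mm), `x`, `y`, `z` (mm), `area` (mm^2),
#' `diameter` (mm).
#' @param centerline a [compute_centerline()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(centerline, path) {
  a <- centerline$cross_section_area
  d <- ifelse(is.na(a), NA_real_, 2 * sqrt(pmax(a, 0) / pi))
  utils::write.csv(data.frame(s = centerline$arc_length,
                              x = centerline$points[, 1],
                              y = centerline$points[, 2],
                              z = centerline$points[, 3],
                              area = a, diameter = d),
                   path, row.names = FALSE)
  invisible(path)
}
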