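#' Aortic axis from centerline start and LVOT interface
#'
#' The aortic axis connects the centroid of the left-ventricular outflow
#' tract interface to the first centerline point (at the sinotubular
#' junction); its direction points from the LVOT towards the STJ.
#'
#' @param centerline a [compute_centerline()] result whose first point is at
#'   the sinotubular junction.
#' @param lvot_interface an [interface_surface()] (or any object with a
#'   `centroid` field) for the LV / aorta separating surface.
#' @return list of class `axis3` with `origin` (LVOT centroid) and unit
#'   `direction`.
#' @export
aortic_axis <- function(centerline, lvot_interface) {
  stj <- centerline$points[1L, ]
  ctr <- lvot_interface$centroid
  make_axis(ctr, stj - ctr)
}

#' Left-ventricular long axis from apex and mitral interface
#'
#' Direction from the ventricular apex to the centroid of the separating
#' surface between left ventricle and left atrium (where the mitral valve
#' sits).
#'
#' @param apex a [landmark()] (or length-3 point) at the ventricular apex.
#' @param mitral_interface an [interface_surface()] for the LV / LA
#'   separating surface.
#' @return list of class `axis3` with `origin` (apex) and unit `direction`.
#' @export
ventricular_axis <- function(apex, mitral_interface) {
  p <- seed_position(apex)
  make_axis(p, mitral_interface$centroid - p)
}

make_axis <- function(origin, direction) {
  len <- sqrt(sum(direction^2))
  if (len < 1e-9) stop("axis endpoints coincide")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / len),
            class = "axis3")
}

#' @export
print.axis3 <- function(x, ...) {
  cat(sprintf("<axis3> origin (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Apex fallback: farthest LV surface point from the mitral centroid
#'
#' When no apex landmark is supplied, the elongated shape of the left
#' ventricle makes the surface vertex farthest from the mitral interface
#' centroid a stable stand-in for the apex.
#'
#' @param lv_surface left-ventricle [tri_surface()].
#' @param mitral_centroid length-3 point (mm).
#' @return a [landmark()] named `"apex_auto"`.
#' @export
auto_apex <- function(lv_surface, mitral_centroid) {
  d2 <- rowSums(sweep(lv_surface$vertices, 2, mitral_centroid)^2)
  landmark("apex_auto", lv_surface$vertices[which.max(d2), ])
}

#' Aorto-septal angle between the aortic and ventricular axes
#'
#' Projects both axis directions onto the measurement plane (orthogonal to
#' `plane_normal`), renormalizes, and takes the arccosine of their dot
#' product, reported in degrees on `[0, 180]` without supplementary-angle
#' folding (the anatomical angle is obtuse). With `plane_normal = "auto"`
#' the plane is the one spanned by the two axes (their normalized cross
#' product), which makes the projection exact: the result equals the direct
#' 3D angle between the axes.
#'
#' @param aortic,ventricular `axis3` objects (see [aortic_axis()],
#'   [ventricular_axis()]).
#' @param plane_normal `"auto"` or an explicit unit normal of the
#'   measurement plane.
#' @return object of class `axis_pair`: `aortic_axis`, `ventricular_axis`,
#'   `plane_normal`, `aosa_deg`.
#' @export
aosa <- function(aortic, ventricular, plane_normal = "auto") {
  d1 <- aortic$direction
  d2 <- ventricular$direction
  if (identical(plane_normal, "auto")) {
    cr <- cross3(d1, d2)
    ncr <- sqrt(sum(cr^2))
    if (ncr < 1e-12) {
      # parallel or antiparallel axes: any containing plane; angle is 0/180
      n <- orthonormal_basis(d1)$u
    } else n <- cr / ncr
  } else {
    n <- as.numeric(plane_normal)
    if (abs(sqrt(sum(n^2)) - 1) > 1e-6) stop("plane_normal must be unit length")
  }
  p1 <- project_unit(d1, n)
  p2 <- project_unit(d2, n)
  ang <- acos(min(1, max(-1, sum(p1 * p2)))) * 180 / pi
  structure(list(aortic_axis = aortic, ventricular_axis = ventricular,
                 plane_normal = n, aosa_deg = ang),
            class = "axis_pair")
}

project_unit <- function(d, n) {
  p <- d - sum(d * n) * n
  len <- sqrt(sum(p^2))
  if (len < 1e-9) stop("axis degenerate in plane (parallel to plane normal)")
  p / len
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.axis_pair <- function(x, ...) {
  cat(sprintf("<axis_pair> AoSA %.2f deg\n", x$aosa_deg))
  invisible(x)
}

#' Inclination of the ascending aorta over its first centimetres
#'
#' For every resampled centerline point with arc length `0 < s <=
#' window_mm`, forms the chord direction from the centerline origin and
#' takes its angle (degrees) to the aortic axis; reports the mean and SD
#' over the window.
#'
#' @param centerline a [compute_centerline()] result starting at the STJ.
#' @param aortic an `axis3` (see [aortic_axis()]).
#' @param window_mm arc-length window, default 20 mm (the first two
#'   centimetres).
#' @return object of class `inclination_result`: `aai_deg`, `aai_sd_deg`,
#'   `window_mm`.
#' @export
ascending_inclination <- function(centerline, aortic, window_mm = 20) {
  if (window_mm <= 0) stop("window_mm must be positive")
  s <- centerline$arc_length
  if (max(s) < window_mm)
    stop("centerline shorter than the inclination window")
  sel <- which(s > 0 & s <= window_mm + 1e-9)
  p0 <- centerline$points[1L, ]
  v <- sweep(centerline$points[sel, , drop = FALSE], 2, p0)
  v <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(1, pmax(-1, as.numeric(v %*% aortic$direction)))) * 180 / pi
  structure(list(aai_deg = mean(ang), aai_sd_deg = stats::sd(ang),
                 window_mm = window_mm),
            class = "inclination_result")
}

#' @export
print.inclination_result <- function(x, ...) {
  cat(sprintf("<inclination_result> AAI %.2f +/- %.2f deg (first %g mm)\n",
              x$aai_deg, x$aai_sd_deg, x$window_mm))
  invisible(x)
}

#' Repeated AoSA measurement with seeded apex jitter
#'
#' Emulates an observer repeating the angle measurement: the apex landmark
#' is perturbed by isotropic Gaussian jitter of SD `jitter_mm` before each
#' re-measurement, deterministically under `seed`. The returned list of
#' angles feeds the coefficient of variation; their mean is the reported
#' angle.
#'
#' @param protocol list with fields `centerline`, `lvot_interface`, `apex`
#'   (a [landmark()]), `mitral_interface`, and optional `plane_normal`
#'   (default `"auto"`).
#' @param n_repeats number of repeats (>= 2), default 5.
#' @param jitter_mm isotropic jitter SD in mm.
#' @param seed integer seed.
#' @return numeric vector of `n_repeats` AoSA values (degrees).
#' @export
repeat_measurement <- function(protocol, n_repeats = 5L, jitter_mm = 2,
                               seed = 1L) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  pn <- protocol$plane_normal
  if (is.null(pn)) pn <- "auto"
  ao <- aortic_axis(protocol$centerline, protocol$lvot_interface)
  apex0 <- seed_position(protocol$apex)
  with_seed(seed, {
    vapply(seq_len(n_repeats), function(i) {
      apex <- apex0 + stats::rnorm(3L, sd = jitter_mm)
      ve <- ventricular_axis(apex, protocol$mitral_interface)
      aosa(ao, ve, plane_normal = pn)$aosa_deg
    }, numeric(1))
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
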