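#' Specification of a synthetic tube phantom
#'
#' Describes a swept-circle tube whose centerline is a planar chain of
#' straight segments and circular arcs in the x-z plane, starting at the
#' origin with tangent (0, 0, 1). All geometric quantities the pipeline
#' measures (length, tortuosity, equivalent diameter, outer/inner
#' curvature-line lengths) then have closed forms.
#'
#' @param segments list of segments: `list(kind = "straight", length = L)`
#'   or `list(kind = "arc", bend_radius = R, angle = theta, direction = +1)`
#'   (`direction = +1` bends towards +x, `-1` towards -x; angles in
#'   radians).
#' @param tube_radius tube radius r (mm); arcs require `bend_radius > r`.
#' @param mesh_step target mesh edge length (mm).
#' @param seed integer, recorded for provenance (the construction is
#'   deterministic).
#' @return object of class `tube_phantom_spec`.
#' @export
tube_phantom_spec <- function(segments, tube_radius, mesh_step = 1,
                              seed = 1L) {
  if (tube_radius <= 0) stop("tube_radius must be positive")
  if (mesh_step <= 0) stop("mesh_step must be positive")
  segments <- lapply(segments, function(sg) {
    if (!sg$kind %in% c("straight", "arc")) stop("unknown segment kind: ", sg$kind)
    if (sg$kind == "straight" && sg$length <= 0) stop("straight length must be positive")
    if (sg$kind == "arc") {
      if (sg$bend_radius <= tube_radius)
        stop("self-intersecting sweep: bend_radius must exceed tube_radius")
      if (sg$angle <= 0) stop("arc angle must be positive")
      if (is.null(sg$direction)) sg$direction <- 1
    }
    sg
  })
  structure(list(segments = segments, tube_radius = tube_radius,
                 mesh_step = mesh_step, seed = as.integer(seed)),
            class = "tube_phantom_spec")
}

# Analytic centerline stations: points, tangent angle phi (tangent =
# (sin phi, 0, cos phi)), and arc length, sampled at ~mesh_step.
tube_centerline_stations <- function(spec, step = spec$mesh_step) {
  p <- c(0, 0, 0)
  phi <- 0
  s <- 0
  pts <- matrix(p, 1L, 3L)
  phis <- phi
  arcs <- 0
  for (sg in spec$segments) {
    if (sg$kind == "straight") {
      len <- sg$length
      nst <- max(2L, ceiling(len / step) + 1L)
      u <- seq(0, len, length.out = nst)[-1L]
      t_dir <- c(sin(phi), 0, cos(phi))
      newp <- t(sapply(u, function(uu) p + uu * t_dir))
      pts <- rbind(pts, newp)
      phis <- c(phis, rep(phi, length(u)))
      arcs <- c(arcs, s + u)
      p <- p + len * t_dir
      s <- s + len
    } else {
      R <- sg$bend_radius
      th <- sg$angle
      dir <- sg$direction
      len <- R * th
      nst <- max(2L, ceiling(len / step) + 1L)
      u <- seq(0, th, length.out = nst)[-1L]
      nvec <- function(a) c(cos(a), 0, -sin(a))
      ctr <- p + dir * R * nvec(phi)
      newp <- t(sapply(u, function(uu) ctr - dir * R * nvec(phi + dir * uu)))
      pts <- rbind(pts, newp)
      phis <- c(phis, phi + dir * u)
      arcs <- c(arcs, s + R * u)
      p <- ctr - dir * R * nvec(phi + dir * th)
      phi <- phi + dir * th
      s <- s + len
    }
  }
  list(points = pts, phi = phis, arc_length = arcs)
}

# Closed-form ground truth for a tube phantom.
tube_truth <- function(spec) {
  st <- tube_centerline_stations(spec, step = min(0.25, spec$mesh_step))
  L <- max(st$arc_length)
  endpoints <- st$points[c(1L, nrow(st$points)), , drop = FALSE]
  D <- sqrt(sum((endpoints[2L, ] - endpoints[1L, ])^2))
  r <- spec$tube_radius
  theta_signed <- sum(vapply(spec$segments, function(sg)
    if (sg$kind == "arc") sg$direction * sg$angle else 0, numeric(1)))
  list(centerline_points = st$points,
       total_length = L,
       endpoint_distance = D,
       tortuosity = L / D - 1,
       diameter = 2 * r,
       outer_length = L + r * abs(theta_signed),
       inner_length = L - r * abs(theta_signed))
}

#' Generate a swept-tube phantom mesh with closed-form ground truth
#'
#' Sweeps a circle of radius `tube_radius` along the planar centerline of
#' `spec`, producing an open tube (no end caps) whose inlet is the ring at
#' the centerline start. The returned truth holds the analytic centerline,
#' total length, tortuosity, diameter, and outer/inner curvature-line
#' lengths (for a planar sweep the wall generator at in-plane offset `e`
#' has length `L - e * Theta`, `Theta` the total signed turn, so the
#' extremes are `L + r|Theta|` and `L - r|Theta|`).
#'
#' @param spec a [tube_phantom_spec()].
#' @return list with `surface` (a [tri_surface()]) and `truth` (list:
#'   `centerline_points`, `total_length`, `endpoint_distance`,
#'   `tortuosity`, `diameter`, `outer_length`, `inner_length`).
#' @export
make_tube <- function(spec) {
  st <- tube_centerline_stations(spec)
  r <- spec$tube_radius
  n_ring <- max(12L, round(2 * pi * r / spec$mesh_step))
  alpha <- (seq_len(n_ring) - 1L) / n_ring * 2 * pi
  n_st <- nrow(st$points)
  verts <- matrix(0, n_st * n_ring, 3L)
  for (i in seq_len(n_st)) {
    phi <- st$phi[i]
    nvec <- c(cos(phi), 0, -sin(phi))
    bvec <- c(0, 1, 0)
    ring <- st$points[rep(i, n_ring), , drop = FALSE] +
      r * (cos(alpha) %o% nvec + sin(alpha) %o% bvec)
    verts[(i - 1L) * n_ring + seq_len(n_ring), ] <- ring
  }
  faces <- matrix(0L, 2L * (n_st - 1L) * n_ring, 3L)
  row <- 1L
  for (i in seq_len(n_st - 1L)) {
    a <- (i - 1L) * n_ring + seq_len(n_ring)
    b <- (i - 1L) * n_ring + c(2:n_ring, 1L)
    c1 <- i * n_ring + seq_len(n_ring)
    d1 <- i * n_ring + c(2:n_ring, 1L)
    faces[row:(row + n_ring - 1L), ] <- cbind(a, b, d1)
    row <- row + n_ring
    faces[row:(row + n_ring - 1L), ] <- cbind(a, d1, c1)
    row <- row + n_ring
  }
  surface <- tri_surface(verts, faces)
  list(surface = surface, truth = tube_truth(spec))
}

#' Specification of a two-chamber heart phantom
#'
#' A left ventricle modelled as an ellipsoid (long axis along +z, apex at
#' the -z pole), a left atrium as a sphere abutting the ventricular base
#' across the mitral plane, and an aorta tube leaving the LVOT on the +x
#' equator such that the constructed angle between the aortic axis and the
#' ventricular long axis equals `aosa_deg_true`. The aortic root (LVOT to
#' sinotubular junction) spans `root_length_mm`; the meshed aorta starts at
#' the STJ, as the clinical centerline does.
#'
#' @param aosa_deg_true target aorto-septal angle (degrees, in (0, 180)).
#' @param lv_semi_axes ellipsoid semi-axes (a, b, c) in mm, `c` the long
#'   axis.
#' @param aorta_spec a [tube_phantom_spec()] for the aorta beyond the STJ
#'   (built in the canonical frame; it is rotated/translated into place).
#' @param atrium_radius LA sphere radius (mm).
#' @param mesh_step chamber mesh resolution (mm).
#' @param root_length_mm LVOT-to-STJ distance (mm).
#' @param seed integer, recorded for provenance.
#' @return object of class `heart_phantom_spec`.
#' @export
heart_phantom_spec <- function(aosa_deg_true,
                               lv_semi_axes = c(25, 25, 45),
                               aorta_spec = tube_phantom_spec(
                                 list(list(kind = "straight", length = 60)),
                                 tube_radius = 12, mesh_step = 1),
                               atrium_radius = 18,
                               mesh_step = 1.5,
                               root_length_mm = 30,
                               seed = 1L) {
  if (aosa_deg_true <= 0 || aosa_deg_true >= 180)
    stop("aosa_deg_true must lie in (0, 180)")
  if (length(lv_semi_axes) != 3L || any(lv_semi_axes <= 0))
    stop("lv_semi_axes must be three positive lengths")
  structure(list(aosa_deg_true = aosa_deg_true,
                 lv_semi_axes = as.numeric(lv_semi_axes),
                 aorta_spec = aorta_spec,
                 atrium_radius = atrium_radius,
                 mesh_step = mesh_step,
                 root_length_mm = root_length_mm,
                 seed = as.integer(seed)),
            class = "heart_phantom_spec")
}

# UV-sphere triangulation of an ellipsoid, apex pole first.
ellipsoid_mesh <- function(semi_axes, center = c(0, 0, 0), step = 1.5) {
  a <- semi_axes[1]; b <- semi_axes[2]; c3 <- semi_axes[3]
  n_lat <- max(8L, ceiling(pi * max(semi_axes) / step))
  n_lon <- max(12L, ceiling(2 * pi * max(a, b) / step))
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1L)[-c(1L, n_lat + 1L)]
  lon <- (seq_len(n_lon) - 1L) / n_lon * 2 * pi
  grid <- expand.grid(lon = lon, lat = lat)
  verts <- cbind(a * cos(grid$lat) * cos(grid$lon),
                 b * cos(grid$lat) * sin(grid$lon),
                 c3 * sin(grid$lat))
  south <- c(0, 0, -c3)
  north <- c(0, 0, c3)
  verts <- rbind(south, verts, north)
  is_pole_s <- 1L
  offset <- 1L
  faces <- list()
  idx <- function(i_lat, j_lon) offset + (i_lat - 1L) * n_lon + ((j_lon - 1L) %% n_lon) + 1L
  # south cap
  faces[[1]] <- cbind(is_pole_s, idx(1L, 2:(n_lon + 1L)), idx(1L, 1:n_lon))
  # bands
  nb <- length(lat)
  for (i in seq_len(nb - 1L)) {
    j <- 1:n_lon
    faces[[length(faces) + 1L]] <- rbind(
      cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
      cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  }
  # north cap
  n_pole <- nrow(verts)
  faces[[length(faces) + 1L]] <- cbind(n_pole, idx(nb, 1:n_lon), idx(nb, 2:(n_lon + 1L)))
  f <- do.call(rbind, faces)
  tri_surface(sweep(verts, 2, center, "+"), f)
}

# Triangulated disc (fan) with exact area-weighted centroid at `center`.
disc_patch <- function(center, normal, radius, n = 48L) {
  basis <- orthonormal_basis(normal)
  alpha <- (seq_len(n) - 1L) / n * 2 * pi
  rim <- sweep(radius * (cos(alpha) %o% basis$u + sin(alpha) %o% basis$v),
               2, center, "+")
  verts <- rbind(center, rim)
  faces <- cbind(1L, 1L + seq_len(n), 1L + c(2:n, 1L))
  patch <- tri_surface(verts, faces)
  structure(list(parent_labels = c("synthetic", "synthetic"),
                 patch = patch, centroid = surface_centroid(patch)),
            class = "interface_surface")
}

#' Generate a two-chamber heart phantom with known aorto-septal angle
#'
#' Builds the LV/LA/aorta meshes, the analytic mitral and LVOT interface
#' patches, the true landmarks (apex, STJ, aorta inlet/outlet seeds), and
#' the ground truth (the constructed AoSA plus the aorta tube truth).
#' Optionally voxelizes the three structures into a [label_volume()] at
#' `voxel_mm` spacing for the full mask-to-mesh pipeline route.
#'
#' @param spec a [heart_phantom_spec()].
#' @param voxelize logical; also build the label volume.
#' @param voxel_mm voxel spacing (mm) when voxelizing.
#' @return list with `meshes` (named list: aorta, left_ventricle,
#'   left_atrium), `interfaces` (named list: lvot, mitral), `landmarks`
#'   (named list), `truth` (aorta tube truth plus `aosa_deg`,
#'   `stj_point`, `aorta_direction`), and optionally `volume`.
#' @export
make_heart <- function(spec, voxelize = FALSE, voxel_mm = 1) {
  a <- spec$lv_semi_axes[1]; b <- spec$lv_semi_axes[2]; c3 <- spec$lv_semi_axes[3]
  ra <- spec$atrium_radius
  alpha_deg <- spec$aosa_deg_true
  alpha <- alpha_deg * pi / 180
  z_m <- 0.6 * c3                       # mitral plane height
  la_center <- c(0, 0, z_m + 0.6 * ra)  # sphere overlaps the plane
  r_mitral <- sqrt(ra^2 - (0.6 * ra)^2) # radius of the sphere/plane disc
  q <- c(a, 0, 0)                       # LVOT centre on the +x equator
  d <- c(sin(alpha), 0, cos(alpha))     # aortic axis direction (unit)
  stj <- q + spec$root_length_mm * d
  # aorta mesh: canonical tube rotated so (0,0,1) -> d, then moved to STJ
  tube <- make_tube(spec$aorta_spec)
  Rot <- rotation_y(alpha)
  aorta <- transform_surface(tube$surface, Rot, stj)
  truth <- tube$truth
  truth$centerline_points <- sweep(truth$centerline_points %*% t(Rot), 2, stj, "+")
  truth$aosa_deg <- alpha_deg
  truth$stj_point <- stj
  truth$aorta_direction <- d
  lv <- ellipsoid_mesh(spec$lv_semi_axes, step = spec$mesh_step)
  la <- ellipsoid_mesh(rep(ra, 3L), center = la_center, step = spec$mesh_step)
  rt <- spec$aorta_spec$tube_radius
  interfaces <- list(
    lvot = disc_patch(q, d, rt),
    mitral = disc_patch(c(0, 0, z_m), c(0, 0, 1), r_mitral))
  aorta_end <- truth$centerline_points[nrow(truth$centerline_points), ]
  landmarks <- list(
    apex_seed = landmark("apex_seed", c(0, 0, -c3)),
    stj_point = landmark("stj_point", stj),
    inlet_seed = landmark("inlet_seed", stj),
    outlet_seed = landmark("outlet_seed", aorta_end))
  out <- list(meshes = list(aorta = aorta, left_ventricle = lv,
                            left_atrium = la),
              interfaces = interfaces, landmarks = landmarks, truth = truth)
  if (voxelize)
    out$volume <- voxelize_heart(spec, q, d, la_center, z_m, voxel_mm)
  out
}

rotation_y <- function(alpha) {
  matrix(c(cos(alpha), 0, -sin(alpha),
           0, 1, 0,
           sin(alpha), 0, cos(alpha)), 3L, 3L)
  # maps (0,0,1) to (sin a, 0, cos a)
}

# Analytic voxelization of the three structures. The aortic root (cylinder
# from just inside the LV surface up to the STJ and beyond, following the
# centerline stations) is part of the aorta label so that the LV/aorta
# adjacency defines the LVOT interface.
voxelize_heart <- function(spec, q, d, la_center, z_m, voxel_mm) {
  a <- spec$lv_semi_axes[1]; b <- spec$lv_semi_axes[2]; c3 <- spec$lv_semi_axes[3]
  ra <- spec$atrium_radius
  rt <- spec$aorta_spec$tube_radius
  # aorta centerline stations in world coordinates (root + tube)
  st <- tube_centerline_stations(spec$aorta_spec, step = min(1, voxel_mm))
  Rot <- rotation_y(spec$aosa_deg_true * pi / 180)
  stj <- q + spec$root_length_mm * d
  tube_pts <- sweep(st$points %*% t(Rot), 2, stj, "+")
  root_u <- seq(-2, spec$root_length_mm, by = min(1, voxel_mm))
  root_pts <- sweep(root_u %o% d, 2, q, "+")
  cl <- rbind(root_pts, tube_pts)
  all_pts <- rbind(cl, c(0, 0, -c3), la_center + ra, la_center - ra,
                   c(a, b, c3), -c(a, b, c3))
  lo <- apply(all_pts, 2, min) - (rt + 5)
  hi <- apply(all_pts, 2, max) + (rt + 5)
  dims <- ceiling((hi - lo) / voxel_mm) + 1L
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- lo
  gx <- lo[1] + (seq_len(dims[1]) - 1L) * voxel_mm
  gy <- lo[2] + (seq_len(dims[2]) - 1L) * voxel_mm
  gz <- lo[3] + (seq_len(dims[3]) - 1L) * voxel_mm
  X <- array(rep(gx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(gy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(gz, each = dims[1] * dims[2]), dims)
  in_ellipsoid <- (X / a)^2 + (Y / b)^2 + (Z / c3)^2 <= 1
  lv_mask <- in_ellipsoid & Z < z_m
  la_mask <- ((X - la_center[1])^2 + (Y - la_center[2])^2 +
              (Z - la_center[3])^2 <= ra^2) & Z >= z_m
  # aorta: within rt of the polyline cl, outside the LV region
  ao_mask <- array(FALSE, dims)
  pts_flat <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  # restrict the distance test to a bounding box around the aorta
  alo <- apply(cl, 2, min) - rt - 2 * voxel_mm
  ahi <- apply(cl, 2, max) + rt + 2 * voxel_mm
  inbox <- which(pts_flat[, 1] >= alo[1] & pts_flat[, 1] <= ahi[1] &
                 pts_flat[, 2] >= alo[2] & pts_flat[, 2] <= ahi[2] &
                 pts_flat[, 3] >= alo[3] & pts_flat[, 3] <= ahi[3])
  if (length(inbox) > 0L) {
    d2min <- rep(Inf, length(inbox))
    sub <- pts_flat[inbox, , drop = FALSE]
    stride <- max(1L, floor(nrow(cl) / 400))
    cl_s <- cl[seq(1L, nrow(cl), by = stride), , drop = FALSE]
    for (i in seq_len(nrow(cl_s))) {
      d2 <- (sub[, 1] - cl_s[i, 1])^2 + (sub[, 2] - cl_s[i, 2])^2 +
        (sub[, 3] - cl_s[i, 3])^2
      d2min <- pmin(d2min, d2)
    }
    ao_mask[inbox[d2min <= rt^2]] <- TRUE
  }
  ao_mask <- ao_mask & !lv_mask
  vox <- array(0L, dims)
  vox[lv_mask] <- 2L
  vox[la_mask] <- 3L
  vox[ao_mask] <- 1L
  label_volume(vox, affine,
               c(aorta = 1L, left_ventricle = 2L, left_atrium = 3L))
}
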