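# Shared fixture builders: everything is generated in code at test time.

# Unit cube as 12 triangles (closed, outward-oriented).
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  list(vertices = v, faces = f)
}

# Straight open cylinder phantom (axis +z from 0 to height).
cylinder_phantom <- function(height = 80, radius = 15, step = 1) {
  make_tube(tube_phantom_spec(
    list(list(kind = "straight", length = height)),
    tube_radius = radius, mesh_step = step))
}

# Planar bend phantom.
arc_phantom <- function(R = 40, r = 10, theta = pi / 2, step = 1,
                        lead = NULL) {
  segs <- list()
  if (!is.null(lead)) segs <- list(list(kind = "straight", length = lead))
  segs <- c(segs, list(list(kind = "arc", bend_radius = R, angle = theta)))
  make_tube(tube_phantom_spec(segs, tube_radius = r, mesh_step = step))
}

# Run the geometric pipeline on a tube phantom; returns measured metrics.
measure_tube <- function(tb, n_levels = 100, samples = 64) {
  tr <- tb$truth
  inlet <- tr$centerline_points[nrow(tr$centerline_points), ]
  outlet <- tr$centerline_points[1L, ]
  f <- solve_harmonic(tb$surface, inlet, outlet)
  iso <- extract_isolines(f, n_levels)
  cl <- compute_centerline(f, iso)
  cl <- suppressMessages(cross_section_areas(cl, tb$surface))
  sm <- segment_metrics(cl)
  rings <- list(aosa:::loop_points(f$surface, f$inlet_loop),
                aosa:::loop_points(f$surface, f$outlet_loop))
  pp <- extremal_paths(iso, samples, end_rings = rings)
  list(field = f, isolines = iso, centerline = cl, segment = sm,
       paths = pp)
}

# Voxel ball label volume (spacing mm, radius mm, centred).
ball_volume <- function(radius = 20, spacing = 1, margin = 5) {
  ext <- radius + margin
  g <- seq(-ext, ext, by = spacing)
  n <- length(g)
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  vox <- array(0L, c(n, n, n))
  vox[X^2 + Y^2 + Z^2 <= radius^2] <- 1L
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -ext
  label_volume(vox, aff, c(ball = 1L))
}

# Independent ICC(2,1) oracle: variance components via stats::aov mean
# squares, with the textbook absolute-agreement formula.
icc_oracle_aov <- function(X) {
  n <- nrow(X); k <- ncol(X)
  df <- data.frame(y = as.vector(X),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Random rigid transform (rotation matrix + translation), seeded.
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0.2, 2.5)
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = stats::rnorm(3, sd = 20))
}

# Distance from a point to a closed polyline (minimum over segments).
point_to_polyline_dist <- function(p, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, "+")
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  proj <- a + t * ab
  min(sqrt(rowSums(sweep(proj, 2, p)^2)))
}
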