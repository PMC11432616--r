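test_that("straight cylinder centerline recovers the axis and its length", {
  h <- 80; r <- 15
  tb <- cylinder_phantom(height = h, radius = r)
  f <- solve_harmonic(tb$surface, c(0, 0, h), c(0, 0, 0))
  iso <- extract_isolines(f, 100)
  cl <- compute_centerline(f, iso)
  expect_lt(abs(max(cl$arc_length) / h - 1), 0.005)
  expect_lt(max(abs(cl$points[, 1:2])), 0.05)  # on-axis
  # uniform resampling: interior gaps equal the step
  gaps <- diff(cl$arc_length)
  expect_true(all(abs(gaps[-length(gaps)] - 0.5) < 1e-6))
})

test_that("arc centerline length matches R * theta", {
  tb <- arc_phantom(R = 40, r = 10, theta = pi / 2)
  m <- measure_tube(tb)
  expect_lt(abs(m$segment$length_L / (40 * pi / 2) - 1), 0.01)
})

test_that("cylinder cross-sections are circular, constant, and correctly sized", {
  h <- 60; r <- 15
  tb <- cylinder_phantom(height = h, radius = r)
  f <- solve_harmonic(tb$surface, c(0, 0, h), c(0, 0, 0))
  iso <- extract_isolines(f, 60)
  cl <- compute_centerline(f, iso)
  cl <- suppressMessages(cross_section_areas(cl, tb$surface))
  interior <- cl$arc_length > 2 & cl$arc_length < h - 2
  a <- cl$cross_section_area[interior]
  expect_true(all(!is.na(a)))
  expect_true(all(abs(a / (pi * r^2) - 1) < 0.01))
  expect_lt(diff(range(a)) / mean(a), 0.01)
})

test_that("elliptic tube sections recover pi * a * b", {
  # swept ellipse built directly: rings (a cos, b sin) along z
  a <- 14; b <- 9; h <- 50
  n_ring <- 72
  alpha <- (seq_len(n_ring) - 1) / n_ring * 2 * pi
  zs <- seq(0, h, by = 1)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(a * cos(alpha), b * sin(alpha), z)))
  faces <- do.call(rbind, lapply(seq_len(length(zs) - 1), function(i) {
    o <- (i - 1) * n_ring
    idx <- seq_len(n_ring)
    nxt <- c(2:n_ring, 1)
    rbind(cbind(o + idx, o + nxt, o + n_ring + nxt),
          cbind(o + idx, o + n_ring + nxt, o + n_ring + idx))
  }))
  tube <- tri_surface(verts, faces)
  f <- solve_harmonic(tube, c(0, 0, h), c(0, 0, 0))
  iso <- extract_isolines(f, 40)
  cl <- compute_centerline(f, iso)
  cl <- suppressMessages(cross_section_areas(cl, tube))
  mid <- which.min(abs(cl$arc_length - h / 2))
  expect_lt(abs(cl$cross_section_area[mid] / (pi * a * b) - 1), 0.02)
})

test_that("equivalent diameter inverts the circle-area formula", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(100 * pi), 20)
  expect_lt(abs(equivalent_diameter(706.86) - 30), 1e-3)
  expect_error(equivalent_diameter(-1), "positive")
})

test_that("segment metrics give the closed-form tortuosity", {
  # straight tube: T = 0
  tb <- cylinder_phantom(height = 60, radius = 12)
  m <- measure_tube(tb, n_levels = 60)
  expect_lt(abs(m$segment$tortuosity_T), 1e-3)
  # semicircular arc: T = pi/2 - 1
  tbs <- arc_phantom(R = 35, r = 7, theta = pi)
  ms <- measure_tube(tbs)
  expect_lt(abs(ms$segment$tortuosity_T / (pi / 2 - 1) - 1), 0.01)
  expect_error(segment_metrics(m$centerline, 10, 10), "s_start")
})

test_that("tortuosity definition is exact in the returned metrics", {
  tb <- arc_phantom(R = 50, r = 8, theta = 1.2, lead = 20)
  m <- measure_tube(tb)
  sm <- m$segment
  expect_equal(sm$tortuosity_T,
               sm$length_L / sm$endpoint_distance_D - 1)
  expect_gte(sm$length_L, sm$endpoint_distance_D)
})

test_that("mirror-image meshes give mirror-image centerlines", {
  tb <- arc_phantom(R = 40, r = 9, theta = 1.3)
  tr <- tb$truth
  inlet <- tr$centerline_points[nrow(tr$centerline_points), ]
  outlet <- tr$centerline_points[1, ]
  run_cl <- function(surf, pin, pout) {
    f <- solve_harmonic(surf, pin, pout)
    compute_centerline(f, extract_isolines(f, 60))
  }
  cl0 <- run_cl(tb$surface, inlet, outlet)
  M <- diag(c(-1, 1, 1))
  cl1 <- run_cl(transform_surface(tb$surface, M), as.numeric(M %*% inlet),
                as.numeric(M %*% outlet))
  expect_equal(cl1$points, cl0$points %*% M, tolerance = 1e-6)
})

test_that("tortuosity is invariant to rigid motion and uniform scaling", {
  tb <- arc_phantom(R = 45, r = 10, theta = 1.6)
  tr <- tb$truth
  inlet <- tr$centerline_points[nrow(tr$centerline_points), ]
  outlet <- tr$centerline_points[1, ]
  tort <- function(surf, pin, pout, scale = 1) {
    f <- solve_harmonic(surf, pin, pout)
    # mm-denominated knobs scale with the geometry
    cl <- compute_centerline(f, extract_isolines(f, 60),
                             smooth_window = 10 * scale,
                             resample_step = 0.5 * scale)
    segment_metrics(cl)$tortuosity_T
  }
  t0 <- tort(tb$surface, inlet, outlet)
  rig <- random_rigid(11)
  t1 <- tort(transform_surface(tb$surface, rig$R, rig$t),
             as.numeric(rig$R %*% inlet + rig$t),
             as.numeric(rig$R %*% outlet + rig$t))
  scaled <- tb$surface
  scaled$vertices <- 2.5 * scaled$vertices
  t2 <- tort(scaled, 2.5 * inlet, 2.5 * outlet, scale = 2.5)
  expect_equal(t1, t0, tolerance = 1e-6)
  expect_equal(t2, t0, tolerance = 1e-6)
})

test_that("moving-average smoothing never lengthens the polyline", {
  set.seed(3)
  for (i in 1:5) {
    tb <- arc_phantom(R = runif(1, 30, 60), r = 8, theta = runif(1, 0.8, 2))
    tr <- tb$truth
    f <- solve_harmonic(tb$surface,
                        tr$centerline_points[nrow(tr$centerline_points), ],
                        tr$centerline_points[1, ])
    iso <- extract_isolines(f, 60)
    cents <- t(vapply(iso$contours,
                      function(p) aosa:::polyline_centroid(p, closed = TRUE),
                      numeric(3)))
    raw_len <- path_length(cents)
    sm <- aosa:::smooth_polyline(cents, 10, method = "moving_average")
    expect_lte(path_length(sm), raw_len + 1e-9)
  }
})
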