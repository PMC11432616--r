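fake_interface <- function(centroid) {
  structure(list(parent_labels = c("a", "b"), patch = NULL,
                 centroid = centroid), class = "interface_surface")
}
fake_centerline <- function(points) {
  structure(list(points = points,
                 arc_length = c(0, cumsum(sqrt(rowSums(diff(points)^2)))),
                 cross_section_area = rep(NA_real_, nrow(points))),
            class = "centerline")
}

test_that("aortic axis runs from the LVOT centroid to the STJ", {
  cl <- fake_centerline(rbind(c(0, 0, 10), c(0, 0, 40)))
  ax <- aortic_axis(cl, fake_interface(c(0, 0, 0)))
  expect_equal(ax$direction, c(0, 0, 1))
  expect_equal(ax$origin, c(0, 0, 0))
  # translation invariance of the direction
  cl2 <- fake_centerline(rbind(c(5, -3, 12), c(5, -3, 40)))
  ax2 <- aortic_axis(cl2, fake_interface(c(5, -3, 2)))
  expect_equal(ax2$direction, c(0, 0, 1))
  expect_error(aortic_axis(cl, fake_interface(c(0, 0, 10))), "coincide")
})

test_that("ventricular axis runs from apex to mitral centroid and rotates with its inputs", {
  ax <- ventricular_axis(landmark("apex_seed", c(0, 0, -80)),
                         fake_interface(c(0, 0, 0)))
  expect_equal(ax$direction, c(0, 0, 1))
  rig <- random_rigid(5)
  ax2 <- ventricular_axis(as.numeric(rig$R %*% c(0, 0, -80) + rig$t),
                          fake_interface(as.numeric(rig$t)))
  expect_equal(ax2$direction, as.numeric(rig$R %*% c(0, 0, 1)),
               tolerance = 1e-12)
})

test_that("auto apex finds the far pole of an ellipsoidal ventricle", {
  lv <- aosa:::ellipsoid_mesh(c(25, 25, 45), step = 1.5)
  apex <- auto_apex(lv, c(0, 0, 27))
  expect_lt(sqrt(sum((apex$position - c(0, 0, -45))^2)), 2)
})

test_that("aosa reproduces closed-form angles and is symmetric", {
  ax <- function(d) aosa:::make_axis(c(0, 0, 0), d)
  expect_equal(aosa(ax(c(0, 0, 1)), ax(c(0, 0, 1)))$aosa_deg, 0)
  expect_equal(aosa(ax(c(0, 0, 1)), ax(c(0, 1, 0)))$aosa_deg, 90)
  expect_equal(aosa(ax(c(0, 0, 1)), ax(c(0, 1, 1) / sqrt(2)))$aosa_deg, 45)
  a1 <- ax(c(0.2, -0.5, 0.84)); a2 <- ax(c(-0.3, 0.6, 0.74))
  expect_equal(aosa(a1, a2)$aosa_deg, aosa(a2, a1)$aosa_deg)
})

test_that("the auto plane makes the projection exact", {
  set.seed(8)
  for (i in 1:20) {
    d1 <- rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
    d2 <- rnorm(3); d2 <- d2 / sqrt(sum(d2^2))
    ax <- function(d) aosa:::make_axis(c(0, 0, 0), d)
    direct <- acos(min(1, max(-1, sum(d1 * d2)))) * 180 / pi
    expect_equal(aosa(ax(d1), ax(d2))$aosa_deg, direct, tolerance = 1e-9)
  }
})

test_that("an explicit measurement plane is honored and degeneracy rejected", {
  ax <- function(d) aosa:::make_axis(c(0, 0, 0), d)
  # both axes in the x-z plane; project onto it explicitly
  got <- aosa(ax(c(0, 0, 1)), ax(c(1, 0, 1) / sqrt(2)),
              plane_normal = c(0, 1, 0))
  expect_equal(got$aosa_deg, 45, tolerance = 1e-9)
  expect_error(aosa(ax(c(0, 1, 0)), ax(c(1, 0, 0)),
                    plane_normal = c(0, 1, 0)), "degenerate")
  expect_error(aosa(ax(c(0, 0, 1)), ax(c(1, 0, 0)),
                    plane_normal = c(0, 2, 0)), "unit length")
})

test_that("straight-tube inclination equals the fixed chord angle with zero SD", {
  z <- seq(0, 40, by = 0.5)
  cl0 <- fake_centerline(cbind(0, 0, z))
  ax <- aosa:::make_axis(c(0, 0, -5), c(0, 0, 1))
  res <- ascending_inclination(cl0, ax)
  expect_equal(res$aai_deg, 0, tolerance = 1e-9)
  expect_equal(res$aai_sd_deg, 0, tolerance = 1e-9)
  tilt <- 15 * pi / 180
  cl15 <- fake_centerline(cbind(sin(tilt) * z, 0, cos(tilt) * z))
  res15 <- ascending_inclination(cl15, ax)
  expect_equal(res15$aai_deg, 15, tolerance = 1e-6)
  expect_lt(res15$aai_sd_deg, 1e-6)
  expect_error(ascending_inclination(fake_centerline(cbind(0, 0, c(0, 5))),
                                     ax), "shorter")
})

test_that("arc inclination matches the numeric chord-angle oracle", {
  # circular arc of radius R starting along the axis: the chord at arc
  # length s subtends s / (2 R) radians to the starting tangent; solve with
  # the inlet at the arc start so the centerline begins there
  R <- 60
  tb <- arc_phantom(R = R, r = 8, theta = 1.2)
  tr <- tb$truth
  f <- solve_harmonic(tb$surface, tr$centerline_points[1, ],
                      tr$centerline_points[nrow(tr$centerline_points), ])
  cl <- compute_centerline(f, extract_isolines(f, 100))
  ax <- aosa:::make_axis(c(0, 0, 0), c(0, 0, 1))  # starting tangent
  got <- ascending_inclination(cl, ax, window_mm = 20)
  s <- cl$arc_length
  s <- s[s > 0 & s <= 20 + 1e-9]
  oracle <- mean(s / (2 * R) * 180 / pi)
  expect_lt(abs(got$aai_deg - oracle), 1)
})

test_that("repeated measurements are seeded and collapse at zero jitter", {
  h <- make_heart(heart_phantom_spec(110))
  m <- measure_tube(list(surface = h$meshes$aorta,
                         truth = h$truth), n_levels = 40)
  proto <- list(centerline = m$centerline,
                lvot_interface = h$interfaces$lvot,
                apex = h$landmarks$apex_seed,
                mitral_interface = h$interfaces$mitral)
  r0 <- repeat_measurement(proto, n_repeats = 5, jitter_mm = 0, seed = 4)
  expect_equal(diff(range(r0)), 0)
  expect_equal(coefficient_of_variation(c(r0[1], r0[1] + 1e-12, r0[1])),
               0, tolerance = 1e-9)
  r1 <- repeat_measurement(proto, n_repeats = 5, jitter_mm = 2, seed = 4)
  r2 <- repeat_measurement(proto, n_repeats = 5, jitter_mm = 2, seed = 4)
  expect_identical(r1, r2)
  expect_gt(stats::sd(r1), 0)
  # jitter regime: CV stays in the low-percent repeatability range
  expect_lt(100 * stats::sd(r1) / mean(r1), 2)
})
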