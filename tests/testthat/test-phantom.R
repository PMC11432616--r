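test_that("tube truth carries the closed forms", {
  tb <- cylinder_phantom(height = 80, radius = 15)
  tr <- tb$truth
  expect_equal(tr$total_length, 80)
  expect_equal(tr$tortuosity, 0)
  expect_equal(tr$diameter, 30)
  expect_equal(tr$outer_length, 80)
  expect_equal(tr$inner_length, 80)

  tq <- arc_phantom(R = 40, r = 10, theta = pi / 2)$truth
  expect_equal(tq$total_length, 20 * pi)
  expect_equal(tq$outer_length, 50 * pi / 2)
  expect_equal(tq$inner_length, 30 * pi / 2)
  expect_equal(tq$tortuosity, 20 * pi / (40 * sqrt(2)) - 1)
})

test_that("opposite-sign bends cancel in the generator extremes", {
  s_up <- list(kind = "arc", bend_radius = 40, angle = 0.8, direction = 1)
  s_dn <- list(kind = "arc", bend_radius = 40, angle = 0.8, direction = -1)
  tr <- make_tube(tube_phantom_spec(list(s_up, s_dn), tube_radius = 8))$truth
  expect_equal(tr$outer_length, tr$total_length)  # total signed turn is 0
  expect_equal(tr$inner_length, tr$total_length)
})

test_that("invalid tube specs are rejected", {
  expect_error(tube_phantom_spec(list(list(kind = "arc", bend_radius = 5,
                                           angle = 1)), tube_radius = 10),
               "self-intersecting")
  expect_error(tube_phantom_spec(list(list(kind = "straight", length = -1)),
                                 tube_radius = 5), "positive")
})

test_that("phantom meshes are deterministic and refine cleanly", {
  spec <- tube_phantom_spec(list(list(kind = "arc", bend_radius = 45,
                                      angle = 1.3)), tube_radius = 9,
                            mesh_step = 1, seed = 2)
  t1 <- make_tube(spec)
  t2 <- make_tube(spec)
  expect_identical(t1$surface$vertices, t2$surface$vertices)
  expect_identical(t1$surface$faces, t2$surface$faces)
  spec_f <- tube_phantom_spec(spec$segments, tube_radius = 9, mesh_step = 0.5)
  a1 <- surface_area(t1$surface)
  a2 <- surface_area(make_tube(spec_f)$surface)
  expect_lt(abs(a2 / a1 - 1), 0.005)
})

test_that("heart phantom pipeline recovers an orthogonal construction", {
  h <- make_heart(heart_phantom_spec(90))
  cfg <- list(meshes = h$meshes, interfaces = h$interfaces,
              landmarks = h$landmarks,
              repeats = list(n = 5, jitter_mm = 0, seed = 1))
  rep <- suppressMessages(run_measure(cfg))
  expect_lt(abs(rep$aosa_deg_mean - 90), 1)
})

test_that("heart phantom interfaces and landmarks encode the construction", {
  h <- make_heart(heart_phantom_spec(117.25))
  expect_equal(h$truth$aosa_deg, 117.25)
  # mitral centroid sits on the LV long axis at the mitral plane
  expect_lt(sqrt(sum((h$interfaces$mitral$centroid - c(0, 0, 27))^2)), 1e-6)
  # aortic direction is the unit vector at the constructed angle from +z
  d <- h$truth$aorta_direction
  expect_equal(acos(d[3]) * 180 / pi, 117.25, tolerance = 1e-9)
  expect_error(heart_phantom_spec(190), "aosa_deg_true")
})

test_that("voxelized heart recovers the angle through the full mask route", {
  hp <- heart_phantom_spec(117.25)
  h <- make_heart(hp, voxelize = TRUE, voxel_mm = 1)
  tr <- h$truth
  d <- tr$aorta_direction
  aend <- tr$centerline_points[nrow(tr$centerline_points), ]
  cfg <- list(volume = h$volume,
              clip_planes = list(list(point = tr$stj_point, normal = d),
                                 list(point = aend - 2 * d, normal = -d)),
              landmarks = list(apex_seed = h$landmarks$apex_seed,
                               inlet_seed = h$landmarks$inlet_seed,
                               outlet_seed = h$landmarks$outlet_seed),
              repeats = list(n = 5, jitter_mm = 0, seed = 1))
  rep <- suppressMessages(suppressWarnings(run_measure(cfg)))
  expect_lt(abs(rep$aosa_deg_mean - 117.25), 2)
  # the voxelized tube also reproduces its gross geometry
  expect_lt(abs(rep$segment$mean_diameter_mm - 24) / 24, 0.05)
})
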