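test_that("voxel ball surface matches the analytic sphere", {
  vol <- ball_volume(radius = 20, spacing = 1)
  surf <- mask_to_surface(vol, "ball")
  expect_length(surf$boundary_loops, 0L)
  expect_lt(abs(surface_area(surf) / (4 * pi * 20^2) - 1), 0.05)
  expect_lt(abs(abs(mesh_volume(surf)) / (4 / 3 * pi * 20^3) - 1), 0.05)
})

test_that("phantom volume recovery holds for radii down to 10 voxels", {
  for (r in c(10, 14)) {
    vol <- ball_volume(radius = r, spacing = 1)
    surf <- mask_to_surface(vol, "ball")
    expect_lt(abs(abs(mesh_volume(surf)) / (4 / 3 * pi * r^3) - 1), 0.05)
  }
})

test_that("Taubin smoothing preserves enclosed volume within 2 percent", {
  vol <- ball_volume(radius = 15, spacing = 1)
  raw <- mask_to_surface(vol, "ball", smoothing_iters = 0)
  sm <- taubin_smooth(raw, iterations = 30)
  expect_lt(abs(mesh_volume(sm) / mesh_volume(raw) - 1), 0.02)
})

test_that("the affine scales world coordinates linearly", {
  vol1 <- ball_volume(radius = 12, spacing = 1)
  vol2 <- vol1
  vol2$affine <- diag(c(2, 2, 2, 1)) %*% vol1$affine
  s1 <- mask_to_surface(vol1, "ball", smoothing_iters = 0)
  s2 <- mask_to_surface(vol2, "ball", smoothing_iters = 0)
  expect_equal(s2$vertices, 2 * s1$vertices, tolerance = 1e-12)
})

test_that("a tube mask touching the grid border yields an open surface", {
  n <- 41
  g <- seq_len(n) - 1
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  vox <- array(0L, c(n, n, n))
  vox[(X - 20)^2 + (Y - 20)^2 <= 8^2] <- 1L  # cylinder spanning all of z
  vol <- label_volume(vox, diag(4), c(tube = 1L))
  expect_warning(surf <- mask_to_surface(vol, "tube"), "border")
  expect_length(surf$boundary_loops, 2L)
})

test_that("empty labels are rejected", {
  vol <- ball_volume(radius = 10, spacing = 1)
  expect_error(mask_to_surface(vol, 7L), "empty")
  expect_error(interface_surface(vol, "ball", 7L), "empty")
})

test_that("half-space interface sits on the dividing plane", {
  n <- 20
  vox <- array(1L, c(n, n, n))
  Z <- array(rep(seq_len(n) - 1, each = n * n), c(n, n, n))
  vox[Z >= 10] <- 2L
  vol <- label_volume(vox, diag(4), c(lower = 1L, upper = 2L))
  isf <- interface_surface(vol, "lower", "upper")
  expect_equal(isf$centroid[3], 9.5, tolerance = 1e-9)  # between voxel centres
  expect_gt(surface_area(isf$patch), 0)
  # centroid equals the area-weighted triangle-centroid mean by construction
  expect_equal(isf$centroid, surface_centroid(isf$patch), tolerance = 1e-12)
})

test_that("disc-shaped interface recovers the analytic centre", {
  n <- 41
  g <- seq_len(n) - 1
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  vox <- array(0L, c(n, n, n))
  disc <- (X - 23)^2 + (Y - 17)^2 <= 9^2
  vox[disc & Z < 20] <- 1L
  vox[disc & Z >= 20] <- 2L
  vol <- label_volume(vox, diag(4), c(a = 1L, b = 2L))
  isf <- interface_surface(vol, "a", "b")
  expect_lt(sqrt(sum((isf$centroid - c(23, 17, 19.5))^2)), 0.5)
})

test_that("non-adjacent labels raise a no-interface error", {
  vox <- array(0L, c(10, 10, 10))
  vox[2, 2, 2] <- 1L
  vox[8, 8, 8] <- 2L
  vol <- label_volume(vox, diag(4), c(a = 1L, b = 2L))
  expect_error(interface_surface(vol, "a", "b"), "no shared interface")
})

test_that("NIfTI label volumes round-trip with their affine", {
  vol <- ball_volume(radius = 8, spacing = 1)
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(vol, path)
  back <- read_label_volume(path, c(ball = 1L))
  expect_equal(back$voxels, vol$voxels)
  expect_equal(matrix(as.numeric(back$affine), 4, 4),
               matrix(as.numeric(vol$affine), 4, 4), tolerance = 1e-5)
  unlink(path)
})
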