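test_that("noiseless cup phantoms threshold back to the exact solid", {
  spec <- phantom_spec(spacing = 2, wall = 4, noise_sd = 0, seed = 9)
  ph <- make_cup_shell(spec)
  mask <- threshold_segment(ph$volume, (spec$shell_hu + spec$background_hu) / 2)
  expect_identical(sum(mask$mask), sum(ph$volume$data == spec$shell_hu))
  expect_true(any(mask$mask))
})

test_that("phantoms are reproducible from spec and seed", {
  s <- phantom_spec(spacing = 2.2, wall = 4.5, seed = 123)
  a <- make_cup_shell(s)
  b <- make_cup_shell(s)
  expect_identical(a$volume$data, b$volume$data)
  c_ <- make_cup_shell(phantom_spec(spacing = 2.2, wall = 4.5, seed = 124))
  expect_false(identical(a$volume$data, c_$volume$data))
  # generation does not disturb the session RNG stream
  set.seed(77); x <- runif(1)
  set.seed(77); make_cup_shell(s); y <- runif(1)
  expect_identical(x, y)
})

test_that("the fissure cuts a gap of the configured width through the shell", {
  spec <- phantom_spec(spacing = 1, noise_sd = 0)
  ph <- make_cup_shell(spec)
  mask <- threshold_segment(ph$volume, 300)
  d <- dim(mask$mask)
  ax <- mask$origin[1] + (seq_len(d[1]) - 1) * mask$spacing[1]
  # walk along x through mid-wall depth on the fissured side (z = 0 row)
  yi <- which.min(abs(ax + (spec$outer_radius - spec$wall / 2)))
  zi <- which.min(abs(ax))
  row <- mask$mask[, yi, zi]
  runs <- rle(row)
  # the foreground is split by a background run about fissure_width wide
  gaps <- runs$lengths[!runs$values]
  gaps <- gaps[-c(1, length(gaps))]           # drop the outside air
  expect_true(any(abs(gaps * spec$spacing - spec$fissure_width) <= spec$spacing))
})

test_that("cup geometry constraints are validated", {
  expect_error(phantom_spec(cup_depth = 20, cup_rim_width = 26), "deeper")
  expect_error(phantom_spec(wall = 1, spacing = 1), "resolvable")
  expect_error(phantom_spec(outer_radius = 20), "does not fit")
})

test_that("sphere phantom truth is exact and its shell is hollow", {
  ph <- make_sphere_shell(radius = 18, wall = 3, spacing = 1, noise_sd = 0)
  r <- sqrt(rowSums(ph$truth$vertices^2))
  expect_true(all(abs(r - 18) < 1e-12))
  centre <- world_to_voxel(ph$volume, c(0, 0, 0))
  expect_lt(ph$volume$data[centre[1], centre[2], centre[3]], 300)
  mask <- threshold_segment(ph$volume, 300)
  mesh <- mask_to_mesh(mask)
  h <- max(closest_point(ph$truth, mesh$vertices)$distance)
  # the meshed shell includes the inner wall at radius - wall; every meshed
  # vertex still lies within wall + one voxel diagonal of the true sphere
  expect_lte(h, ph$volume$spacing[1] * sqrt(3) + 3)
  outer <- mesh$vertices[sqrt(rowSums(mesh$vertices^2)) > 18 - 1.5, , drop = FALSE]
  expect_lte(max(abs(sqrt(rowSums(outer^2)) - 18)), sqrt(3))
})

test_that("rigid phantom motion is an exact isometry", {
  mesh <- unit_icosphere(2)
  expect_identical(transform_phantom(mesh)$vertices, mesh$vertices)
  R <- rotation_z(0.9)
  t <- c(4, 5, -6)
  moved <- transform_phantom(mesh, R, t)
  back <- transform_phantom(moved, t(R), -as.vector(t(R) %*% t))
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-12)
  i <- c(1, 5, 9); j <- c(2, 7, 11)
  d0 <- sqrt(rowSums((mesh$vertices[i, ] - mesh$vertices[j, ])^2))
  d1 <- sqrt(rowSums((moved$vertices[i, ] - moved$vertices[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("phantom specs round-trip through the flat config format", {
  s <- phantom_spec(spacing = 1.7, wall = 3.5, seed = 5, fissure_count = 2)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_phantom_spec(s, f)
  back <- read_phantom_spec(f)
  expect_equal(unclass(back), unclass(s), tolerance = 1e-9)
  writeLines(c("outer_radius = 40", "bogus_key = 1"), f)
  expect_error(read_phantom_spec(f), "bogus_key")
})
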