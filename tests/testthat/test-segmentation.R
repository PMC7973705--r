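test_that("bone threshold recovers the noiseless shell exactly", {
  ph <- make_sphere_shell(radius = 12, wall = 3, spacing = 1, noise_sd = 0)
  vol <- ph$volume
  mask <- threshold_segment(vol, lower_hu = 300)
  truth <- vol$data >= (1000 + 40) / 2
  expect_identical(mask$mask, truth)
  expect_identical(dim(mask$mask), dim(vol$data))
  expect_identical(mask$spacing, vol$spacing)
})

test_that("the PLA window segments a scanned-print phantom exactly", {
  ph <- make_sphere_shell(radius = 10, wall = 2, shell_hu = -500,
                          background_hu = -1000, spacing = 1, noise_sd = 0)
  mask <- threshold_segment(ph$volume, lower_hu = -900, upper_hu = -200)
  expect_identical(mask$mask, ph$volume$data == -500)
  expect_gt(sum(mask$mask), 0)
})

test_that("threshold is monotone in the lower cutoff and handles empty masks", {
  set.seed(5)
  vol <- voxel_volume(array(rnorm(8000, 200, 300), c(20, 20, 20)))
  cuts <- c(-100, 100, 300, 500)
  counts <- vapply(cuts, function(ct) sum(threshold_segment(vol, ct)$mask), 1)
  expect_true(all(diff(counts) <= 0))
  empty <- threshold_segment(vol, lower_hu = 1e5)
  expect_false(any(empty$mask))
  expect_error(mask_to_mesh(empty), "empty")
  expect_error(threshold_segment(vol, 300, 200), "below")
})

test_that("component selection matches a graph-based labeling oracle", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:4, 2:4, 2:4] <- TRUE     # 27-voxel cube
  m[8:9, 8:9, 8:9] <- TRUE     # 8-voxel cube
  mask <- label_mask(m)
  largest <- select_component(mask, "largest")
  lab <- oracle_components(m)
  big_label <- lab[3, 3, 3]
  expect_identical(largest$mask, lab == big_label)
  expect_identical(sum(largest$mask), 27L)

  seeded <- select_component(mask, "seeded", seed = c(8, 8, 8))
  expect_identical(seeded$mask, lab == lab[8, 8, 8])
  expect_identical(sum(seeded$mask), 8L)

  expect_error(select_component(mask, "seeded", seed = c(6, 6, 6)),
               "not foreground")
})

test_that("diagonally touching voxels form one 26-connected component", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # touches only across the corner
  sel <- select_component(label_mask(m), "largest")
  expect_identical(sum(sel$mask), 2L)
  single <- select_component(label_mask(m), "largest")
  expect_identical(single$mask, m)  # single component: unchanged
})

test_that("a solid ball mask meshes to a closed sphere of the right radius", {
  d <- 45L
  ax <- seq_len(d) - (d + 1) / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  m <- array(sqrt(g$x^2 + g$y^2 + g$z^2) <= 20, c(d, d, d))
  mask <- label_mask(m, origin = -(d - 1) / 2 * c(1, 1, 1))
  mesh <- mask_to_mesh(mask)
  r <- sqrt(rowSums(mesh$vertices^2))
  expect_true(all(abs(r - 20) <= sqrt(3)))   # one voxel diagonal
  cm <- check_manifold(mesh)
  expect_true(cm$watertight)
  expect_true(cm$orientation_consistent)
  expect_gt(mesh_volume(mesh), 0)            # outward winding
})

test_that("a two-component mask meshes into two surface components", {
  m <- array(FALSE, c(14, 14, 14))
  m[2:5, 2:5, 2:5] <- TRUE
  m[9:12, 9:12, 9:12] <- TRUE
  mesh <- mask_to_mesh(label_mask(m))
  expect_identical(max(mesh_components(mesh)), 2L)
})

test_that("meshed masks enclose all their foreground voxel centres", {
  ph <- make_sphere_shell(radius = 9, wall = 3, spacing = 1, noise_sd = 0)
  mask <- threshold_segment(ph$volume, 300)
  mesh <- mask_to_mesh(mask)
  centres <- voxel_to_world(mask, which(mask$mask, arr.ind = TRUE))
  expect_true(all(point_in_mesh(mesh, centres)))
})
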