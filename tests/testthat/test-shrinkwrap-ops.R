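test_that("the initial sphere strictly encloses the target", {
  cube <- mask_to_mesh(label_mask(array(TRUE, c(3, 3, 3)),
                                  spacing = c(20, 20, 20)))
  cfg <- filter_config()
  s <- init_sphere(cube, cfg)
  expect_true(check_manifold(s)$watertight)
  expect_true(all(point_in_mesh(s, cube$vertices)))
  centre <- colMeans(apply(cube$vertices, 2, range))
  r <- sqrt(rowSums(sweep(s$vertices, 2, centre)^2))
  bb <- apply(cube$vertices, 2, range)
  expect_equal(mean(r), cfg$sphere_margin * sqrt(sum((bb[2, ] - bb[1, ])^2)) / 2,
               tolerance = 1e-6)
  # doubling the margin doubles the radius
  s2 <- init_sphere(cube, filter_config(sphere_margin = 2.4))
  r2 <- sqrt(rowSums(sweep(s2$vertices, 2, centre)^2))
  expect_equal(mean(r2) / mean(r), 2, tolerance = 1e-9)
})

test_that("a shrink step lands vertices exactly at the offset", {
  plane <- surface_mesh(rbind(c(-100, -100, 0), c(100, -100, 0),
                              c(100, 100, 0), c(-100, 100, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  s <- surface_mesh(rbind(c(0, 0, 55), c(3, 4, 20), c(1, 1, 15)),
                    matrix(c(1L, 2L, 3L), 1))
  out <- shrink_step(s, plane, 15)
  expect_equal(out$vertices[1, ], c(0, 0, 15))
  expect_equal(out$vertices[2, ], c(3, 4, 15))
  expect_equal(out$vertices[3, ], c(1, 1, 15))  # already at offset: unchanged

  zero <- shrink_step(s, plane, 0)
  expect_equal(zero$vertices[, 3], c(0, 0, 0))
})

test_that("offset consistency holds against a convex target", {
  M <- unit_icosphere(4)
  M$vertices <- M$vertices * 25
  S <- unit_icosphere(3)
  S$vertices <- S$vertices * 60
  out <- shrink_step(S, M, 15)
  d <- closest_point(M, out$vertices)$distance
  expect_true(all(abs(d - 15) < 1e-6))
})

test_that("an offset shrinkwrap phase converges to the offset surface", {
  M <- test_sphere_mesh()                      # hollow shell, outer radius 24
  cfg <- filter_config()
  S <- init_sphere(M, cfg)
  wrapped <- shrinkwrap_phase(S, M, offset = 15, iterations = 3,
                              remesh_voxel = cfg$remesh_voxel)
  d <- closest_point(M, wrapped$vertices)$distance
  diag <- cfg$remesh_voxel * sqrt(3)
  expect_true(all(abs(d - 15) <= diag))

  hugging <- shrinkwrap_phase(wrapped, M, offset = 0, iterations = 3,
                              remesh_voxel = cfg$remesh_voxel,
                              final_remesh = FALSE)
  expect_lte(max(closest_point(M, hugging$vertices)$distance), 1e-6)
})

test_that("long-edge separation routes exactly the stretched faces", {
  ico <- unit_icosphere(3)
  ico$vertices <- ico$vertices * 10            # all edges far below 20
  sep <- separate_long_edge_faces(ico, 20)
  expect_identical(n_faces(sep$sub), 0L)
  expect_identical(n_faces(sep$rest), n_faces(ico))

  stretched <- ico
  stretched$vertices[1, ] <- stretched$vertices[1, ] * 4  # pull one vertex out
  sep2 <- separate_long_edge_faces(stretched, 20)
  el <- edge_lengths(sep2$rest)
  expect_true(all(el <= 20))
  expect_gt(n_faces(sep2$sub), 0)
  # faces are partitioned, none lost
  expect_identical(n_faces(sep2$sub) + n_faces(sep2$rest), n_faces(stretched))
})

test_that("separation then reattachment is the identity up to vertex order", {
  ico <- unit_icosphere(3)
  stretched <- ico
  stretched$vertices[1, ] <- stretched$vertices[1, ] * 4
  stretched$vertices <- stretched$vertices * 10
  sep <- separate_long_edge_faces(stretched, 20)
  sub <- sep$sub
  attr(sub, "edge_splits") <- NULL
  merged <- reattach(sep, sub)
  expect_identical(n_faces(merged), n_faces(stretched))
  shared <- length(attr(sep, "shared"))
  expect_identical(n_vertices(merged),
                   n_vertices(sep$rest) + n_vertices(sep$sub) - shared)
  expect_equal(sort(round(as.vector(merged$vertices), 9)),
               sort(round(as.vector(stretched$vertices), 9)))
  cm <- check_manifold(merged)
  expect_true(cm$watertight)
  expect_true(cm$orientation_consistent)
})

test_that("reattachment after subdivision stays edge-manifold", {
  ico <- unit_icosphere(3)
  ico$vertices <- ico$vertices * 10
  stretched <- ico
  stretched$vertices[1, ] <- stretched$vertices[1, ] * 4
  sep <- separate_long_edge_faces(stretched, 20)
  sub2 <- loop_subdivide(sep$sub, 5)
  merged <- reattach(sep, sub2)
  cm <- check_manifold(merged)
  expect_true(cm$watertight)
  expect_true(cm$orientation_consistent)
})

test_that("projection obeys the length window and isolation pruning", {
  plane <- surface_mesh(rbind(c(-100, -100, 0), c(100, -100, 0),
                              c(100, 100, 0), c(-100, 100, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  # dense patch 10 mm above the plane: hits 1 mm apart, all accepted
  patch <- flat_patch(11, 10)
  patch$vertices[, 3] <- 10
  pr <- project_vertices(patch, plane, filter_config())
  expect_true(all(pr$candidates$accepted))
  expect_true(all(abs(pr$mesh$vertices[, 3]) < 1e-9))
  expect_true(all(abs(pr$candidates$length - 10) < 1e-9))
  # candidate bookkeeping: hit = origin + length * direction
  with(pr$candidates, {
    expect_equal(hit_x, origin_x + length * normal_x, tolerance = 1e-6)
    expect_equal(hit_z, origin_z + length * normal_z, tolerance = 1e-6)
  })

  # one huge triangle: its three hits are mutually ~30 mm apart -> pruned
  lone <- surface_mesh(rbind(c(0, 0, 10), c(30, 0, 10), c(0, 30, 10)),
                       matrix(c(1L, 2L, 3L), 1))
  pr2 <- project_vertices(lone, plane, filter_config())
  expect_false(any(pr2$candidates$accepted))
  expect_true(all(pr2$candidates$isolation >= 2))
  expect_identical(pr2$mesh$vertices, lone$vertices)

  # ray length beyond the window: not moved
  far <- flat_patch(3, 4)
  far$vertices[, 3] <- 150
  pr3 <- project_vertices(far, plane, filter_config())
  expect_false(any(pr3$candidates$accepted))
  expect_identical(pr3$mesh$vertices, far$vertices)
})

test_that("gap deletion removes exactly the far vertices", {
  M <- test_sphere_mesh()
  S <- shrinkwrap_phase(init_sphere(M, filter_config()), M, 0, 3, 2.5)
  near <- delete_far_vertices(S, M, gap = 25)
  expect_identical(near$faces, S$faces)        # everything well within 25 mm
  expect_identical(near$vertices, S$vertices)

  trimmed <- delete_far_vertices(S, M, gap = 1)
  d <- closest_point(M, trimmed$vertices)$distance
  expect_true(all(d < 1))
  # a surface nowhere near the target loses every vertex
  far_away <- transform_phantom(S, translation = c(500, 0, 0))
  expect_error(delete_far_vertices(far_away, M, gap = 1), "farther")
})

test_that("solidification produces a watertight shell of exact thickness", {
  ico <- unit_icosphere(3)
  ico$vertices <- ico$vertices * 20
  keep <- apply(ico$faces, 1, function(f) all(ico$vertices[f, 3] > -1e-9))
  hemi <- subset_faces(ico, keep)
  solid <- solidify(hemi, 0.8)
  cm <- check_manifold(solid)
  expect_true(cm$watertight)
  expect_true(cm$orientation_consistent)
  nv <- n_vertices(solid) / 2
  pair_d <- sqrt(rowSums((solid$vertices[seq_len(nv) + nv, , drop = FALSE] -
                          solid$vertices[seq_len(nv), , drop = FALSE])^2))
  expect_true(all(abs(pair_d - 0.8) < 1e-6))
  # two triangles per boundary edge close the rim
  b <- attr(solid, "boundary_edge_count")
  expect_identical(n_faces(solid), 2L * n_faces(hemi) + 2L * b)
})

test_that("a solidified flat patch encloses area times thickness", {
  patch <- flat_patch(6, 10)                   # 10 x 10 mm, area 100
  solid <- solidify(patch, 0.8)
  expect_true(check_manifold(solid)$watertight)
  expect_equal(abs(mesh_volume(solid)), 100 * 0.8, tolerance = 0.05 * 80)
})

test_that("degenerate pipeline inputs are rejected", {
  tiny <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1L, 2L, 3L), 1))
  expect_error(run_pipeline(tiny), "degenerate")
})
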