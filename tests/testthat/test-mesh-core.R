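test_that("closest point on an axis-aligned plane is exact", {
  plane <- surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  cp <- closest_point(plane, c(5, 5, 7))
  expect_equal(drop(cp$point), c(5, 5, 0))
  expect_equal(cp$distance, 7)
  expect_equal(drop(cp$direction), c(0, 0, -1))

  on_surface <- closest_point(plane, c(3, 3, 0))
  expect_equal(on_surface$distance, 0)
  expect_equal(drop(on_surface$direction), c(0, 0, 0))

  expect_error(closest_point(surface_mesh(matrix(0, 1, 3),
                                          matrix(integer(0), 0, 3)),
                             c(0, 0, 0)), "no faces")
})

test_that("BVH closest point matches the exhaustive oracle on random queries", {
  soup <- random_triangle_soup(50, seed = 7)
  set.seed(8)
  q <- matrix(runif(3 * 250, -14, 14), ncol = 3)
  got <- closest_point(soup, q)
  for (i in seq_len(nrow(q))) {
    ref <- oracle_closest_point(soup, q[i, ])
    expect_equal(got$distance[i], ref$distance, tolerance = 1e-9)
  }
})

test_that("vertex normals behave on spheres, flat patches and under flipping", {
  ico <- unit_icosphere(3)
  vn <- vertex_normals(ico)
  expect_true(all(abs(rowSums(vn * ico$vertices) - 1) < 1e-3))

  patch <- flat_patch(4, 6)
  pn <- vertex_normals(patch)
  expect_equal(pn, matrix(rep(c(0, 0, 1), each = n_vertices(patch)), ncol = 3),
               tolerance = 1e-12)

  flipped <- surface_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  expect_equal(vertex_normals(flipped), -vn, tolerance = 1e-12)

  # all normals of a convex mesh point away from the centroid
  centred <- sweep(ico$vertices, 2, colMeans(ico$vertices))
  expect_true(all(rowSums(vn * centred) > 0))
})

test_that("ray casting respects the open parameter window and matches the oracle", {
  plane <- surface_mesh(rbind(c(-50, -50, 0), c(50, -50, 0), c(50, 50, 0),
                              c(-50, 50, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  hit <- ray_intersect(plane, c(0, 0, 10), c(0, 0, -1))
  expect_true(hit$hit)
  expect_equal(hit$length, 10)
  expect_equal(drop(hit$point), c(0, 0, 0))

  miss <- ray_intersect(plane, c(0, 0, 10), c(0, 0, -1), t_max = 5)
  expect_false(miss$hit)

  soup <- random_triangle_soup(50, seed = 13)
  set.seed(14)
  o <- matrix(runif(3 * 200, -15, 15), ncol = 3)
  d <- matrix(rnorm(3 * 200), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  got <- ray_intersect(soup, o, d)
  for (i in seq_len(nrow(o))) {
    ref <- oracle_ray(soup, o[i, ], d[i, ])
    if (is.na(ref)) {
      expect_false(got$hit[i])
    } else {
      expect_true(got$hit[i])
      expect_equal(got$length[i], ref, tolerance = 1e-9)
    }
  }
})

test_that("manifold report distinguishes closed, punctured and non-solid meshes", {
  ico <- unit_icosphere(2)
  cm <- check_manifold(ico)
  expect_true(cm$watertight)
  expect_identical(cm$edge_defects, 0L)
  expect_true(cm$orientation_consistent)

  punctured <- surface_mesh(ico$vertices, ico$faces[-1, , drop = FALSE])
  cm2 <- check_manifold(punctured)
  expect_false(cm2$watertight)
  expect_identical(cm2$boundary_edges, 3L)

  run <- test_cup_run()
  expect_false(check_manifold(run$snapshots$F)$watertight)
})

test_that("mesh formats round-trip geometry", {
  cube_v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
  cube <- mask_to_mesh(label_mask(array(TRUE, c(2, 2, 2))))
  stl <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, stl)
  back <- read_mesh(stl)
  expect_identical(n_faces(back), n_faces(cube))
  expect_equal(sort(round(as.vector(back$vertices), 4)),
               sort(round(as.vector(cube$vertices), 4)), tolerance = 1e-4)
  expect_true(check_manifold(back)$watertight)

  ply <- withr::local_tempfile(fileext = ".ply")
  ico <- unit_icosphere(2)
  write_mesh(ico, ply)
  back <- read_mesh(ply)
  expect_identical(n_vertices(back), n_vertices(ico))
  expect_equal(back$vertices, ico$vertices, tolerance = 1e-12)
  expect_identical(back$faces, ico$faces)

  # OBJ of a non-manifold deleted-vertex model loads without error
  obj <- withr::local_tempfile(fileext = ".obj")
  open_mesh <- surface_mesh(ico$vertices, ico$faces[-(1:5), , drop = FALSE])
  write_mesh(open_mesh, obj)
  back <- read_mesh(obj)
  expect_identical(n_faces(back), n_faces(open_mesh))
  expect_equal(back$vertices, open_mesh$vertices, tolerance = 1e-12)

  expect_error(write_mesh(ico, "mesh.xyz"), "unknown mesh format")
})
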