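# Shared fixtures, computed once per test run and memoized.
# Phantom scale and grid spacing here are the package's test-scale study
# conditions (coarser grids than the 1 mm clinical default, same geometry).

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

test_cup_spec <- function() phantom_spec(spacing = 1.4)

test_cup_phantom <- function() memo_fixture("cup_phantom",
  make_cup_shell(test_cup_spec()))

test_cup_mesh <- function() memo_fixture("cup_mesh", {
  mask <- select_component(threshold_segment(test_cup_phantom()$volume, 300),
                           "largest")
  mask_to_mesh(mask)
})

test_cup_run <- function() memo_fixture("cup_run",
  run_pipeline(test_cup_mesh(), filter_config()))

test_sphere_phantom <- function() memo_fixture("sphere_phantom",
  make_sphere_shell(radius = 24, wall = 3.2, spacing = 1.6))

test_sphere_mesh <- function() memo_fixture("sphere_mesh", {
  mask <- select_component(threshold_segment(test_sphere_phantom()$volume, 300),
                           "largest")
  mask_to_mesh(mask)
})

test_sphere_run <- function() memo_fixture("sphere_run",
  run_pipeline(test_sphere_mesh(), filter_config()))

# fissured mini-phantom run in the validity regime of the gap-preservation
# bound: fissure width 3 mm > 2 * (gap + remesh voxel diagonal) requires a
# remesh voxel below 3 mm / (2 sqrt 3) - gap/sqrt3 ~ 0.29 mm
test_fissure_spec <- function() phantom_spec(
  outer_radius = 20, wall = 2.4, cup_depth = 10.5, cup_rim_width = 8,
  fissure_width = 3, fissure_count = 1, spacing = 0.8, noise_sd = 20)

test_fissure_mesh <- function() memo_fixture("fissure_mesh", {
  ph <- make_cup_shell(test_fissure_spec())
  mask <- select_component(threshold_segment(ph$volume, 300), "largest")
  mask_to_mesh(mask)
})

test_fissure_run <- function() memo_fixture("fissure_run",
  run_pipeline(test_fissure_mesh(), filter_config(remesh_voxel = 0.25)))

# faces of `mesh` whose vertices all sit inside the open span of fissure 1
# (normal along x, guarded region at low y) and that cross its midplane
fissure_crossing_faces <- function(mesh, spec, end_margin = 2) {
  guard <- spec$cup_rim_width + spec$wall + 2
  v <- mesh$vertices; f <- mesh$faces
  xs <- cbind(v[f[, 1], 1], v[f[, 2], 1], v[f[, 3], 1])
  ys <- cbind(v[f[, 1], 2], v[f[, 2], 2], v[f[, 3], 2])
  apply(xs, 1, min) < 0 & apply(xs, 1, max) > 0 &
    apply(ys, 1, max) < -(guard + end_margin)
}

# a small flat square patch in the z = 0 plane, outward normal +z
flat_patch <- function(n = 5, size = 10) {
  ax <- seq(0, size, length.out = n)
  g <- as.matrix(expand.grid(x = ax, y = ax))
  verts <- cbind(g, 0)
  id <- function(i, j) (j - 1) * n + i
  faces <- NULL
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    faces <- rbind(faces, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                   c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(verts, faces)
}

unit_icosphere <- function(subdiv = 3) bonewrap:::icosphere(subdiv)

# parametric closed torus, major radius R, minor r
torus_mesh <- function(R = 20, r = 8, nu = 48, nv = 24) {
  u <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  v <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  g <- expand.grid(u = u, v = v)
  verts <- cbind((R + r * cos(g$v)) * cos(g$u),
                 (R + r * cos(g$v)) * sin(g$u),
                 r * sin(g$v))
  id <- function(i, j) ((j - 1) %% nv) * nu + ((i - 1) %% nu) + 1
  faces <- NULL
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    faces <- rbind(faces, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                   c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(verts, faces)
}

mesh_genus <- function(mesh) {
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  ne <- length(edge_lengths(mesh))
  (2 - (nv - ne + nf)) / 2
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}
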