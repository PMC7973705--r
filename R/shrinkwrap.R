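#' Surface-filter configuration
#'
#' Parameters of the shrinkwrap surface-filtering pipeline. Defaults are the
#' experimentally determined settings that work for hemipelvis models:
#'
#' * `offset` (O, 15 mm): distance kept between surface and segmented model
#'   during the first wrap phase.
#' * `edge_threshold` (E_T, 20 mm): faces with a longer edge are routed to the
#'   projection step.
#' * `subdiv_edge` (E_S, 5 mm): maximal edge length after Loop subdivision of
#'   the separated faces.
#' * `proj_min`, `proj_max` (P_min 0 mm, P_max 100 mm): open window for the
#'   projection ray length, suppressing failed projections to far-off mesh
#'   elements.
#' * `prune_dist` (D, 2 mm): a projected vertex is only accepted when its
#'   nearest projected neighbour is closer than this, pruning isolated hits
#'   inside narrow gaps.
#' * `gap` (G, 1 mm): vertices farther than this from the segmented model
#'   after the final wrap are deleted, which keeps fracture lines open.
#' * `thickness` (T, 0.8 mm): shell thickness of the solidification step.
#' * `phase1_iters` (3) and `phase2_iters` (7): shrinkwrap iteration counts
#'   with offset `O` and offset 0 respectively.
#' * `remesh_voxel` (2.5 mm = `subdiv_edge / 2`): voxel size of the
#'   remeshing; exposed because the resolution of the original remeshing is a
#'   free parameter.
#' * `sphere_margin` (1.2) and `sphere_edge` (8 mm): radius factor (times half
#'   the bounding-box diagonal) and edge length of the initial sphere.
#'
#' @param offset,edge_threshold,subdiv_edge,proj_min,proj_max,prune_dist,gap,thickness
#'   Lengths in mm as described above.
#' @param phase1_iters,phase2_iters Iteration counts (>= 1).
#' @param remesh_voxel,sphere_edge Lengths in mm.
#' @param sphere_margin Dimensionless radius factor.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(offset = 15, edge_threshold = 20, subdiv_edge = 5,
                          proj_min = 0, proj_max = 100, prune_dist = 2,
                          gap = 1, thickness = 0.8, phase1_iters = 3,
                          phase2_iters = 7, remesh_voxel = 2.5,
                          sphere_margin = 1.2, sphere_edge = 8) {
  cfg <- list(offset = offset, edge_threshold = edge_threshold,
              subdiv_edge = subdiv_edge, proj_min = proj_min,
              proj_max = proj_max, prune_dist = prune_dist, gap = gap,
              thickness = thickness, phase1_iters = as.integer(phase1_iters),
              phase2_iters = as.integer(phase2_iters),
              remesh_voxel = remesh_voxel, sphere_margin = sphere_margin,
              sphere_edge = sphere_edge)
  lens <- c("offset", "edge_threshold", "subdiv_edge", "proj_max",
            "prune_dist", "gap", "thickness", "remesh_voxel", "sphere_margin",
            "sphere_edge")
  for (nm in lens) if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (cfg$proj_min < 0) stop("proj_min must be >= 0")
  if (cfg$proj_min >= cfg$proj_max) stop("proj_min must be below proj_max")
  if (cfg$phase1_iters < 1L || cfg$phase2_iters < 1L)
    stop("iteration counts must be >= 1")
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a filter configuration file
#'
#' Flat `key = value` text format; keys are the `filter_config()` argument
#' names. Unknown keys raise an error naming the key.
#'
#' @param path Config file path.
#' @param config A `filter_config`.
#' @return `read_filter_config()` returns a `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[= \t]+")
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  known <- names(formals(filter_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown configuration key: ", paste(bad, collapse = ", "))
  if (anyNA(vals)) stop("non-numeric configuration value for key: ",
                        paste(keys[is.na(vals)], collapse = ", "))
  do.call(filter_config, as.list(stats::setNames(vals, keys)))
}

#' @rdname read_filter_config
#' @export
write_filter_config <- function(config, path) {
  stopifnot(inherits(config, "filter_config"))
  writeLines(sprintf("%s = %.10g", names(config),
                     vapply(config, as.numeric, 1)), path)
  invisible(path)
}

# ---- initial sphere -------------------------------------------------------

# unit icosphere with `subdiv` midpoint subdivisions
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v, f)
  for (s in seq_len(subdiv)) {
    mesh <- subdivide_midpoint(mesh)
    mesh$vertices <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  }
  mesh
}

# 1:4 split at edge midpoints (no smoothing); returns mesh, with the split
# records (v1, v2, midpoint) in attribute "splits"
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  he <- mesh_half_edges(mesh)
  keys <- edge_keys(he, nv)
  uk <- unique(keys)
  eidx <- match(keys, uk)                 # per half-edge, unique edge id
  first <- !duplicated(keys)
  ue <- he[first, , drop = FALSE]         # one representative per edge
  mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  midid <- nv + seq_len(nrow(ue))
  nf <- nrow(f)
  m12 <- midid[eidx[seq_len(nf)]]
  m23 <- midid[eidx[nf + seq_len(nf)]]
  m31 <- midid[eidx[2 * nf + seq_len(nf)]]
  nfaces <- rbind(cbind(f[, 1], m12, m31),
                  cbind(f[, 2], m23, m12),
                  cbind(f[, 3], m31, m23),
                  cbind(m12, m23, m31))
  out <- surface_mesh(rbind(v, mid), nfaces)
  attr(out, "splits") <- cbind(ue, midid)
  out
}

#' Initial wrapping sphere
#'
#' Subdivided icosphere centred at the bounding-box centre of the target,
#' with radius `sphere_margin` times half the bounding-box diagonal, so it
#' strictly encloses the target mesh.
#'
#' @param target A non-empty `surface_mesh` (the segmented model).
#' @param config A [filter_config()].
#' @return A watertight `surface_mesh` sphere.
#' @export
init_sphere <- function(target, config = filter_config()) {
  stopifnot_mesh(target)
  if (n_vertices(target) == 0L) stop("target mesh is empty")
  bb <- apply(target$vertices, 2, range)
  centre <- colMeans(bb)
  radius <- config$sphere_margin * sqrt(sum((bb[2, ] - bb[1, ])^2)) / 2
  # icosahedron edge ~ 1.05 r; each subdivision halves edge length
  subdiv <- max(0L, ceiling(log2(1.05 * radius / config$sphere_edge)))
  s <- icosphere(subdiv)
  surface_mesh(sweep(s$vertices * radius, 2, centre, "+"), s$faces)
}

# ---- shrink + wrap phases -------------------------------------------------

#' One shrink step
#'
#' Moves every vertex of `S` along the direction to its closest point on `M`
#' by (lambda - offset), where lambda is the closest-point distance: the
#' vertex lands exactly at distance `offset` from its closest point. Vertices
#' with lambda = 0 are left unchanged.
#'
#' @param S Surface model (a `surface_mesh`).
#' @param M Segmented model (a `surface_mesh`, non-empty).
#' @param offset Offset in mm kept between the meshes (O).
#' @return The moved `surface_mesh`.
#' @export
shrink_step <- function(S, M, offset) {
  stopifnot_mesh(S); stopifnot_mesh(M)
  cp <- closest_point(M, S$vertices)
  move <- cp$distance > 0
  v <- S$vertices
  # land exactly at `offset` from the closest point, along the query direction
  v[move, ] <- cp$point[move, , drop = FALSE] -
    cp$direction[move, , drop = FALSE] * offset
  surface_mesh(v, S$faces)
}

#' A shrinkwrap phase: alternate shrinking and remeshing
#'
#' Runs `iterations` rounds of [shrink_step()] followed by [remesh()]. With
#' `final_remesh = FALSE` the last round skips the remesh so the returned
#' surface is the exact post-shrink state (used at the end of phase 1, where
#' the stretched faces over concavities must survive for the separation
#' step).
#'
#' @param S,M Surface and segmented model meshes.
#' @param offset Offset in mm (O for phase 1, 0 for phase 2).
#' @param iterations Number of rounds (>= 1).
#' @param remesh_voxel Remeshing voxel size in mm.
#' @param final_remesh Remesh after the last shrink too?
#' @return The wrapped `surface_mesh`.
#' @export
shrinkwrap_phase <- function(S, M, offset, iterations, remesh_voxel,
                             final_remesh = TRUE) {
  if (iterations < 1L) stop("iterations must be >= 1")
  for (it in seq_len(iterations)) {
    S <- shrink_step(S, M, offset)
    if (final_remesh || it < iterations) S <- remesh(S, remesh_voxel)
  }
  S
}

# ---- separation / subdivision / projection / reattachment -----------------

#' Separate faces with long edges
#'
#' Splits the surface model into the faces having at least one edge longer
#' than `edge_threshold` (the projection subset, typically covering the
#' acetabular cup opening) and the remainder. Boundary vertices are present
#' in both parts; the correspondence needed by [reattach()] is stored in
#' attributes.
#'
#' @param S A `surface_mesh`.
#' @param edge_threshold E_T in mm.
#' @return List with `rest` and `sub` (`surface_mesh`es; `sub` may be empty),
#'   carrying reattachment bookkeeping as attributes.
#' @export
separate_long_edge_faces <- function(S, edge_threshold) {
  stopifnot_mesh(S)
  v <- S$vertices
  f <- S$faces
  el2 <- function(a, b) rowSums((v[a, , drop = FALSE] - v[b, , drop = FALSE])^2)
  long <- el2(f[, 1], f[, 2]) > edge_threshold^2 |
          el2(f[, 2], f[, 3]) > edge_threshold^2 |
          el2(f[, 3], f[, 1]) > edge_threshold^2
  sub <- subset_faces(S, long)
  rest <- subset_faces(S, !long)
  out <- list(rest = rest, sub = sub)
  attr(out, "shared") <- intersect(attr(sub, "vertex_map"),
                                   attr(rest, "vertex_map"))
  class(out) <- "mesh_separation"
  out
}

#' Loop subdivision to a maximal edge length
#'
#' Repeated Loop subdivision of the separated face set until every edge is at
#' most `max_edge`. Interior vertices are smoothed with the Loop rules (3/8,
#' 1/8 edge masks; beta vertex mask); boundary midpoints use the linear 1/2,
#' 1/2 rule and original boundary vertices stay fixed so the separation
#' interface is preserved for reattachment. The chain of boundary-edge splits
#' is recorded in attribute `edge_splits` (old vertex ids and inserted
#' midpoint id per round).
#'
#' @param S_sub A triangular `surface_mesh` (may have boundary).
#' @param max_edge E_S, the target maximal edge length in mm.
#' @return The subdivided `surface_mesh`.
#' @export
loop_subdivide <- function(S_sub, max_edge) {
  stopifnot_mesh(S_sub)
  if (max_edge <= 0) stop("max_edge must be positive")
  all_splits <- attr(S_sub, "edge_splits")
  mesh <- S_sub
  while (n_faces(mesh) > 0 && max(edge_lengths(mesh)) > max_edge) {
    v <- mesh$vertices
    nv <- nrow(v)
    he <- mesh_half_edges(mesh)
    keys <- edge_keys(he, nv)
    uk <- unique(keys)
    cnt <- tabulate(match(keys, uk))
    boundary_edge <- cnt[match(keys, uk)] == 1L   # per half-edge
    bverts <- unique(as.vector(he[boundary_edge, ]))
    # plain 1:4 split first (records the midpoints)
    split <- subdivide_midpoint(mesh)
    sp <- attr(split, "splits")
    newv <- split$vertices
    # Loop edge mask for interior midpoints: 3/8 (a+b) + 1/8 (c+d).
    # sp rows are in unique-edge order (uk); find each edge's two opposite
    # vertices from the stacked half-edges.
    f <- mesh$faces
    eid <- match(keys, uk)
    ov <- c(f[, 3], f[, 1], f[, 2])       # opposite vertex per half-edge
    opp <- matrix(NA_integer_, nrow(sp), 2)
    fo <- !duplicated(eid)
    opp[eid[fo], 1] <- ov[fo]
    so <- duplicated(eid)
    opp[eid[so], 2] <- ov[so]
    mi <- which(!is.na(opp[, 2]))
    newv[sp[mi, 3], ] <- 0.375 * (v[sp[mi, 1], , drop = FALSE] +
                                  v[sp[mi, 2], , drop = FALSE]) +
                         0.125 * (v[opp[mi, 1], , drop = FALSE] +
                                  v[opp[mi, 2], , drop = FALSE])
    # Loop vertex mask for old interior vertices; boundary vertices fixed
    deg <- tabulate(c(he[first_of(keys), 1], he[first_of(keys), 2]), nbins = nv)
    adj <- rowsum(rbind(v[he[first_of(keys), 2], , drop = FALSE],
                        v[he[first_of(keys), 1], , drop = FALSE]),
                  group = c(he[first_of(keys), 1], he[first_of(keys), 2]),
                  reorder = FALSE)
    adjsum <- matrix(0, nv, 3)
    adjsum[as.integer(rownames(adj)), ] <- adj
    n <- pmax(deg, 1)
    beta <- ifelse(n > 3, 3 / (8 * n),
                   ifelse(n == 3, 3 / 16, 0))
    old_int <- setdiff(which(deg > 0), bverts)
    newv[old_int, ] <- (1 - n[old_int] * beta[old_int]) * v[old_int, , drop = FALSE] +
      beta[old_int] * adjsum[old_int, , drop = FALSE]
    mesh <- surface_mesh(newv, split$faces)
    # record splits of boundary (interface) edges for reattachment
    bsp <- sp[cnt == 1L, , drop = FALSE]
    all_splits <- rbind(all_splits, bsp)
  }
  attr(mesh, "edge_splits") <- all_splits
  attr(mesh, "vertex_map") <- attr(S_sub, "vertex_map")
  mesh
}

first_of <- function(keys) !duplicated(keys)

#' Project subdivided vertices onto the segmented model by ray casting
#'
#' For every vertex of the subdivided subset a ray is cast along its inward
#' normal (the vertex normal negated, pointing toward the segmented model).
#' The vertex is moved to the intersection point `s + lambda * n` when both
#' conditions hold: `proj_min < lambda < proj_max`, and the isolation distance
#' `d_i` (nearest-neighbour distance among all intersection points passing
#' the length window, computed before any pruning) is below `prune_dist`.
#' Pruning is simultaneous, so the result is order independent; it removes
#' isolated projections that typically hit elements inside narrow gaps such
#' as fracture fissures.
#'
#' @param S_sub The subdivided `surface_mesh`.
#' @param M The segmented model.
#' @param config A [filter_config()].
#' @return List with `mesh` (vertices moved) and `candidates`, a tibble with
#'   one row per vertex: origin, normal (the projection direction used), hit,
#'   length, isolation, accepted.
#' @export
project_vertices <- function(S_sub, M, config = filter_config()) {
  stopifnot_mesh(S_sub); stopifnot_mesh(M)
  nv <- n_vertices(S_sub)
  vn <- vertex_normals(S_sub)
  dirs <- -vn  # outward winding; rays go inward, toward M
  rc <- ray_intersect(M, S_sub$vertices, dirs, t_min = 0,
                      t_max = config$proj_max)
  lambda <- rc$length
  passing <- rc$hit & lambda > config$proj_min & lambda < config$proj_max
  iso <- rep(NA_real_, nv)
  if (any(passing)) {
    iso[passing] <- cpp_nn_distance(rc$point[passing, , drop = FALSE])
  }
  accepted <- passing & !is.na(iso) & iso < config$prune_dist
  v <- S_sub$vertices
  v[accepted, ] <- rc$point[accepted, , drop = FALSE]
  out <- surface_mesh(v, S_sub$faces)
  attr(out, "edge_splits") <- attr(S_sub, "edge_splits")
  attr(out, "vertex_map") <- attr(S_sub, "vertex_map")
  cand <- tibble::tibble(
    vertex = seq_len(nv),
    origin_x = S_sub$vertices[, 1], origin_y = S_sub$vertices[, 2],
    origin_z = S_sub$vertices[, 3],
    normal_x = dirs[, 1], normal_y = dirs[, 2], normal_z = dirs[, 3],
    hit_x = rc$point[, 1], hit_y = rc$point[, 2], hit_z = rc$point[, 3],
    length = lambda, isolation = iso, accepted = accepted)
  list(mesh = out, candidates = cand)
}

#' Reattach the projected subset to the rest of the surface model
#'
#' Merges the (subdivided, projected) subset back into the remainder using
#' the boundary correspondence recorded by [separate_long_edge_faces()]. When
#' subdivision inserted midpoints on interface edges, the neighbouring faces
#' of the remainder are split against the same midpoints so the merged mesh
#' stays edge-manifold (no hanging nodes).
#'
#' @param separation The list returned by [separate_long_edge_faces()]
#'   (provides `rest` and the correspondence).
#' @param S_sub2 The processed subset ([loop_subdivide()] +
#'   [project_vertices()] output mesh).
#' @return The merged `surface_mesh`.
#' @export
reattach <- function(separation, S_sub2) {
  if (!inherits(separation, "mesh_separation"))
    stop("reattach: broken correspondence (expected a mesh_separation)")
  rest <- separation$rest
  if (n_faces(S_sub2) == 0L) return(rest)
  sub_map <- attr(S_sub2, "vertex_map")    # sub-local original ids -> S ids
  rest_map <- attr(rest, "vertex_map")
  if (is.null(sub_map) || is.null(rest_map))
    stop("reattach: broken correspondence (missing vertex maps)")
  n_orig_sub <- length(sub_map)
  nv_sub <- n_vertices(S_sub2)
  # global ids: rest vertices keep their slots; sub originals map via S ids
  # where shared, otherwise get fresh slots, as do subdivision midpoints
  shared <- c(match(sub_map, rest_map),    # NA when not on the interface
              rep(NA_integer_, nv_sub - n_orig_sub))
  is_shared <- !is.na(shared)
  glob_of_sub <- integer(nv_sub)
  glob_of_sub[is_shared] <- shared[is_shared]
  fresh <- which(!is_shared)
  glob_of_sub[fresh] <- n_vertices(rest) + seq_along(fresh)
  verts <- rbind(rest$vertices, S_sub2$vertices[fresh, , drop = FALSE])
  # interface vertices may have been moved by projection
  verts[glob_of_sub[is_shared], ] <- S_sub2$vertices[is_shared, , drop = FALSE]
  rest_faces <- rest$faces
  # split rest faces against interface-edge midpoints (in insertion order)
  sp <- attr(S_sub2, "edge_splits")
  if (!is.null(sp) && nrow(sp)) {
    for (r in seq_len(nrow(sp))) {
      u <- glob_of_sub[sp[r, 1]]; w <- glob_of_sub[sp[r, 2]]
      m <- glob_of_sub[sp[r, 3]]
      hasu <- rest_faces[, 1] == u | rest_faces[, 2] == u | rest_faces[, 3] == u
      hasw <- rest_faces[, 1] == w | rest_faces[, 2] == w | rest_faces[, 3] == w
      idx <- which(hasu & hasw)
      for (fi in idx) {
        tri <- rest_faces[fi, ]
        # replace u with m in one copy, w with m in the other
        t1 <- tri; t1[t1 == w] <- m
        t2 <- tri; t2[t2 == u] <- m
        rest_faces[fi, ] <- t1
        rest_faces <- rbind(rest_faces, t2)
      }
    }
  }
  sub_faces <- matrix(glob_of_sub[S_sub2$faces], ncol = 3)
  surface_mesh(verts, rbind(rest_faces, sub_faces))
}

# ---- gap deletion and solidification --------------------------------------

#' Delete vertices far from the segmented model
#'
#' Every vertex whose closest distance g to the segmented model satisfies
#' g >= `gap` is removed together with its incident faces. The result may
#' have boundaries (a non-manifold model with visible fracture lines); that
#' is intended.
#'
#' @param S The wrapped `surface_mesh`.
#' @param M The segmented model.
#' @param gap G in mm.
#' @return A `surface_mesh`, possibly with boundary.
#' @export
delete_far_vertices <- function(S, M, gap) {
  stopifnot_mesh(S); stopifnot_mesh(M)
  g <- closest_point(M, S$vertices)$distance
  keep <- g < gap
  if (!any(keep)) stop("all vertices farther than the gap threshold from the target")
  f <- S$faces
  fkeep <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  out <- subset_faces(S, fkeep)
  attr(out, "vertex_map") <- NULL
  out
}

#' Solidify an open surface into a watertight shell
#'
#' Creates an offset copy of every vertex at `s + n * thickness` along its
#' (outward) vertex normal, adds the offset faces, reverses the winding of
#' the inner faces, and closes every boundary loop with two triangles per
#' boundary edge between the original and offset rim. The result is
#' watertight and consistently oriented. Offset copies that fold over at
#' high-curvature vertices trigger a warning, not an error.
#'
#' @param S A `surface_mesh` with outward orientation (away from the
#'   segmented model).
#' @param thickness T, the shell thickness in mm.
#' @return A watertight `surface_mesh`.
#' @export
solidify <- function(S, thickness) {
  stopifnot_mesh(S)
  if (thickness <= 0) stop("thickness must be positive")
  S <- split_pinch_vertices(S)
  nv <- n_vertices(S)
  vn <- vertex_normals(S)
  outer_v <- S$vertices + vn * thickness
  he <- mesh_half_edges(S)
  keys <- edge_keys(he, nv)
  uk <- unique(keys)
  cnt <- tabulate(match(keys, uk))
  bnd <- he[cnt[match(keys, uk)] == 1L, , drop = FALSE]  # directed a -> b
  # fold-over check along edges
  if (nrow(he)) {
    e_in <- S$vertices[he[, 2], , drop = FALSE] - S$vertices[he[, 1], , drop = FALSE]
    e_out <- outer_v[he[, 2], , drop = FALSE] - outer_v[he[, 1], , drop = FALSE]
    if (any(rowSums(e_in * e_out) < 0))
      warning("offset surface folds over at high-curvature vertices")
  }
  inner_f <- S$faces[, c(1, 3, 2), drop = FALSE]      # reversed: points inward
  outer_f <- S$faces + nv                             # keeps winding: outward
  wall <- NULL
  if (nrow(bnd)) {
    a <- bnd[, 1]; b <- bnd[, 2]
    wall <- rbind(cbind(a, b, b + nv), cbind(a, b + nv, a + nv))
  }
  out <- surface_mesh(rbind(S$vertices, outer_v), rbind(inner_f, outer_f, wall))
  attr(out, "boundary_edge_count") <- nrow(bnd)
  out
}

# Duplicate vertices whose incident faces form more than one edge-connected
# fan (pinch points, e.g. where two boundary loops touch after gap deletion),
# so that boundary-loop closure in solidify yields 2-regular edges.
split_pinch_vertices <- function(S) {
  nv <- n_vertices(S)
  he <- mesh_half_edges(S)
  keys <- edge_keys(he, nv)
  cnt_per_he <- tabulate(match(keys, unique(keys)))[match(keys, unique(keys))]
  bverts <- unique(as.vector(he[cnt_per_he == 1L, , drop = FALSE]))
  deg_b <- tabulate(as.vector(he[cnt_per_he == 1L, , drop = FALSE]), nbins = nv)
  cand <- bverts[deg_b[bverts] > 2L]
  if (!length(cand)) return(S)
  f <- S$faces
  verts <- S$vertices
  for (v in cand) {
    fidx <- which(f[, 1] == v | f[, 2] == v | f[, 3] == v)
    if (length(fidx) < 2L) next
    # connect faces that share an edge containing v
    other <- lapply(fidx, function(fi) setdiff(f[fi, ], v))
    grp <- seq_along(fidx)
    repeat {
      changed <- FALSE
      for (a in seq_along(fidx)) for (b in seq_along(fidx)) {
        if (grp[a] != grp[b] && length(intersect(other[[a]], other[[b]]))) {
          grp[grp == grp[b]] <- grp[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    gids <- unique(grp)
    if (length(gids) < 2L) next
    for (g in gids[-1]) {
      members <- fidx[grp == g]
      # nudge the copy toward its fan (0.5 um) so exact-coordinate vertex
      # welding (e.g. on STL re-import) cannot re-create the pinch
      cen <- colMeans(do.call(rbind, lapply(members, function(fi)
        colMeans(verts[f[fi, ], , drop = FALSE]))))
      dir <- cen - verts[v, ]
      len <- sqrt(sum(dir^2))
      nudge <- if (len > 0) 5e-4 * dir / len else c(0, 0, 0)
      verts <- rbind(verts, verts[v, , drop = FALSE] + nudge)
      newid <- nrow(verts)
      for (fi in members) f[fi, ][f[fi, ] == v] <- newid
    }
  }
  surface_mesh(verts, f)
}

# ---- the full pipeline ----------------------------------------------------

#' Run the full surface-filtering pipeline
#'
#' Executes the complete filter on a segmented model M: initial sphere ->
#' phase-1 offset shrinkwrap -> long-edge face separation -> Loop subdivision
#' -> normal-ray projection with isolation pruning -> reattachment -> phase-2
#' zero-offset shrinkwrap -> gap deletion -> solidification. Stage snapshots
#' A-G mirror the interim stages: A wrap at offset O, B separated subset, C
#' subdivided subset, D after projection and reattachment, E wrap at offset
#' 0, F non-solid model after gap deletion, G solidified printable model.
#'
#' @param M The segmented model (`surface_mesh`, at least 4 faces).
#' @param config A [filter_config()].
#' @param snapshot_dir Optional directory; when given, snapshots are written
#'   as numbered PLY files A-G.
#' @param verbose Log per-stage timing to stderr?
#' @return Object of class `shrinkwrap_result`: list with `printable` (the
#'   final watertight mesh), `snapshots` (list A-G), `candidates` (projection
#'   tibble), `stage_stats` (tibble), `config` and `timings`.
#' @export
run_pipeline <- function(M, config = filter_config(), snapshot_dir = NULL,
                         verbose = FALSE) {
  stopifnot_mesh(M)
  if (n_faces(M) < 4L) stop("segmented model is degenerate (< 4 faces)")
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  snap <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
    if (verbose) message(sprintf("[bonewrap] %-12s %6.1f s", stage, timings[[stage]]))
  }

  S <- init_sphere(M, config)
  tick("init_sphere")
  S <- shrinkwrap_phase(S, M, config$offset, config$phase1_iters,
                        config$remesh_voxel, final_remesh = FALSE)
  snap$A <- S
  tick("phase1")

  sep <- separate_long_edge_faces(S, config$edge_threshold)
  snap$B <- sep$sub
  tick("separate")
  candidates <- tibble::tibble()
  if (n_faces(sep$sub) > 0L) {
    sub2 <- loop_subdivide(sep$sub, config$subdiv_edge)
    snap$C <- sub2
    tick("subdivide")
    pr <- project_vertices(sub2, M, config)
    candidates <- pr$candidates
    S <- reattach(sep, pr$mesh)
    snap$D <- S
    tick("project")
  } else {
    snap$C <- sep$sub
    snap$D <- S
    tick("project")
  }

  S <- shrinkwrap_phase(S, M, 0, config$phase2_iters, config$remesh_voxel,
                        final_remesh = TRUE)
  snap$E <- S
  tick("phase2")

  S <- delete_far_vertices(S, M, config$gap)
  snap$F <- S
  tick("gap_deletion")

  printable <- solidify(S, config$thickness)
  snap$G <- printable
  tick("solidify")

  dist_to_M <- function(mesh) {
    if (n_faces(mesh) == 0L) return(NA_real_)
    max(closest_point(M, mesh$vertices)$distance)
  }
  stats <- tibble::tibble(
    stage = names(snap),
    n_vertices = vapply(snap, n_vertices, 1L),
    n_faces = vapply(snap, n_faces, 1L),
    max_dist_mm = vapply(snap, dist_to_M, 1))
  if (!is.null(snapshot_dir)) {
    if (!dir.exists(snapshot_dir)) dir.create(snapshot_dir, recursive = TRUE)
    for (nm in names(snap))
      write_mesh(snap[[nm]], file.path(snapshot_dir,
                                       sprintf("%d_%s.ply", match(nm, names(snap)), nm)))
  }
  structure(list(printable = printable, snapshots = snap,
                 candidates = candidates, stage_stats = stats,
                 config = config, timings = timings),
            class = "shrinkwrap_result")
}

#' @export
print.shrinkwrap_result <- function(x, ...) {
  cat("<shrinkwrap_result>\n")
  cat(sprintf("  printable: %d vertices, %d faces, watertight: %s\n",
              n_vertices(x$printable), n_faces(x$printable),
              check_manifold(x$printable)$watertight))
  print(x$stage_stats)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.shrinkwrap_result <- function(x, ...) x$candidates

#' @export
glance.shrinkwrap_result <- function(x, ...) {
  cm <- check_manifold(x$printable)
  tibble::tibble(
    n_vertices = n_vertices(x$printable),
    n_faces = n_faces(x$printable),
    watertight = cm$watertight,
    n_projected = if (nrow(x$candidates)) sum(x$candidates$accepted) else 0L,
    final_max_dist_mm = x$stage_stats$max_dist_mm[x$stage_stats$stage == "F"],
    total_time_s = sum(unlist(x$timings)))
}

#' Stage-distance plot for a pipeline result
#'
#' Maximum surface-to-target distance per pipeline stage.
#'
#' @param object A `shrinkwrap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shrinkwrap_result <- function(object, ...) {
  df <- object$stage_stats
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$max_dist_mm)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "pipeline stage", y = "max distance to segmented model [mm]")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
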