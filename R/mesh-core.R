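#' Triangle surface mesh
#'
#' Creates a `surface_mesh`, the container used for both the segmented model
#' (the wrapping target extracted from CT) and the evolving surface model.
#' Coordinates are world millimetres; faces are 1-based triangles.
#'
#' @param vertices Numeric matrix, n x 3, vertex positions in mm.
#' @param faces Integer matrix, m x 3, vertex indices (1-based).
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                     matrix(c(1L, 2L, 3L), 1))
#' n_faces(tri)
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix (triangles only)")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
  } else {
    faces <- matrix(integer(0), 0, 3)
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices)) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

#' @rdname surface_mesh
#' @param mesh A `surface_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname surface_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "surface_mesh")) stop("expected a surface_mesh")
  invisible(mesh)
}

# directed edges of every face, as an (3m x 2) matrix in face order
mesh_half_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2), drop = FALSE],
        f[, c(2, 3), drop = FALSE],
        f[, c(3, 1), drop = FALSE])
}

# undirected edge keys (double-encoded, exact for < 2^26 vertices)
edge_keys <- function(e, nv) {
  a <- pmin(e[, 1], e[, 2])
  b <- pmax(e[, 1], e[, 2])
  (a - 1) * as.double(nv) + b
}

#' Edge lengths of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Numeric vector with one length per unique undirected edge (mm).
#' @export
edge_lengths <- function(mesh) {
  stopifnot_mesh(mesh)
  he <- mesh_half_edges(mesh)
  keys <- edge_keys(he, n_vertices(mesh))
  e <- he[!duplicated(keys), , drop = FALSE]
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Area-weighted per-vertex normals
#'
#' Unit normals as the area-weighted average of incident face normals;
#' orientation follows the face winding (counter-clockwise seen from outside).
#' Isolated vertices receive a zero normal and a warning.
#'
#' @param mesh A `surface_mesh` with consistent winding.
#' @return Numeric matrix n x 3 of unit (or zero) vectors.
#' @export
vertex_normals <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted already
  idx <- c(f[, 1], f[, 2], f[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = idx, reorder = FALSE)
  out <- matrix(0, n_vertices(mesh), 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  used <- seq_len(n_vertices(mesh)) %in% idx
  if (any(!used)) warning("isolated vertices present; zero normals returned")
  nz <- len > 0
  out[nz, ] <- out[nz, , drop = FALSE] / len[nz]
  out
}

#' Manifoldness report
#'
#' A mesh is watertight when every undirected edge bounds exactly two faces.
#' Orientation is consistent when each such edge is traversed once in each
#' direction by its two faces.
#'
#' @param mesh A `surface_mesh`.
#' @return List with `watertight`, `edge_defects` (number of edges not shared
#'   by exactly two faces), `boundary_edges`, and `orientation_consistent`.
#' @export
check_manifold <- function(mesh) {
  stopifnot_mesh(mesh)
  he <- mesh_half_edges(mesh)
  nv <- n_vertices(mesh)
  keys <- edge_keys(he, nv)
  uk <- unique(keys)
  cnt <- tabulate(match(keys, uk))
  boundary <- sum(cnt == 1L)
  defects <- sum(cnt != 2L)
  # orientation: directed edge keys must be unique, and for interior edges the
  # reverse direction must appear
  dk <- (he[, 1] - 1) * as.double(nv) + he[, 2]
  orient <- !anyDuplicated(dk)
  list(watertight = defects == 0L,
       edge_defects = defects,
       boundary_edges = boundary,
       orientation_consistent = orient)
}

#' Connected components of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Integer vector of component ids per face (1 = largest).
#' @export
mesh_components <- function(mesh) {
  stopifnot_mesh(mesh)
  nf <- n_faces(mesh)
  if (nf == 0L) return(integer(0))
  # faces are connected when they share a vertex
  g <- igraph::graph_from_edgelist(mesh_half_edges(mesh), directed = FALSE)
  vc <- igraph::components(g)$membership[seq_len(n_vertices(mesh))]
  fcomp <- vc[mesh$faces[, 1]]
  sizes <- sort(table(fcomp), decreasing = TRUE)
  match(as.character(fcomp), names(sizes))
}

#' Keep a subset of faces
#'
#' Returns the submesh of the given faces with unreferenced vertices dropped.
#' The mapping of new to old vertex indices is kept in attribute `vertex_map`.
#'
#' @param mesh A `surface_mesh`.
#' @param face_idx Logical or integer selection of faces.
#' @return A `surface_mesh`.
#' @export
subset_faces <- function(mesh, face_idx) {
  stopifnot_mesh(mesh)
  f <- mesh$faces[face_idx, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[keep] <- seq_along(keep)
  out <- surface_mesh(mesh$vertices[keep, , drop = FALSE],
                      matrix(remap[f], ncol = 3))
  attr(out, "vertex_map") <- keep
  out
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive for outward-wound closed meshes.
#'
#' @param mesh A `surface_mesh`.
#' @return Volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# merge geometrically coincident vertices (exact match after rounding)
weld_vertices <- function(mesh, digits = 9) {
  key <- apply(round(mesh$vertices, digits), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])     # new (unique) index per old vertex
  f <- matrix(map[mesh$faces], ncol = 3)
  surface_mesh(mesh$vertices[first, , drop = FALSE], f)
}

#' Rigidly transform a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation in mm.
#' @return The transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  surface_mesh(v, mesh$faces)
}
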