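#' Closest point on a mesh
#'
#' Globally nearest point on any triangle (vertex, edge or interior) of the
#' target for each query point, found through an axis-aligned BVH. Behaviour
#' matches exhaustive per-triangle minimization.
#'
#' @param target A `surface_mesh` with at least one face.
#' @param query Numeric vector of length 3, or an n x 3 matrix of points (mm).
#' @return List with `point` (n x 3 closest points), `distance` (mm),
#'   `direction` (n x 3 unit vectors from query toward closest point; the zero
#'   vector where distance is 0), and `face` (1-based triangle index).
#' @export
closest_point <- function(target, query) {
  stopifnot_mesh(target)
  if (n_faces(target) == 0L) stop("closest_point: target mesh has no faces")
  q <- if (is.null(dim(query))) matrix(query, ncol = 3) else as.matrix(query)
  storage.mode(q) <- "double"
  res <- cpp_closest_point(target$vertices, target$faces, q)
  dir <- res$point - q
  nz <- res$distance > 0
  dir[nz, ] <- dir[nz, , drop = FALSE] / res$distance[nz]
  dir[!nz, ] <- 0
  list(point = res$point, distance = res$distance, direction = dir,
       face = res$face)
}

#' Ray-mesh intersection
#'
#' Nearest intersection of each ray with the target, with ray parameter
#' restricted to the open interval (`t_min`, `t_max`). Absence of a hit is a
#' valid result, not an error.
#'
#' @param target A `surface_mesh`.
#' @param origin Length-3 vector or n x 3 matrix of ray origins (mm).
#' @param direction Length-3 unit vector or n x 3 matrix of unit directions.
#' @param t_min,t_max Open interval for the ray parameter in mm.
#' @return List with `hit` (logical), `point` (n x 3, NA rows where no hit),
#'   `length` (ray parameter, mm) and `face`.
#' @export
ray_intersect <- function(target, origin, direction, t_min = 0, t_max = Inf) {
  stopifnot_mesh(target)
  if (n_faces(target) == 0L) stop("ray_intersect: target mesh has no faces")
  o <- if (is.null(dim(origin))) matrix(origin, ncol = 3) else as.matrix(origin)
  d <- if (is.null(dim(direction))) matrix(direction, ncol = 3) else as.matrix(direction)
  if (any(t_min >= t_max)) stop("t_min must be smaller than t_max")
  storage.mode(o) <- "double"
  storage.mode(d) <- "double"
  res <- cpp_ray_cast(target$vertices, target$faces, o, d,
                      as.double(t_min), as.double(pmin(t_max, 1e12)))
  pt <- o + d * res$t
  pt[!res$hit, ] <- NA_real_
  list(hit = res$hit, point = pt, length = res$t, face = res$face)
}

#' Point-in-mesh test
#'
#' Crossing-parity test along a fixed (slightly irrational, deterministic)
#' direction. Intended for closed meshes.
#'
#' @param mesh A closed `surface_mesh`.
#' @param points Length-3 vector or n x 3 matrix.
#' @return Logical vector, `TRUE` for points inside.
#' @export
point_in_mesh <- function(mesh, points) {
  stopifnot_mesh(mesh)
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  storage.mode(p) <- "double"
  d <- matrix(rep(c(0.577350269189626, 0.577002, 0.5777), nrow(p)),
              ncol = 3, byrow = TRUE)
  d <- d / sqrt(rowSums(d^2))
  cnt <- cpp_ray_crossings(mesh$vertices, mesh$faces, p, d)
  cnt %% 2L == 1L
}
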