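#' Landmark rigid registration
#'
#' Least-squares rigid (6 degrees of freedom) alignment of paired landmark
#' sets, minimizing sum ||R p_i + t - q_i||^2 over proper rotations
#' (Kabsch/Umeyama solution via SVD of the cross-covariance). Printed models
#' are 1:1 scale, so similarity scaling is off by default; set
#' `allow_scaling = TRUE` for a similarity fit.
#'
#' @param source,target n x 3 matrices of paired landmarks in mm, n >= 3,
#'   same order; the source must not be collinear.
#' @param allow_scaling Estimate a global scale factor as well?
#' @return Object of class `landmark_registration`: `rotation` (3 x 3, proper,
#'   det +1), `translation`, `scale`, `rms_error` (mm, root mean square of the
#'   residuals) and `n`.
#' @export
landmark_register <- function(source, target, allow_scaling = FALSE) {
  p <- as.matrix(source); q <- as.matrix(target)
  if (ncol(p) != 3L || ncol(q) != 3L) stop("landmarks must be n x 3 matrices")
  if (nrow(p) != nrow(q)) stop("landmark sets must have equal counts")
  if (nrow(p) < 3L) stop("registration needs at least 3 landmarks")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv_src <- svd(pc)$d
  if (sv_src[2] < 1e-9 * max(sv_src[1], 1))
    stop("degenerate landmark configuration (collinear points)")
  H <- crossprod(pc, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- 1
  if (allow_scaling) s <- sum(diag(S) * sv$d) / sum(pc^2)
  tr <- cq - s * as.vector(R %*% cp)
  res <- s * pc %*% t(R) - qc
  rms <- sqrt(mean(rowSums(res^2)))
  structure(list(rotation = R, translation = tr, scale = s,
                 rms_error = rms, n = nrow(p)),
            class = "landmark_registration")
}

#' @export
print.landmark_registration <- function(x, ...) {
  cat(sprintf("<landmark_registration: n = %d, RMS error = %.4g mm, scale = %.6g>\n",
              x$n, x$rms_error, x$scale))
  invisible(x)
}

#' @export
glance.landmark_registration <- function(x, ...) {
  tibble::tibble(n = x$n, rms_error_mm = x$rms_error, scale = x$scale)
}

#' @export
tidy.landmark_registration <- function(x, ...) {
  tibble::tibble(term = c(sprintf("R[%d,%d]", rep(1:3, 3), rep(1:3, each = 3)),
                          sprintf("t[%d]", 1:3)),
                 estimate = c(as.vector(x$rotation), x$translation))
}

#' Apply a registration to points or a mesh
#'
#' @param transform A `landmark_registration`.
#' @param x n x 3 point matrix or a `surface_mesh`.
#' @return Transformed points or mesh.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "landmark_registration"))
  tp <- function(v) sweep(transform$scale * v %*% t(transform$rotation), 2,
                          transform$translation, "+")
  if (inherits(x, "surface_mesh")) return(surface_mesh(tp(x$vertices), x$faces))
  tp(as.matrix(x))
}

#' Vertex-wise surface distance between two meshes
#'
#' For every vertex of the (optionally transformed) query mesh, the closest
#' distance to the reference surface is computed. The measure is directed
#' (query toward reference) and not symmetric; the report records the
#' direction. Summary columns mirror the validation table: number of
#' vertices, MAD (mean average distance), STD and MAX in mm.
#'
#' @param query_mesh `surface_mesh` whose vertices are measured.
#' @param reference_mesh `surface_mesh` measured against.
#' @param transform Optional `landmark_registration` applied to `query_mesh`
#'   first; its RMS error is carried into the report.
#' @return Object of class `surface_distance`: `distances` (per-vertex, mm)
#'   and `report`, a one-row tibble with `n_vertices`, `mad`, `std`, `max`,
#'   `rms_error`, `direction`.
#' @export
surface_distance <- function(query_mesh, reference_mesh, transform = NULL) {
  stopifnot_mesh(query_mesh); stopifnot_mesh(reference_mesh)
  if (n_faces(query_mesh) == 0L || n_faces(reference_mesh) == 0L)
    stop("surface_distance needs two non-empty meshes")
  if (!is.null(transform)) query_mesh <- apply_transform(transform, query_mesh)
  d <- closest_point(reference_mesh, query_mesh$vertices)$distance
  report <- tibble::tibble(
    n_vertices = length(d),
    mad = mean(d),
    std = stats::sd(d),
    max = max(d),
    rms_error = if (is.null(transform)) NA_real_ else transform$rms_error,
    direction = "query_to_reference")
  structure(list(distances = d, report = report), class = "surface_distance")
}

#' @export
print.surface_distance <- function(x, ...) {
  cat("<surface_distance (query -> reference)>\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.surface_distance <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$distances), distance_mm = x$distances)
}

#' @export
glance.surface_distance <- function(x, ...) x$report

#' Distance histogram for a surface-distance result
#'
#' @param object A `surface_distance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surface_distance <- function(object, ...) {
  df <- tibble::tibble(distance_mm = object$distances)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(x = "closest distance to reference [mm]", y = "vertices")
}

#' Read landmark coordinate files
#'
#' Plain text, one `x y z` triple in mm per line; blank lines and `#`
#' comments are ignored.
#'
#' @param path Landmark file.
#' @return n x 3 numeric matrix.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(lines, "[ ,\t]+"), function(x)
    as.numeric(x[1:3])))
  if (is.null(m) || anyNA(m)) stop("malformed landmark file: ", path)
  m
}

#' Write a validation report CSV row
#'
#' Columns follow the validation table: PatientID, RMS-error, N, MAD, STD,
#' MAX (all distances in mm).
#'
#' @param report The `report` tibble of a [surface_distance()] (or compatible
#'   data frame).
#' @param path Output CSV.
#' @param patient_id Identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_distance_report <- function(report, path, patient_id = "model") {
  df <- data.frame(PatientID = patient_id,
                   `RMS-error` = report$rms_error,
                   N = report$n_vertices,
                   MAD = report$mad,
                   STD = report$std,
                   MAX = report$max,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
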