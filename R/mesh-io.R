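#' Read and write triangle meshes
#'
#' Binary STL, ASCII PLY and OBJ, chosen by `format` or file extension.
#' Round-trips preserve vertices and faces to float precision; STL stores one
#' vertex per face corner, so reading an STL de-duplicates coincident
#' vertices.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output file.
#' @param format `"auto"`, `"stl"`, `"ply"` or `"obj"`.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` a
#'   `surface_mesh`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj")) {
  stopifnot_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  switch(format,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path))
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "obj")) stop("unknown mesh format: .", ext)
  ext
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  nf <- n_faces(mesh)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # 12 floats + 2 attribute bytes per facet; build one block for speed
  block <- matrix(0, 12, nf)
  block[1:3, ] <- t(nrm); block[4:6, ] <- t(a)
  block[7:9, ] <- t(b); block[10:12, ] <- t(cc)
  floats <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  fm <- matrix(as.raw(0), 50, nf)
  fm[1:48, ] <- matrix(floats, 48, nf)
  writeBin(as.vector(fm), con)
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 80)
  if (grepl("^solid", rawToChar(head[1:5]))) {
    close(con); on.exit(NULL)
    return(read_stl_ascii(path))
  }
  nf <- readBin(con, "integer", size = 4, endian = "little")
  if (nf < 0 || 84 + 50 * nf > sz) stop("corrupt STL file (format error)")
  body <- readBin(con, "raw", n = 50 * nf)
  fm <- matrix(body, 50, nf)
  floats <- readBin(as.vector(fm[1:48, ]), "double", n = 12 * nf, size = 4,
                    endian = "little")
  block <- matrix(floats, 12, nf)
  verts <- rbind(t(block[4:6, , drop = FALSE]), t(block[7:9, , drop = FALSE]),
                 t(block[10:12, , drop = FALSE]))
  faces <- cbind(seq_len(nf), nf + seq_len(nf), 2L * nf + seq_len(nf))
  weld_vertices(surface_mesh(verts, faces), digits = 6)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  weld_vertices(surface_mesh(verts, faces), digits = 6)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n_vertices(mesh)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", n_faces(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh$vertices, digits = 17, scientific = FALSE,
                     trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (n_faces(mesh))
    write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1], "ply")) stop("not a PLY file (format error)")
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[1:3])))
  faces <- matrix(integer(0), 0, 3)
  if (!is.na(nf) && nf > 0) {
    fl <- lines[(endh + nv + 1):(endh + nv + nf)]
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      if (as.integer(x[1]) != 3L) stop("only triangle PLY faces are supported")
      as.integer(x[2:4]) + 1L
    }))
  }
  surface_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write.table(cbind("v", format(mesh$vertices, digits = 17,
                                scientific = FALSE, trim = TRUE)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (n_faces(mesh))
    write.table(cbind("f", mesh$faces), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- if (length(fl)) {
    do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  } else matrix(integer(0), 0, 3)
  surface_mesh(verts, faces)
}
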