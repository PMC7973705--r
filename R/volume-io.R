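#' Scalar voxel volume in Hounsfield Units
#'
#' Axis-aligned scalar grid with per-axis spacing and a world origin at the
#' centre of the first voxel. World coordinates of 1-based voxel index
#' (i, j, k) are `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of intensities (HU).
#' @param spacing Length-3 positive voxel size in mm.
#' @param origin Length-3 world position of the first voxel centre in mm.
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("volume needs at least 2 voxels per axis")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume: %s voxels, spacing %s mm, HU range [%.0f, %.0f]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname voxel_volume
#' @param volume A `voxel_volume` (or `label_mask`).
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- if (is.null(dim(ijk))) matrix(ijk, ncol = 3) else as.matrix(ijk)
  sweep(sweep(ijk - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' @rdname voxel_volume
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
  sweep(sweep(xyz, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
}

guess_volume_format <- function(path) {
  if (dir.exists(path)) return("dicom_dir")
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  stop("cannot guess volume format from path: ", path)
}

#' Read a CT volume
#'
#' Reads a DICOM series directory, an NRRD file, or a NIfTI-1 file into a
#' [voxel_volume()] with intensities in Hounsfield Units and geometry taken
#' from the header. DICOM slices are sorted into a single volume by slice
#' position along the stack normal.
#'
#' @param path File (NRRD/NIfTI) or directory (DICOM series).
#' @param format One of `"auto"`, `"dicom_dir"`, `"nrrd"`, `"nifti"`.
#' @return A `voxel_volume`.
#' @export
read_volume <- function(path, format = c("auto", "dicom_dir", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_volume_format(path)
  if (format != "dicom_dir" && !file.exists(path)) stop("file not found: ", path)
  switch(format,
         nrrd = read_nrrd(path),
         nifti = read_nifti_volume(path),
         dicom_dir = read_dicom_dir(path))
}

#' Write a volume or mask
#'
#' @param volume A `voxel_volume` or `label_mask` (masks are written as 0/1).
#' @param path Output file; extension selects the format unless given.
#' @param format `"auto"`, `"nrrd"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_volume_format(path)
  if (inherits(volume, "label_mask"))
    volume <- voxel_volume(array(as.double(volume$mask), dim(volume$mask)),
                           volume$spacing, volume$origin)
  if (!inherits(volume, "voxel_volume")) stop("expected a voxel_volume")
  switch(format,
         nrrd = write_nrrd(volume, path),
         nifti = write_nifti_volume(volume, path))
  invisible(path)
}

# ---- NRRD (raw little-endian encoding) -----------------------------------

write_nrrd <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(volume$data)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "space dimension: 3",
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   volume$spacing[1], volume$spacing[2], volume$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

nrrd_type_info <- function(type) {
  switch(type,
         "double" = list(what = "double", size = 8),
         "float"  = list(what = "double", size = 4),
         "short" = , "int16" = , "signed short" =
           list(what = "integer", size = 2, signed = TRUE),
         "unsigned short" = , "ushort" = , "uint16" =
           list(what = "integer", size = 2, signed = FALSE),
         "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
         "uchar" = , "uint8" = , "unsigned char" =
           list(what = "integer", size = 1, signed = FALSE),
         stop("unsupported NRRD type: ", type))
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), "[, ]+")[[1]]))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file (format error): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  enc <- tolower(fields[["encoding"]] %||% "raw")
  if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  info <- nrrd_type_info(tolower(trimws(fields[["type"]])))
  endian <- tolower(fields[["endian"]] %||% "little")
  n <- prod(sizes)
  raw <- readBin(con, what = info$what, n = n, size = info$size,
                 signed = if (info$size < 4) isTRUE(info$signed) else TRUE,
                 endian = endian)
  if (length(raw) < n) stop("truncated NRRD data")
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    mat <- do.call(rbind, dirs)
    if (any(abs(mat - diag(diag(mat))) > 1e-9))
      stop("non-axis-aligned NRRD space directions are not supported")
    spacing <- diag(mat)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), " +")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  voxel_volume(array(as.double(raw), sizes), spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NIfTI-1 via RNifti ---------------------------------------------------

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file (format error): ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("only 3D NIfTI volumes are supported")
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(abs(rot - diag(spacing)) > 1e-3 * max(spacing)))
    stop("non-axis-aligned NIfTI orientation is not supported")
  voxel_volume(arr, spacing, aff[1:3, 4])
}

# ---- minimal DICOM (uncompressed little-endian CT series) -----------------

dicom_vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (format error): ", path)
  pos <- 133L
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  elems <- list()
  explicit <- TRUE
  ts <- NULL
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    if (grp != 2L && !is.null(ts) && is.null(elems[["started_data"]])) {
      elems[["started_data"]] <- TRUE
      explicit <- !identical(ts, "1.2.840.10008.1.2")
    }
    if (grp == 2L || explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% dicom_vr_long) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements not supported")
    val_at <- pos + hdr
    key <- sprintf("%04x%04x", grp, ele)
    if (key %in% c("00020010", "00200013", "00200032", "00200037", "00280010",
                   "00280011", "00280030", "00280100", "00280103", "00281052",
                   "00281053", "7fe00010")) {
      elems[[key]] <- raw[val_at:(val_at + len - 1L)]
    }
    if (key == "00020010") {
      b <- raw[val_at:(val_at + len - 1L)]
      ts <- trimws(rawToChar(b[b != as.raw(0)]))
    }
    pos <- val_at + len
  }
  dstr <- function(key) {
    b <- elems[[key]]
    if (is.null(b)) return(NULL)
    as.numeric(strsplit(trimws(rawToChar(b[b != as.raw(0)])), "\\\\")[[1]])
  }
  dus <- function(key) {
    b <- elems[[key]]
    if (is.null(b)) return(NULL)
    as.integer(b[1]) + 256L * as.integer(b[2])
  }
  bits <- dus("00280100") %||% 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- (dus("00280103") %||% 0L) == 1L
  rows <- dus("00280010"); cols <- dus("00280011")
  if (is.null(rows) || is.null(cols) || is.null(elems[["7fe00010"]]))
    stop("DICOM file lacks pixel data: ", path)
  px <- readBin(elems[["7fe00010"]], "integer", n = rows * cols, size = 2,
                signed = signed, endian = "little")
  slope <- (dstr("00281053") %||% 1)[1]
  inter <- (dstr("00281052") %||% 0)[1]
  list(pixels = matrix(px * slope + inter, nrow = cols, ncol = rows),
       position = dstr("00200032") %||% c(0, 0, 0),
       orientation = dstr("00200037") %||% c(1, 0, 0, 0, 1, 0),
       pixel_spacing = dstr("00280030") %||% c(1, 1),
       instance = (dstr("00200013") %||% NA_real_)[1])
}

read_dicom_dir <- function(path) {
  if (!dir.exists(path)) stop("DICOM directory not found: ", path)
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
  }
  if (length(files) == 0L) stop("no DICOM files in directory (format error): ", path)
  slices <- lapply(sort(files), parse_dicom_file)
  ori <- slices[[1]]$orientation
  normal <- c(ori[2] * ori[6] - ori[3] * ori[5],
              ori[3] * ori[4] - ori[1] * ori[6],
              ori[1] * ori[5] - ori[2] * ori[4])
  zpos <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  if (length(slices) < 2L) stop("DICOM series needs at least 2 slices")
  dz <- diff(zpos)
  if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * mean(dz))
    stop("inconsistent DICOM slice spacing (geometry error)")
  ps <- slices[[1]]$pixel_spacing  # (row spacing = dy, column spacing = dx)
  arr <- array(0, c(nrow(slices[[1]]$pixels), ncol(slices[[1]]$pixels),
                    length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
  voxel_volume(arr, spacing = c(ps[2], ps[1], mean(dz)),
               origin = slices[[1]]$position)
}

# internal writer used to build DICOM test fixtures at run time
write_dicom_series <- function(volume, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$data)
  enc16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  elem <- function(grp, ele, vr, value) {
    if (vr %in% c("DS", "IS", "UI", "CS")) {
      v <- charToRaw(value)
      if (length(v) %% 2 == 1)
        v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
    } else if (vr == "US") {
      v <- enc16(value)
    } else v <- value  # raw
    hdr <- c(enc16(grp), enc16(ele), charToRaw(vr))
    if (vr %in% dicom_vr_long) {
      c(hdr, as.raw(c(0, 0)), writeBin(length(v), raw(), size = 4,
                                       endian = "little"), v)
    } else {
      c(hdr, enc16(length(v)), v)
    }
  }
  for (k in seq_len(d[3])) {
    sl <- volume$data[, , k]
    stored <- as.integer(round(sl + 1024))
    px <- writeBin(stored, raw(), size = 2, endian = "little")
    pos <- volume$origin + c(0, 0, (k - 1) * volume$spacing[3])
    body <- c(
      elem(0x0008L, 0x0016L, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      elem(0x0008L, 0x0018L, "UI", sprintf("1.2.826.0.1.3680043.2.0.%d", k)),
      elem(0x0020L, 0x0013L, "IS", as.character(k)),
      elem(0x0020L, 0x0032L, "DS",
           sprintf("%.8g\\%.8g\\%.8g", pos[1], pos[2], pos[3])),
      elem(0x0020L, 0x0037L, "DS", "1\\0\\0\\0\\1\\0"),
      elem(0x0028L, 0x0002L, "US", 1L),
      elem(0x0028L, 0x0010L, "US", d[2]),  # rows
      elem(0x0028L, 0x0011L, "US", d[1]),  # columns
      elem(0x0028L, 0x0030L, "DS",
           sprintf("%.8g\\%.8g", volume$spacing[2], volume$spacing[1])),
      elem(0x0028L, 0x0100L, "US", 16L),
      elem(0x0028L, 0x0101L, "US", 16L),
      elem(0x0028L, 0x0102L, "US", 15L),
      elem(0x0028L, 0x0103L, "US", 1L),
      elem(0x0028L, 0x1052L, "DS", "-1024"),
      elem(0x0028L, 0x1053L, "DS", "1"),
      elem(0x7fe0L, 0x0010L, "OW", px))
    meta <- elem(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
    con <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(meta, con)
    writeBin(body, con)
    close(con)
  }
  invisible(dir)
}
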