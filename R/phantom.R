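#' Phantom specification
#'
#' Parameters of the synthetic CT phantoms. The default cup phantom emulates
#' the geometry the pipeline exists for: a thin cortical shell (1000 HU on a
#' 40 HU soft-tissue background, so the 200-350 HU bone threshold band is
#' meaningful), a socket-like concavity and optional fracture fissures.
#'
#' `cup_rim_width` is the rim-to-axis distance of the circular opening (the
#' opening half-width); the default 26 mm opening with 28 mm depth matches
#' adult acetabular proportions (about 52 mm diameter, 28 mm deep), a
#' concavity deeper than its rim is wide, so the closest surface from above
#' is always the rim and pure closest-point wrapping cannot reach the bottom.
#'
#' @param outer_radius Outer shell radius in mm.
#' @param wall Shell wall thickness in mm (>= 2 x spacing).
#' @param cup_depth Depth of the cup below the outer surface in mm; must
#'   exceed `cup_rim_width`.
#' @param cup_rim_width Opening half-width (rim-to-axis distance) in mm.
#' @param fissure_width Width of fracture fissures in mm.
#' @param fissure_count Number of fissures (0 for none).
#' @param shell_hu,background_hu Intensities in HU.
#' @param noise_sd Gaussian noise standard deviation in HU.
#' @param spacing Isotropic voxel size in mm.
#' @param seed Random seed for the noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 44, wall = 3, cup_depth = 28,
                         cup_rim_width = 26, fissure_width = 3,
                         fissure_count = 1, shell_hu = 1000,
                         background_hu = 40, noise_sd = 20, spacing = 1,
                         seed = 1L) {
  spec <- list(outer_radius = outer_radius, wall = wall, cup_depth = cup_depth,
               cup_rim_width = cup_rim_width, fissure_width = fissure_width,
               fissure_count = as.integer(fissure_count), shell_hu = shell_hu,
               background_hu = background_hu, noise_sd = noise_sd,
               spacing = spacing, seed = as.integer(seed))
  if (spec$cup_depth <= spec$cup_rim_width)
    stop("cup must be deeper than its rim half-width (cup_depth > cup_rim_width)")
  if (spec$wall < 2 * spec$spacing)
    stop("shell wall is not resolvable: wall must be >= 2 x spacing")
  if (spec$cup_rim_width + spec$wall >= spec$outer_radius)
    stop("cup opening does not fit into the outer radius")
  if (spec$noise_sd < 0 || spec$fissure_count < 0L || spec$fissure_width <= 0)
    stop("invalid phantom parameters")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# evaluate RNG code under a fixed seed without disturbing the session RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# solid indicator of the cup-shell phantom on arbitrary coordinates (mm)
cup_solid <- function(spec, x, y, z) {
  R <- spec$outer_radius; w <- spec$wall
  r_cup <- spec$cup_rim_width
  z_floor <- R - spec$cup_depth
  rad <- sqrt(x^2 + y^2 + z^2)
  rho <- sqrt(x^2 + y^2)
  sphere_shell <- rad <= R & rad >= R - w
  cup_wall <- rho >= r_cup & rho <= r_cup + w & z >= z_floor - w & rad <= R
  floor_disc <- rho <= r_cup + w & z >= z_floor - w & z <= z_floor
  void <- rho < r_cup & z > z_floor
  solid <- (sphere_shell | cup_wall | floor_disc) & !void
  if (spec$fissure_count > 0L) {
    guard <- r_cup + w + 2
    for (k in seq_len(spec$fissure_count)) {
      phi <- (k - 1) * pi / spec$fissure_count
      nrm <- c(cos(phi), sin(phi))
      tng <- c(-sin(phi), cos(phi))
      fis <- abs(nrm[1] * x + nrm[2] * y) < spec$fissure_width / 2 &
        (tng[1] * x + tng[2] * y) < -guard
      solid <- solid & !fis
    }
  }
  solid
}

phantom_grid <- function(extent, spacing, margin = 4) {
  half <- extent + margin
  n <- ceiling(2 * half / spacing) + 1
  origin <- rep(-(n - 1) / 2 * spacing, 3)
  list(n = as.integer(rep(n, 3)), origin = origin)
}

#' Cup-shell phantom: the pipeline's hard case
#'
#' Hollow spherical cortical shell with a cylinder-walled cup recessed into
#' its top (opening half-width `cup_rim_width`, depth `cup_depth`, floor and
#' walls of shell material) and optional fracture fissures (slabs of
#' background HU cutting through the shell away from the cup). Gaussian noise
#' is added with the spec seed, so phantoms are fully reproducible. The
#' ground-truth mesh is the noiseless solid surface extracted at grid
#' resolution.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a `voxel_volume`) and `truth` (a
#'   `surface_mesh`).
#' @export
make_cup_shell <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec$outer_radius, spec$spacing)
  ax <- g$origin[1] + (seq_len(g$n[1]) - 1) * spec$spacing
  x <- array(rep(ax, times = g$n[2] * g$n[3]), g$n)
  y <- array(rep(rep(ax, each = g$n[1]), times = g$n[3]), g$n)
  z <- array(rep(ax, each = g$n[1] * g$n[2]), g$n)
  solid <- cup_solid(spec, x, y, z)
  hu <- array(spec$background_hu, g$n)
  hu[solid] <- spec$shell_hu
  if (spec$noise_sd > 0)
    hu <- hu + with_seed(spec$seed,
                         array(stats::rnorm(length(hu), 0, spec$noise_sd), g$n))
  vol <- voxel_volume(hu, rep(spec$spacing, 3), g$origin)
  field <- array(0.5, g$n)
  field[solid] <- -0.5
  mc <- cpp_marching_tets(as.vector(field), g$n, g$origin,
                          rep(spec$spacing, 3), 0)
  list(volume = vol, truth = surface_mesh(mc$vertices, mc$faces))
}

#' Hollow-sphere phantom: the convex control case
#'
#' @param radius Outer radius in mm.
#' @param wall Wall thickness in mm.
#' @param shell_hu,background_hu Intensities in HU.
#' @param spacing Voxel size in mm.
#' @param noise_sd Gaussian noise SD in HU.
#' @param seed Random seed.
#' @return List with `volume` and `truth` (icosphere with vertices exactly at
#'   `radius`).
#' @export
make_sphere_shell <- function(radius = 30, wall = 3, shell_hu = 1000,
                              background_hu = 40, spacing = 1, noise_sd = 0,
                              seed = 1L) {
  if (wall < 2 * spacing) stop("shell wall is not resolvable")
  g <- phantom_grid(radius, spacing)
  ax <- g$origin[1] + (seq_len(g$n[1]) - 1) * spacing
  x <- array(rep(ax, times = g$n[2] * g$n[3]), g$n)
  y <- array(rep(rep(ax, each = g$n[1]), times = g$n[3]), g$n)
  z <- array(rep(ax, each = g$n[1] * g$n[2]), g$n)
  rad <- sqrt(x^2 + y^2 + z^2)
  solid <- rad <= radius & rad >= radius - wall
  hu <- array(background_hu, g$n)
  hu[solid] <- shell_hu
  if (noise_sd > 0)
    hu <- hu + with_seed(seed, array(stats::rnorm(length(hu), 0, noise_sd), g$n))
  truth <- icosphere(4)
  truth$vertices <- truth$vertices * radius
  list(volume = voxel_volume(hu, rep(spacing, 3), g$origin), truth = truth)
}

#' Rigidly move a phantom mesh
#'
#' Exact rigid motion (rotation then translation); a registration test
#' fixture.
#'
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector in mm.
#' @return The moved `surface_mesh`.
#' @export
transform_phantom <- function(mesh, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  transform_mesh(mesh, rotation, translation)
}

#' Write or read a phantom spec as a flat config file
#'
#' @param spec A `phantom_spec`.
#' @param path File path.
#' @return `read_phantom_spec()` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  writeLines(sprintf("%s = %.10g", names(spec),
                     vapply(spec, as.numeric, 1)), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[= \t]+")
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  known <- names(formals(phantom_spec))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown phantom key: ", paste(bad, collapse = ", "))
  do.call(phantom_spec, as.list(stats::setNames(vals, keys)))
}
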