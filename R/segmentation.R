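#' Binary label mask
#'
#' Boolean grid congruent with its source [voxel_volume()] (same shape,
#' spacing and origin). Empty masks are representable but cannot be meshed.
#'
#' @param mask Logical 3D array.
#' @param spacing,origin Geometry copied from the source volume.
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask: %s voxels, %d foreground>\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Threshold segmentation in Hounsfield Units
#'
#' A voxel is foreground iff `lower_hu <= intensity` (and `<= upper_hu` when a
#' finite upper bound is given). The default lower cutoff of 300 HU sits in
#' the 200-350 HU band commonly used for cortical bone; for CT scans of
#' PLA-printed models a window of about -900 to -200 HU matches the printed
#' material instead.
#'
#' @param volume A `voxel_volume`.
#' @param lower_hu Lower cutoff in HU (default 300, bone).
#' @param upper_hu Optional upper cutoff in HU (default `Inf`, unbounded).
#' @return A [label_mask()] with geometry copied from `volume`.
#' @export
threshold_segment <- function(volume, lower_hu = 300, upper_hu = Inf) {
  if (!inherits(volume, "voxel_volume")) stop("expected a voxel_volume")
  if (lower_hu >= upper_hu) stop("lower_hu must be below upper_hu")
  m <- volume$data >= lower_hu & volume$data <= upper_hu
  label_mask(m, volume$spacing, volume$origin)
}

#' Select one 26-connected component of a mask
#'
#' Programmatic replacement for the manual separation of pelvis, femoral head
#' and sacrum after thresholding: keep either the largest component or the one
#' containing a seed voxel. 26-connectivity is used so thin diagonal cortical
#' walls stay connected.
#'
#' @param mask A `label_mask`, non-empty.
#' @param mode `"largest"` or `"seeded"`.
#' @param seed 1-based voxel index (length 3), required for `mode = "seeded"`;
#'   must lie on a foreground voxel.
#' @return A `label_mask` containing only the selected component.
#' @export
select_component <- function(mask, mode = c("largest", "seeded"), seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(mask, "label_mask")) stop("expected a label_mask")
  if (!any(mask$mask)) stop("mask is empty")
  d <- dim(mask$mask)
  lab <- cpp_label_components(as.vector(mask$mask), d)
  if (mode == "largest") {
    target <- which.max(tabulate(lab))
  } else {
    if (is.null(seed) || length(seed) != 3L) stop("seeded mode needs a length-3 seed")
    lin <- seed[1] + d[1] * (seed[2] - 1 + d[2] * (seed[3] - 1))
    target <- lab[lin]
    if (target == 0L) stop("seed voxel is not foreground")
  }
  label_mask(array(lab == target, d), mask$spacing, mask$origin)
}

#' Extract the segmented model mesh from a mask
#'
#' Isosurface of the binary grid at the 0.5 level (marching tetrahedra), in
#' world millimetres, with consistent outward winding. The grid is padded by
#' one background voxel so masks touching the grid boundary still yield a
#' closed surface.
#'
#' @param mask A non-empty `label_mask`.
#' @return A closed `surface_mesh` (the segmented model M).
#' @export
mask_to_mesh <- function(mask) {
  if (!inherits(mask, "label_mask")) stop("expected a label_mask")
  if (!any(mask$mask)) stop("cannot mesh an empty mask")
  d <- dim(mask$mask)
  field <- array(0.5, d + 2L)           # outside value (field > iso)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- 0.5 - mask$mask
  origin <- mask$origin - mask$spacing  # padded node (1,1,1) is one voxel out
  mc <- cpp_marching_tets(as.vector(field), dim(field), origin, mask$spacing, 0)
  surface_mesh(mc$vertices, mc$faces)
}
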