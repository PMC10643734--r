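# Volume and label-mask containers.
#
# A spine_volume is a plain 3D numeric array plus voxel spacing (mm) and a
# world-space origin (mm) for the centre of voxel (1,1,1). Axis convention
# throughout the package: axis 1 = anterior -> posterior, axis 2 = cranial ->
# caudal (the craniocaudal axis), axis 3 = left -> right (the thick-slice
# direction in sagittal acquisitions). World coordinates are right-handed and
# voxel-centred: world = origin + (index - 1) * spacing.

#' Construct a 3D image volume
#'
#' Wraps a numeric 3D array together with voxel spacing and origin so all
#' geometric operations (registration, resampling, landmark extraction) can be
#' done in world millimetres rather than voxel indices.
#'
#' @param data numeric 3D array.
#' @param spacing per-axis voxel size in mm (length 3, strictly positive).
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1).
#' @return an object of class `spine_volume`.
#' @export
spine_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "spine_volume")
}

#' Construct an integer label mask
#'
#' A label mask shares the grid semantics of [spine_volume()] but stores
#' integer labels (0 = background). Used for per-vertebra instance labels and
#' body / spinous-process subregion labels.
#'
#' @inheritParams spine_volume
#' @return an object of class `label_mask` (inherits `spine_volume`).
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- spine_volume(data, spacing, origin)
  storage.mode(v$data) <- "integer"
  class(v) <- c("label_mask", "spine_volume")
  v
}

is_label_mask <- function(x) inherits(x, "label_mask")

#' @export
print.spine_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.spine_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# voxel (1-based, possibly fractional) -> world mm; idx is n x 3
voxel_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

# world mm -> voxel (1-based fractional); pts is n x 3
world_to_voxel <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

#' World coordinate of the geometric centre of a volume
#' @param vol a `spine_volume` or `label_mask`.
#' @return length-3 world position (mm).
#' @export
volume_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
}

#' Read a volume or label mask from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask read as integer [label_mask()] instead of a numeric volume.
#' @return a `spine_volume` or `label_mask`.
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (mask) label_mask(arr, sp, org) else spine_volume(arr, sp, org)
}

#' Write a volume or label mask to NIfTI
#'
#' @param vol a `spine_volume` or `label_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "spine_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::asNifti(img, qoffset_x = vol$origin[1],
                         qoffset_y = vol$origin[2], qoffset_z = vol$origin[3])
  RNifti::writeNifti(img, path)
  invisible(path)
}
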