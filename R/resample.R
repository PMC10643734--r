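# Grid resampling under rigid transforms. All sampling is voxel-centred in
# world mm; images are interpolated trilinearly, masks with nearest neighbour.

#' Describe a sampling grid
#'
#' @param dim voxel counts per axis.
#' @param spacing voxel size per axis (mm).
#' @param origin world position of the first voxel centre (mm).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  if (any(dim < 1)) stop("grid dim must be >= 1")
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Grid of an existing volume
#' @param vol a `spine_volume` or `label_mask`.
#' @return the [grid_spec()] describing its sampling grid.
#' @export
grid_of <- function(vol) grid_spec(dim(vol$data), vol$spacing, vol$origin)

# Trilinear interpolation of `arr` at fractional 1-based voxel coordinates
# (n x 3). Out-of-field samples get `background`.
interp_trilinear <- function(arr, idx, background) {
  d <- dim(arr)
  i0 <- floor(idx[, 1]); j0 <- floor(idx[, 2]); k0 <- floor(idx[, 3])
  fi <- idx[, 1] - i0; fj <- idx[, 2] - j0; fk <- idx[, 3] - k0
  acc <- numeric(nrow(idx))
  wtot <- numeric(nrow(idx))  # in-field corner weight; the rest -> background
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) *
         (if (dk) fk else 1 - fk)
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    sel <- ok & w > 0
    if (any(sel)) {
      lin <- ii[sel] + (jj[sel] - 1) * d[1] + (kk[sel] - 1) * d[1] * d[2]
      acc[sel] <- acc[sel] + w[sel] * arr[lin]
    }
    wtot[ok] <- wtot[ok] + w[ok]
  }
  acc + (1 - wtot) * background
}

interp_nearest <- function(arr, idx, background) {
  d <- dim(arr)
  ii <- round(idx[, 1]); jj <- round(idx[, 2]); kk <- round(idx[, 3])
  ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
  out <- rep(background, nrow(idx))
  lin <- ii[ok] + (jj[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
  out[ok] <- arr[lin]
  out
}

#' Resample a volume or mask under a rigid transform
#'
#' Samples `moving` on `target_grid`: the output voxel at world position w
#' takes the value of `moving` at `transform`^-1(w), i.e. `transform` maps
#' moving-space world coordinates onto target-space world coordinates. Images
#' use trilinear interpolation; label masks always use nearest neighbour.
#' Out-of-field voxels are filled with `background` (default -1024 HU for
#' images, 0 for masks).
#'
#' @param moving a `spine_volume` or `label_mask`.
#' @param transform a `rigid_transform` (identity by default).
#' @param target_grid a [grid_spec()]; defaults to the moving grid.
#' @param interpolation `"linear"` or `"nearest"`; masks must be `"nearest"`.
#' @param background fill value outside the moving field of view.
#' @return resampled object of the same class as `moving`.
#' @export
resample_onto <- function(moving, transform = rigid_transform(),
                          target_grid = grid_of(moving),
                          interpolation = c("linear", "nearest"),
                          background = NULL) {
  interp_given <- !missing(interpolation)
  interpolation <- match.arg(interpolation)
  if (is_label_mask(moving)) {
    if (interp_given && interpolation == "linear")
      stop("label masks must be resampled with nearest-neighbour interpolation")
    interpolation <- "nearest"
    if (is.null(background)) background <- 0
  } else if (is.null(background)) background <- -1024
  if (any(target_grid$spacing <= 0)) stop("target grid spacing must be positive")

  d <- target_grid$dim
  g <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                             k = seq_len(d[3])))
  world <- sweep(sweep(g - 1, 2, target_grid$spacing, `*`), 2,
                 target_grid$origin, `+`)
  src_world <- transform_points(invert_transform(transform), world)
  src_idx <- world_to_voxel(moving, src_world)
  vals <- if (interpolation == "linear") {
    interp_trilinear(moving$data, src_idx, background)
  } else {
    interp_nearest(moving$data, src_idx, background)
  }
  arr <- array(vals, dim = d)
  if (is_label_mask(moving)) {
    label_mask(arr, target_grid$spacing, target_grid$origin)
  } else {
    spine_volume(arr, target_grid$spacing, target_grid$origin)
  }
}
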