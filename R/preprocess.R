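# Intensity normalisation, augmentation, resampling, slicing and patching:
# the rules that turn registered volume pairs into training samples.

#' Normalise a CT volume from HU to [-1, 1]
#'
#' `v -> clamp(v / 1000, -1, 1)`: air maps to -1, water to 0, and anything
#' at or above 1000 HU saturates at 1, retaining the air / soft-tissue /
#' bone contrast while suppressing extreme intensities.
#'
#' @param ct a `spine_volume` in HU, or a bare numeric array.
#' @return same type, values in [-1, 1].
#' @export
normalize_ct <- function(ct) {
  arr <- if (inherits(ct, "spine_volume")) ct$data else ct
  nbad <- sum(!is.finite(arr))
  if (nbad > 0) stop("CT contains ", nbad, " non-finite voxel(s)")
  out <- pmin(pmax(arr / 1000, -1), 1)
  if (inherits(ct, "spine_volume")) spine_volume(out, ct$spacing, ct$origin)
  else out
}

#' Normalise an MR volume to [-1, 1]
#'
#' Linear rescale of [0, max] onto [-1, 1], with max the volume-wise maximum:
#' `v -> 2 v / max - 1`.
#'
#' @param mr a `spine_volume` with values >= 0, or a bare numeric array.
#' @return same type, values in [-1, 1].
#' @export
normalize_mr <- function(mr) {
  arr <- if (inherits(mr, "spine_volume")) mr$data else mr
  mx <- max(arr)
  if (mx <= 0) stop("degenerate intensity range: MR maximum must be > 0")
  out <- 2 * arr / mx - 1
  if (inherits(mr, "spine_volume")) spine_volume(out, mr$spacing, mr$origin)
  else out
}

#' Random brightness / contrast jitter
#'
#' Emulates scanner-to-scanner intensity variability on normalized MR data:
#' brightness `b ~ U(1 - s, 1 + s)` and contrast `c ~ U(1 - s, 1 + s)` are
#' applied as `v -> clamp(c (b v - m) + m, -1, 1)` with `m` the mean of the
#' input, so the jitter is anchored at the image's own mean level.
#'
#' @param x array or `spine_volume` in [-1, 1].
#' @param strength jitter half-range (default 0.2).
#' @param seed optional seed for a deterministic draw.
#' @return same type and shape as `x`.
#' @export
jitter_mr <- function(x, strength = 0.2, seed = NULL) {
  if (strength < 0) stop("strength must be >= 0")
  if (strength == 0) return(x)
  arr <- if (inherits(x, "spine_volume")) x$data else x
  appl <- function() {
    b <- stats::runif(1, 1 - strength, 1 + strength)
    cf <- stats::runif(1, 1 - strength, 1 + strength)
    m <- mean(arr)
    pmin(pmax(cf * (b * arr - m) + m, -1), 1)
  }
  out <- if (is.null(seed)) appl() else with_seed(seed, appl())
  if (inherits(x, "spine_volume")) spine_volume(out, x$spacing, x$origin)
  else out
}

resample_to_spacing <- function(vol, new_spacing) {
  d <- dim(vol$data)
  if (all(abs(vol$spacing - new_spacing) < 1e-9)) return(vol)
  new_dim <- pmax(1L, as.integer(round(d * vol$spacing / new_spacing)))
  resample_onto(vol, rigid_transform(),
                grid_spec(new_dim, new_spacing, vol$origin),
                if (is_label_mask(vol)) "nearest" else "linear")
}

#' Resample a paired case to the training resolution
#'
#' `sagittal_2d`: 1 x 1 mm in the sagittal plane, through-plane (left-right)
#' spacing preserved — the thick-slice 2D regime. `isotropic_3d`: 1 mm on
#' all axes, required by the volumetric model. Images are interpolated
#' linearly, masks nearest-neighbour.
#'
#' @param case an aligned `paired_case` (no pending misalignment).
#' @param mode `"sagittal_2d"` or `"isotropic_3d"`.
#' @return the resampled `paired_case`.
#' @export
resample_pair <- function(case, mode = c("sagittal_2d", "isotropic_3d")) {
  mode <- match.arg(mode)
  sp <- case$mr$spacing
  new_sp <- if (mode == "sagittal_2d") c(1, 1, sp[3]) else c(1, 1, 1)
  out <- case
  out$mr <- resample_to_spacing(case$mr, new_sp)
  out$ct <- resample_to_spacing(case$ct, new_sp)
  out$mask <- resample_to_spacing(case$mask, new_sp)
  if (!is.null(case$ct_mask))
    out$ct_mask <- resample_to_spacing(case$ct_mask, new_sp)
  out
}

# dense displacement field (mm) by trilinear upsampling of a coarse control
# grid of Gaussian displacements
dense_displacement <- function(d, sp, control_points, sd_mm) {
  ext <- (d - 1) * sp
  ctrl <- array(stats::rnorm(prod(control_points) * 3, 0, sd_mm),
                c(control_points, 3))
  # fractional control-grid coordinates of each voxel
  g <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                             k = seq_len(d[3])))
  frac <- sweep(sweep(g - 1, 2, sp, `*`), 2, pmax(ext, 1e-9), `/`)
  idx <- sweep(frac, 2, control_points - 1, `*`) + 1
  disp <- matrix(0, nrow(g), 3)
  for (a in 1:3)
    disp[, a] <- interp_trilinear(array(ctrl[, , , a], control_points), idx, 0)
  disp
}

warp_volume <- function(vol, disp, background) {
  d <- dim(vol$data)
  g <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                             k = seq_len(d[3])))
  src_idx <- g + sweep(disp, 2, vol$spacing, `/`)
  vals <- if (is_label_mask(vol)) interp_nearest(vol$data, src_idx, background)
          else interp_trilinear(vol$data, src_idx, background)
  arr <- array(vals, d)
  if (is_label_mask(vol)) label_mask(arr, vol$spacing, vol$origin)
  else spine_volume(arr, vol$spacing, vol$origin)
}

#' Elastic augmentation of a paired case
#'
#' Generates `copies` elastically deformed versions of the case to enlarge
#' the training set and emulate weak scoliosis and residual misalignment.
#' Each copy draws a coarse control grid (default 5 x 5 x 5) of Gaussian
#' displacements (default SD 4 mm), upsamples it to a dense field, and warps
#' MR, CT and mask with the *identical* field (mask nearest-neighbour), so
#' image and labels stay geometrically consistent and no new labels appear.
#'
#' @param case an aligned `paired_case`.
#' @param copies number of deformed copies (default 10).
#' @param sd_mm control-point displacement SD in mm.
#' @param control_points control-grid size per axis.
#' @param seed base seed; copy i uses `seed + i`.
#' @return list of `copies` deformed `paired_case`s.
#' @export
elastic_augment <- function(case, copies = 10L, sd_mm = 4, control_points = 5L,
                            seed = 1L) {
  cp <- rep_len(as.integer(control_points), 3)
  d <- dim(case$mr$data)
  lapply(seq_len(copies), function(i) {
    disp <- with_seed(seed + i, dense_displacement(d, case$mr$spacing, cp, sd_mm))
    out <- case
    out$mr <- warp_volume(case$mr, disp, background = min(case$mr$data))
    out$ct <- warp_volume(case$ct, disp, background = -1024)
    out$mask <- warp_volume(case$mask, disp, background = 0)
    out$meta$deformation <- list(index = i, sd_mm = sd_mm, seed = seed + i)
    out
  })
}

crop_or_pad_2d <- function(sl, i0, j0, size, fill) {
  out <- matrix(fill, size, size)
  src_i <- max(1, i0):min(nrow(sl), i0 + size - 1)
  src_j <- max(1, j0):min(ncol(sl), j0 + size - 1)
  if (length(src_i) > 0 && length(src_j) > 0)
    out[src_i - i0 + 1, src_j - j0 + 1] <- sl[src_i, src_j]
  out
}

#' Build 2D training / evaluation samples from cases
#'
#' Slices each case sagittally (along the left-right axis), drops slices
#' whose mask plane is empty, and crops to `crop_size` square. Training mode
#' draws one random in-bounds crop per slice; evaluation mode emits one
#' deterministic crop centred on the mask's in-plane bounding box. Slices
#' smaller than the crop are padded with the background value (-1 = air).
#'
#' @param cases list of normalized, resampled `paired_case`s.
#' @param crop_size square crop side in pixels (default 256).
#' @param mode `"train"` (random crop) or `"eval"` (deterministic centred).
#' @param seed seed for the random crops.
#' @return list of records: `mr`, `ct` (matrices in [-1, 1]), `mask`
#'   (integer matrix with >= 1 nonzero pixel), and `provenance`.
#' @export
make_2d_dataset <- function(cases, crop_size = 256L, mode = c("train", "eval"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(cases, "paired_case")) cases <- list(cases)
  recs <- list()
  with_seed(seed, {
    for (ci in seq_along(cases)) {
      case <- cases[[ci]]
      d <- dim(case$mr$data)
      for (k in seq_len(d[3])) {
        mk <- case$mask$data[, , k]
        if (!any(mk != 0)) next
        nz <- which(mk != 0, arr.ind = TRUE)
        if (mode == "eval") {
          ci0 <- floor((min(nz[, 1]) + max(nz[, 1])) / 2 - crop_size / 2) + 1L
          cj0 <- floor((min(nz[, 2]) + max(nz[, 2])) / 2 - crop_size / 2) + 1L
          ci0 <- min(max(ci0, min(1, d[1] - crop_size + 1)),
                     max(d[1] - crop_size + 1, 1))
          cj0 <- min(max(cj0, min(1, d[2] - crop_size + 1)),
                     max(d[2] - crop_size + 1, 1))
        } else {
          # draw random crops until one contains segmentation
          for (try in seq_len(20L)) {
            ci0 <- if (d[1] > crop_size)
              sample.int(d[1] - crop_size + 1, 1) else 1L
            cj0 <- if (d[2] > crop_size)
              sample.int(d[2] - crop_size + 1, 1) else 1L
            if (any(mk[ci0:min(ci0 + crop_size - 1, d[1]),
                       cj0:min(cj0 + crop_size - 1, d[2])] != 0)) break
          }
        }
        msl <- crop_or_pad_2d(mk, ci0, cj0, crop_size, 0L)
        if (!any(msl != 0)) next
        recs[[length(recs) + 1L]] <- list(
          mr = crop_or_pad_2d(case$mr$data[, , k], ci0, cj0, crop_size, -1),
          ct = crop_or_pad_2d(case$ct$data[, , k], ci0, cj0, crop_size, -1),
          mask = msl,
          provenance = list(case = ci, slice = k, crop = c(ci0, cj0),
                            deformation = case$meta$deformation$index %||% 0L))
      }
    }
  })
  recs
}

# normalized position ramp of an axis: value at voxel i is (i-1)/(n-1)
axis_ramp <- function(n) if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5

#' Sample 3D training patches with position ramps
#'
#' Draws random patches of `patch_shape` from each case; patches containing
#' no mask voxels are rejected. Each patch carries three ramp channels
#' giving every voxel's normalized position within the *full* volume (each
#' axis affine from 0 to 1 over the whole extent), so the fully-convolutional
#' 3D model keeps a notion of anatomical position. Volumes smaller than the
#' patch are padded with air (-1) and flagged in the provenance.
#'
#' @param cases list of isotropic-resampled, normalized `paired_case`s.
#' @param patch_shape patch voxel counts (default `c(128, 128, 32)`).
#' @param n_per_case patches drawn per case.
#' @param seed RNG seed; the patch sequence is deterministic given it.
#' @param max_tries rejection-sampling budget per patch.
#' @return list of records: `mr`, `ct` (3D arrays), `mask`, `ramps`
#'   (array `patch_shape x 3`), `provenance`.
#' @export
make_3d_patches <- function(cases, patch_shape = c(128L, 128L, 32L),
                            n_per_case = 4L, seed = 1L, max_tries = 50L) {
  if (inherits(cases, "paired_case")) cases <- list(cases)
  ps <- as.integer(patch_shape)
  recs <- list()
  with_seed(seed, {
    for (ci in seq_along(cases)) {
      case <- cases[[ci]]
      d <- dim(case$mr$data)
      padded <- any(d < ps)
      pad_to <- pmax(d, ps)
      get_arr <- function(vol, fill) {
        if (!padded) return(vol$data)
        out <- array(fill, pad_to)
        out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol$data
        out
      }
      mr_a <- get_arr(case$mr, -1); ct_a <- get_arr(case$ct, -1)
      mk_a <- get_arr(case$mask, 0L)
      ramps_full <- list(axis_ramp(pad_to[1]), axis_ramp(pad_to[2]),
                         axis_ramp(pad_to[3]))
      for (p in seq_len(n_per_case)) {
        got <- FALSE
        for (try in seq_len(max_tries)) {
          o <- vapply(1:3, function(a)
            if (pad_to[a] > ps[a]) sample.int(pad_to[a] - ps[a] + 1, 1) else 1L,
            integer(1))
          ii <- o[1]:(o[1] + ps[1] - 1); jj <- o[2]:(o[2] + ps[2] - 1)
          kk <- o[3]:(o[3] + ps[3] - 1)
          mkp <- mk_a[ii, jj, kk]
          if (!any(mkp != 0)) next
          ramps <- array(0, c(ps, 3))
          ramps[, , , 1] <- array(ramps_full[[1]][ii], ps)
          ramps[, , , 2] <- array(rep(ramps_full[[2]][jj], each = ps[1]), ps)
          ramps[, , , 3] <- array(rep(ramps_full[[3]][kk],
                                      each = ps[1] * ps[2]), ps)
          recs[[length(recs) + 1L]] <- list(
            mr = mr_a[ii, jj, kk], ct = ct_a[ii, jj, kk], mask = mkp,
            ramps = ramps,
            provenance = list(case = ci, offset = o, padded = padded))
          got <- TRUE
          break
        }
        if (!got)
          warning("no mask-containing patch found for case ", ci)
      }
    }
  })
  recs
}
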