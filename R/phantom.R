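# Synthetic spine phantom: paired MR-like / CT-like sagittal volumes with
# ground-truth instance + subregion labels and a known, configurable rigid
# misalignment. Every downstream stage (registration, translation, metric
# evaluation) is testable against this generator without external data.
#
# Geometry per vertebra: an ellipsoidal vertebral body, a thin posterior arch
# rod, and a rectangular spinous-process block. Vertebrae are stacked along
# the craniocaudal axis (axis 2) inside a soft-tissue torso cylinder; the
# remainder is air. The CT compartments are a deterministic function of the
# tissue class, and the MR is a different deterministic function of the same
# tissue class (non-monotonically related: bone is bright in CT but dark in
# MR), so the true MR->CT translation is known analytically.

#' Phantom configuration
#'
#' @param n_vertebrae number of vertebrae (>= 1).
#' @param grid_shape voxel counts per axis (AP, craniocaudal, LR).
#' @param spacing_mm voxel size per axis in mm; default emulates thin-slice
#'   sagittal acquisitions (fine in plane, coarse left-right).
#' @param body_radii_mm ellipsoid semi-axes of the vertebral body (mm).
#' @param process_size_mm spinous-process block extents (AP length,
#'   craniocaudal height, LR width, in mm).
#' @param ct_intensities named HU values for the air / soft-tissue / bone
#'   compartments, each in [-1024, 3000].
#' @param mr_intensities named arbitrary-unit (>= 0) values per compartment;
#'   default makes bone dark and soft tissue bright, the non-monotonic
#'   MR/CT relationship that defeats intensity-only translation.
#' @param noise_sd additive Gaussian noise SD per modality, named `mr`, `ct`.
#' @param misalignment `NULL`, or a list with `angle_deg`, `axis`
#'   (see [rotation_about()]) and `translation_mm`, applied to the CT side.
#' @param seed integer; the single source of randomness for the phantom.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_vertebrae = 5,
                           grid_shape = c(64, 96, 20),
                           spacing_mm = c(1, 1, 3),
                           body_radii_mm = c(7, 6, 9),
                           process_size_mm = c(10, 7, 5),
                           ct_intensities = c(air = -1000, soft = 40, bone = 700),
                           mr_intensities = c(air = 0, soft = 800, bone = 150),
                           noise_sd = c(mr = 30, ct = 20),
                           misalignment = NULL,
                           seed = 1L) {
  cfg <- list(n_vertebrae = as.integer(n_vertebrae),
              grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              body_radii_mm = as.numeric(body_radii_mm),
              process_size_mm = as.numeric(process_size_mm),
              ct_intensities = ct_intensities,
              mr_intensities = mr_intensities,
              noise_sd = noise_sd,
              misalignment = misalignment,
              seed = as.integer(seed))
  if (cfg$n_vertebrae < 1) stop("n_vertebrae must be >= 1")
  if (any(cfg$spacing_mm <= 0)) stop("spacing_mm must be strictly positive")
  if (any(cfg$body_radii_mm <= 0) || any(cfg$process_size_mm <= 0))
    stop("all radii/extents must be strictly positive")
  if (any(ct_intensities < -1024) || any(ct_intensities > 3000))
    stop("ct_intensities must lie in [-1024, 3000] HU")
  if (any(mr_intensities < 0)) stop("mr_intensities must be >= 0")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  class(cfg) <- "phantom_config"
  cfg
}

# evaluate an expression under a seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  # pin the generator kinds so results do not depend on session state
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# per-vertebra label scheme: body = 2*id - 1, spinous process = 2*id
body_label <- function(id) 2L * id - 1L
process_label <- function(id) 2L * id

#' Generate a paired MR/CT spine phantom
#'
#' Builds the tissue map, renders both modalities from it, adds independent
#' per-modality noise, and (optionally) applies the configured rigid
#' misalignment to the CT side. The returned case carries the ground-truth
#' label mask (aligned with the MR), a label table mapping vertebra ids to
#' body / spinous-process labels, the true body and process centroids in mm,
#' and the applied misalignment (or `NULL`).
#'
#' @param config a [phantom_config()].
#' @return an object of class `paired_case` with elements `mr`, `ct`, `mask`,
#'   `label_table`, `truth_transform`, `meta`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape; sp <- config$spacing_mm
  ext <- d * sp  # physical extent mm
  rb <- config$body_radii_mm; ps <- config$process_size_mm

  # vertebra placement along the craniocaudal axis
  margin <- rb[2] + 2
  usable <- ext[2] - 2 * margin
  pitch <- usable / config$n_vertebrae
  if (pitch < 2 * rb[2] + 1)
    stop(sprintf(paste0("grid too small along the craniocaudal axis: need ",
                        "%.0f mm for %d vertebrae, have %.0f mm usable"),
                 config$n_vertebrae * (2 * rb[2] + 1), config$n_vertebrae,
                 usable))
  arch_len <- 6
  body_cx <- max(rb[1] + 2, ext[1] * 0.4 - ps[1])
  proc_x0 <- body_cx + rb[1] + arch_len
  if (proc_x0 + ps[1] > ext[1] - 1)
    stop("grid too small along the anterior-posterior axis for the spinous process")
  if (2 * rb[3] + 2 > ext[3])
    stop("grid too small along the left-right axis for the vertebral body")
  cz <- ext[3] / 2
  cys <- margin + pitch * (seq_len(config$n_vertebrae) - 0.5)

  # world coordinates of voxel centres
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  # torso: elliptical soft-tissue cylinder along the craniocaudal axis
  torso_cx <- ext[1] / 2
  torso <- ((X - torso_cx) / (ext[1] * 0.46))^2 +
    ((Z - cz) / (ext[3] * 0.46))^2 <= 1
  tissue <- array(0L, dim = d)  # 0 air, 1 soft, 2 bone
  tissue[torso] <- 1L
  mask <- array(0L, dim = d)

  body_centers <- matrix(NA_real_, config$n_vertebrae, 3)
  proc_centers <- matrix(NA_real_, config$n_vertebrae, 3)
  for (v in seq_len(config$n_vertebrae)) {
    cy <- cys[v]
    body <- ((X - body_cx) / rb[1])^2 + ((Y - cy) / rb[2])^2 +
      ((Z - cz) / rb[3])^2 <= 1
    arch <- X > body_cx + rb[1] - 1 & X <= proc_x0 &
      abs(Y - cy) <= 1.5 & abs(Z - cz) <= 1.5
    proc <- X > proc_x0 & X <= proc_x0 + ps[1] &
      abs(Y - cy) <= ps[2] / 2 & abs(Z - cz) <= ps[3] / 2
    if (!any(body) || !any(proc))
      stop("grid too coarse: a vertebral substructure contains no voxels")
    mask[body] <- body_label(v)
    mask[arch | proc] <- process_label(v)
    tissue[body | arch | proc] <- 2L
    body_centers[v, ] <- c(body_cx, cy, cz)
    proc_centers[v, ] <- c(proc_x0 + ps[1] / 2, cy, cz)
  }

  cti <- as.numeric(config$ct_intensities)
  mri <- as.numeric(config$mr_intensities)
  ct_clean <- array(cti[tissue + 1L], dim = d)
  mr_clean <- array(mri[tissue + 1L], dim = d)
  noisy <- with_seed(config$seed, {
    ct <- ct_clean
    mr <- mr_clean
    if (config$noise_sd[["mr"]] > 0)
      mr <- mr + array(stats::rnorm(prod(d), 0, config$noise_sd[["mr"]]), d)
    if (config$noise_sd[["ct"]] > 0)
      ct <- ct + array(stats::rnorm(prod(d), 0, config$noise_sd[["ct"]]), d)
    list(mr = pmax(mr, 0), ct = ct)
  })

  case <- structure(list(
    mr = spine_volume(noisy$mr, sp),
    ct = spine_volume(noisy$ct, sp),
    mask = label_mask(mask, sp),
    label_table = data.frame(vertebra = seq_len(config$n_vertebrae),
                             body = body_label(seq_len(config$n_vertebrae)),
                             process = process_label(seq_len(config$n_vertebrae))),
    truth_transform = NULL,
    meta = list(body_centers = body_centers, process_centers = proc_centers,
                config = config,
                ct_clean = spine_volume(ct_clean, sp))
  ), class = "paired_case")

  if (!is.null(config$misalignment)) {
    m <- config$misalignment
    tf <- rotation_about(m$angle_deg %||% 0, m$axis %||% "craniocaudal",
                         center = volume_center(case$ct),
                         translation = m$translation_mm %||% c(0, 0, 0))
    case <- apply_misalignment(case, tf)
  }
  case
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.paired_case <- function(x, ...) {
  d <- dim(x$mr$data)
  cat(sprintf("<paired_case> %d vertebrae, grid %d x %d x %d, spacing %s mm\n",
              nrow(x$label_table), d[1], d[2], d[3],
              paste(format(x$mr$spacing), collapse = " x ")))
  if (!is.null(x$truth_transform))
    cat(sprintf("  CT misaligned: %.2f deg rotation, |t| = %.2f mm\n",
                rotation_angle(x$truth_transform) * 180 / pi,
                sqrt(sum(x$truth_transform$translation^2))))
  invisible(x)
}

#' Apply a rigid misalignment to the CT side of a case
#'
#' Resamples the CT (linear) and its mask (nearest neighbour) under
#' `transform` on the original grid and records the transform as the case's
#' ground truth. The MR is untouched, emulating a CT acquired in a different
#' patient position. The CT-side mask travels with the CT; the case `mask`
#' stays aligned with the MR.
#'
#' @param case a `paired_case`.
#' @param transform a [rigid_transform()]; `|det(R) - 1|` is validated.
#' @return the misaligned `paired_case`, with `ct_mask` holding the moved mask.
#' @export
apply_misalignment <- function(case, transform) {
  stopifnot(inherits(case, "paired_case"), inherits(transform, "rigid_transform"))
  base_mask <- case$ct_mask %||% case$mask
  out <- case
  out$ct <- resample_onto(case$ct, transform, grid_of(case$ct), "linear")
  out$ct_mask <- resample_onto(base_mask, transform, grid_of(base_mask))
  out$truth_transform <- if (is.null(case$truth_transform)) transform else
    compose_transforms(transform, case$truth_transform)
  out
}

# ---- connected components (6-connectivity), vectorised frontier flood fill

connected_components <- function(bin) {
  d <- dim(bin)
  n <- prod(d)
  lab <- integer(n)
  binv <- as.vector(bin)
  remaining <- which(binv)
  comp <- 0L
  s1 <- 1L; s2 <- d[1]; s3 <- d[1] * d[2]
  while (length(remaining) > 0) {
    comp <- comp + 1L
    frontier <- remaining[1]
    lab[frontier] <- comp
    while (length(frontier) > 0) {
      nb <- integer(0)
      i <- ((frontier - 1L) %% d[1]) + 1L
      j <- (((frontier - 1L) %/% d[1]) %% d[2]) + 1L
      k <- ((frontier - 1L) %/% (d[1] * d[2])) + 1L
      nb <- c(frontier[i > 1] - s1, frontier[i < d[1]] + s1,
              frontier[j > 1] - s2, frontier[j < d[2]] + s2,
              frontier[k > 1] - s3, frontier[k < d[3]] + s3)
      nb <- unique(nb[binv[nb] & lab[nb] == 0L])
      lab[nb] <- comp
      frontier <- nb
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  array(lab, dim = d)
}

#' Threshold-based vertebra segmenter for phantom CT
#'
#' A reference segmenter playing the role of an external CT segmentation
#' model: thresholds bone intensity, extracts 6-connected components, orders
#' them cranial to caudal, assigns vertebra ids, and splits each component
#' into vertebral body and spinous process at the anterior-posterior position
#' where the cross-sectional area collapses into the thin posterior arch.
#' Output labels follow the package scheme (body `2*id - 1`, process `2*id`).
#'
#' @param ct a `spine_volume`, in HU (`scale = "hu"`, threshold 150 HU) or on
#'   the normalized [-1, 1] scale (`scale = "normalized"`, threshold 0.15).
#'   The default threshold sits well above soft tissue but below
#'   partial-volume-diluted bone, so thin resampled structures survive.
#' @param scale intensity scale of `ct`.
#' @param threshold bone threshold override.
#' @param min_voxels components smaller than this are discarded as noise.
#' @return a `label_mask` on the CT grid.
#' @export
phantom_segmenter <- function(ct, scale = c("hu", "normalized"),
                              threshold = NULL, min_voxels = 8L) {
  scale <- match.arg(scale)
  if (is.null(threshold)) threshold <- if (scale == "hu") 150 else 0.15
  bin <- ct$data > threshold
  if (!any(bin)) stop("empty segmentation: no voxel above the bone threshold")
  comps <- connected_components(bin)
  sizes <- tabulate(comps)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0) stop("empty segmentation: all components below min_voxels")
  d <- dim(comps)

  # craniocaudal (axis 2) intervals per component; a spinous process severed
  # from its body by partial volume shares its body's interval, while
  # neighbouring vertebrae do not overlap, so components with intersecting
  # intervals belong to one vertebra
  jr <- lapply(keep, function(cmp) {
    idx <- which(comps == cmp)
    j <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
    c(min(j), max(j), mean(j))
  })
  groups <- as.list(seq_along(keep))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      if (is.null(groups[[a]])) next
      for (b in seq_along(groups)) {
        if (b <= a || is.null(groups[[b]])) next
        ra <- range(unlist(lapply(groups[[a]], function(k) jr[[k]][1:2])))
        rb <- range(unlist(lapply(groups[[b]], function(k) jr[[k]][1:2])))
        if (ra[1] <= rb[2] && rb[1] <= ra[2]) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  groups <- Filter(Negate(is.null), groups)
  cent_j <- vapply(groups, function(g)
    mean(vapply(g, function(k) jr[[k]][3], numeric(1))), numeric(1))
  groups <- groups[order(cent_j)]

  out <- array(0L, dim = d)
  for (v in seq_along(groups)) {
    idx <- unlist(lapply(groups[[v]], function(k) which(comps == keep[k])))
    i <- ((idx - 1L) %% d[1]) + 1L
    # AP cross-sectional area profile; the split point is where the profile
    # collapses into the thin posterior arch (or a partial-volume gap)
    area <- tabulate(i, nbins = d[1])
    amax <- max(area)
    peak <- which.max(area)
    thin <- if (peak < max(i)) {
      post <- seq(peak + 1L, max(i))
      post[area[post] < 0.2 * amax]
    } else integer(0)
    split_i <- if (length(thin) > 0) min(thin) else d[1] + 1L
    out[idx[i < split_i]] <- body_label(v)
    out[idx[i >= split_i]] <- process_label(v)
  }
  label_mask(out, ct$spacing, ct$origin)
}

#' Analytic MR-to-CT oracle for the phantom
#'
#' Returns a translator callable that classifies each MR voxel to its nearest
#' phantom tissue class and emits that class's CT intensity — the exact
#' translation implied by the generator. Useful as a drop-in for a trained
#' model when testing registration refinement and the evaluation pipeline.
#'
#' @param config the [phantom_config()] that produced the MR.
#' @return function mapping an MR `spine_volume` to a CT `spine_volume` (HU).
#' @export
phantom_oracle_translator <- function(config = phantom_config()) {
  mri <- as.numeric(config$mr_intensities)
  cti <- as.numeric(config$ct_intensities)
  function(mr) {
    stopifnot(inherits(mr, "spine_volume"))
    dmat <- vapply(mri, function(m) as.vector((mr$data - m)^2),
                   numeric(length(mr$data)))
    cls <- max.col(-dmat, ties.method = "first")
    spine_volume(array(cti[cls], dim = dim(mr$data)), mr$spacing, mr$origin)
  }
}
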