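# Landmark-based rigid registration. Landmarks are per-vertebra centres of
# mass (vertebral body for the 1-point mode; body + spinous process for the
# 2-point mode). The fit is a single global least-squares rigid transform
# over all matched landmarks (Kabsch/SVD), in world millimetres.

#' Build a landmark set
#'
#' @param vertebra integer vertebra ids.
#' @param structure `"body"` or `"spinous_process"` per landmark.
#' @param position n x 3 matrix of world coordinates (mm).
#' @return a `landmark_set` data frame with columns vertebra, structure, x, y, z.
#' @export
landmark_set <- function(vertebra, structure, position) {
  position <- matrix(position, ncol = 3)
  structure <- as.character(structure)
  if (!all(structure %in% c("body", "spinous_process")))
    stop("structure must be 'body' or 'spinous_process'")
  if (any(!is.finite(position))) stop("landmark positions must be finite")
  key <- paste(vertebra, structure)
  if (anyDuplicated(key)) stop("(vertebra, structure) pairs must be unique")
  out <- data.frame(vertebra = as.integer(vertebra), structure = structure,
                    x = position[, 1], y = position[, 2], z = position[, 3])
  class(out) <- c("landmark_set", "data.frame")
  out
}

lm_points <- function(lm) as.matrix(lm[, c("x", "y", "z")])

#' Extract centre-of-mass landmarks from a label mask
#'
#' Each landmark is the unweighted mean voxel position of a (vertebra,
#' structure) label, mapped to world coordinates. Labels follow the package
#' scheme (body `2*id - 1`, spinous process `2*id`) unless a `label_table`
#' with columns `vertebra`, `body`, `process` is supplied.
#'
#' @param mask a `label_mask`.
#' @param structures which structures to extract.
#' @param label_table optional explicit label mapping.
#' @return a `landmark_set`.
#' @export
extract_centroids <- function(mask,
                              structures = c("body", "spinous_process"),
                              label_table = NULL) {
  stopifnot(is_label_mask(mask))
  structures <- match.arg(structures, several.ok = TRUE)
  labs <- sort(setdiff(unique(as.vector(mask$data)), 0L))
  if (is.null(label_table)) {
    ids <- sort(unique((labs + 1L) %/% 2L))
    label_table <- data.frame(vertebra = ids, body = 2L * ids - 1L,
                              process = 2L * ids)
  }
  rows <- list(); missing <- integer(0)
  d <- dim(mask$data)
  for (r in seq_len(nrow(label_table))) {
    for (s in structures) {
      lab <- if (s == "body") label_table$body[r] else label_table$process[r]
      idx <- which(mask$data == lab)
      if (length(idx) == 0) { missing <- c(missing, label_table$vertebra[r]); next }
      i <- ((idx - 1L) %% d[1]) + 1L
      j <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
      k <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
      pos <- voxel_to_world(mask, cbind(mean(i), mean(j), mean(k)))
      rows[[length(rows) + 1L]] <-
        data.frame(vertebra = label_table$vertebra[r], structure = s,
                   x = pos[1], y = pos[2], z = pos[3])
    }
  }
  if (length(missing) > 0)
    stop("missing landmark structure for vertebra id(s): ",
         paste(unique(missing), collapse = ", "))
  out <- do.call(rbind, rows)
  landmark_set(out$vertebra, out$structure, as.matrix(out[, c("x", "y", "z")]))
}

# minimal rotation taking unit vector a onto unit vector b
minimal_rotation_between <- function(a, b) {
  if (sum(a * b) < 0) b <- -b  # line directions: orientation-free
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) return(diag(3))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Least-squares rigid fit between matched landmark sets (Kabsch)
#'
#' Finds the proper rigid transform minimising the sum of squared distances
#' `sum ||R m + t - f||^2` over landmarks matched by (vertebra, structure).
#' Solved in closed form: centre both sets, SVD of the cross-covariance, and
#' sign-correct the smallest singular vector so that det(R) = +1. Unmatched
#' landmarks are dropped with a warning. Collinear configurations leave the
#' rotation about the common line unconstrained; the fit then resolves to the
#' minimal-rotation solution (the rotation that maps one line direction onto
#' the other with the smallest angle) and warns.
#'
#' @param moving,fixed `landmark_set`s; `moving` is mapped onto `fixed`.
#' @return a [rigid_transform()] with attributes `rmse` (mm) and `n_landmarks`.
#' @export
fit_rigid <- function(moving, fixed) {
  key_m <- paste(moving$vertebra, moving$structure)
  key_f <- paste(fixed$vertebra, fixed$structure)
  common <- intersect(key_m, key_f)
  if (length(common) < length(key_m) || length(common) < length(key_f))
    warning("dropping ", length(key_m) + length(key_f) - 2 * length(common),
            " unmatched landmark(s)")
  if (length(common) < 3)
    stop("insufficient landmarks: need >= 3 matched points, have ",
         length(common))
  M <- lm_points(moving)[match(common, key_m), , drop = FALSE]
  F_ <- lm_points(fixed)[match(common, key_f), , drop = FALSE]
  mbar <- colMeans(M); fbar <- colMeans(F_)
  Mc <- sweep(M, 2, mbar); Fc <- sweep(F_, 2, fbar)

  sv_m <- svd(Mc)
  collinear <- sv_m$d[2] < 1e-8 * max(sv_m$d[1], 1e-12)
  if (collinear) {
    warning("collinear landmark configuration: rotation about the common ",
            "axis is unconstrained; returning the minimal-rotation solution")
    sv_f <- svd(Fc)
    R <- minimal_rotation_between(sv_m$v[, 1], sv_f$v[, 1])
  } else {
    H <- crossprod(Mc, Fc)  # sum m f^T
    sv <- svd(H)
    s <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  }
  t_ <- as.numeric(fbar - R %*% mbar)
  tf <- rigid_transform(R, t_)
  resid <- transform_points(tf, M) - F_
  attr(tf, "rmse") <- sqrt(mean(rowSums(resid^2)))
  attr(tf, "n_landmarks") <- length(common)
  tf
}

#' Iterative registration refinement via translate-and-segment
#'
#' Implements the closed loop that bootstraps registration from a translator:
#' translate the MR to a synthetic CT, segment it to get MR-space landmarks,
#' fit the real CT's landmarks onto them, resample the CT, and repeat with
#' fresh CT-side landmarks. Stops after `rounds` refinement rounds or when
#' the mean landmark displacement of a round drops below `tol_mm`.
#'
#' @param mr the MR `spine_volume` (reference side).
#' @param ct the (possibly misaligned) CT `spine_volume`.
#' @param translator callable MR volume -> synthetic CT volume (HU).
#' @param segmenter callable CT volume -> `label_mask`.
#' @param rounds maximum refinement rounds after the initial fit (>= 0).
#' @param points 1 = vertebral bodies only, 2 = bodies + spinous processes.
#' @param tol_mm early-stop threshold on mean landmark displacement.
#' @return list with `transform` (CT -> MR), `landmarks` (last CT-side set),
#'   `ct_registered`, `rounds_run`, `displacements` (mm per round).
#' @export
refine_registration <- function(mr, ct, translator, segmenter, rounds = 3,
                                points = 2, tol_mm = 0.5) {
  stopifnot(points %in% c(1, 2))
  structures <- if (points == 1) "body" else c("body", "spinous_process")
  synth <- translator(mr)
  fixed_lm <- tryCatch(extract_centroids(segmenter(synth), structures),
                       error = function(e)
                         stop("segmenter failed on translated MR: ",
                              conditionMessage(e)))
  run_fit <- function(ct_now, round_idx) {
    lm <- tryCatch(extract_centroids(segmenter(ct_now), structures),
                   error = function(e)
                     stop("segmenter failed on CT (round ", round_idx, "): ",
                          conditionMessage(e)))
    list(lm = lm, tf = fit_rigid(lm, fixed_lm))
  }
  init <- run_fit(ct, 0L)
  total <- init$tf
  last_lm <- init$lm
  disp <- numeric(0)
  r <- 0L
  while (r < rounds) {
    r <- r + 1L
    ct_now <- resample_onto(ct, total, grid_of(mr), "linear")
    step <- run_fit(ct_now, r)
    last_lm <- step$lm
    pts <- lm_points(step$lm)
    d_mm <- mean(sqrt(rowSums((transform_points(step$tf, pts) - pts)^2)))
    disp <- c(disp, d_mm)
    total <- compose_transforms(step$tf, total)
    if (d_mm < tol_mm) break
  }
  list(transform = total, landmarks = last_lm,
       ct_registered = resample_onto(ct, total, grid_of(mr), "linear"),
       rounds_run = r, displacements = disp)
}

#' Write a landmark set as JSON
#' @param lm a `landmark_set`.
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  recs <- lapply(seq_len(nrow(lm)), function(i)
    list(vertebra = lm$vertebra[i], structure = lm$structure[i],
         mm = c(lm$x[i], lm$y[i], lm$z[i])))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark set from JSON
#' @param path JSON path written by [write_landmarks()].
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  landmark_set(vapply(recs, `[[`, numeric(1), "vertebra"),
               vapply(recs, `[[`, character(1), "structure"),
               t(vapply(recs, function(r) as.numeric(unlist(r$mm)), numeric(3))))
}
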