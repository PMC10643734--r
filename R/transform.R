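# Rigid transforms in world coordinates (mm): x' = R x + t with R a proper
# rotation. Serialised to JSON as a row-major 3x3 rotation plus translation.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 translation in mm.
#' @param tol orthogonality / determinant tolerance.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > sqrt(tol))
    stop("`rotation` is not orthogonal within tolerance")
  if (abs(det(rotation) - 1) > sqrt(tol))
    stop("invalid rotation: det(R) must be +1 (got ", format(det(rotation)), ")")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation about a named anatomical axis
#'
#' Builds a rigid transform rotating by `angle_deg` about `axis` through the
#' world point `center` (mm), plus an optional extra translation. Axis names
#' follow the package convention: `"ap"` (axis 1), `"craniocaudal"` (axis 2),
#' `"lr"` (axis 3).
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis `"craniocaudal"`, `"ap"` or `"lr"`, or a unit 3-vector.
#' @param center world point the rotation axis passes through (mm).
#' @param translation extra translation applied after rotation (mm).
#' @return a `rigid_transform`.
#' @export
rotation_about <- function(angle_deg, axis = "craniocaudal",
                           center = c(0, 0, 0), translation = c(0, 0, 0)) {
  u <- if (is.character(axis)) {
    switch(match.arg(axis, c("craniocaudal", "ap", "lr")),
           ap = c(1, 0, 0), craniocaudal = c(0, 1, 0), lr = c(0, 0, 1))
  } else {
    axis / sqrt(sum(axis^2))
  }
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  center <- as.numeric(center)
  rigid_transform(R, center - R %*% center + translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.3f deg, translation (%s) mm\n",
              rotation_angle(x) * 180 / pi,
              paste(format(x$translation, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to world points
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -Rt %*% tf$translation)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`.
#' @param first,second `rigid_transform`s.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  second$rotation %*% first$translation + second$translation)
}

# rotation angle in radians (geodesic distance from identity)
rotation_angle <- function(tf) {
  R <- if (inherits(tf, "rigid_transform")) tf$rotation else tf
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Write a rigid transform as JSON
#' @param tf a `rigid_transform`.
#' @param path output path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(tf$rotation)), translation = tf$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON path written by [write_transform()].
#' @return a `rigid_transform`.
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
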