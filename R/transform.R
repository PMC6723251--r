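#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthogonal matrix with
#' determinant +1) plus a translation vector, applied as `R x + t`.
#' All superposition machinery in the package passes these around;
#' [apply_transform()] applies one to a complete structure.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 translation (Angstrom).
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform(diag(3), c(1, 2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform components must be finite")
  ortho <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho >= 1e-8)
    stop(sprintf("rotation is not orthogonal (|R'R - I| = %.3g)", ortho))
  if (abs(det(rotation) - 1) >= 1e-8)
    stop(sprintf("rotation is improper (det = %.6f); reflections are rejected", det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (angle", sprintf("%.2f", rotation_angle(x$rotation)),
      "deg, |t| =", sprintf("%.3f", sqrt(sum(x$translation^2))), "A)\n")
  invisible(x)
}

#' Apply a rigid transform to a set of points
#'
#' @param points n x 3 numeric matrix of coordinates.
#' @param transform a [rigid_transform()].
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  stopifnot(is_rigid_transform(transform))
  points <- rbind(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

#' Rotation angle of a rotation matrix, in degrees
#'
#' @param rotation 3x3 rotation matrix.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_angle <- function(rotation) {
  ctheta <- (sum(diag(rotation)) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues construction; mainly used by the fixture generators and tests.
#'
#' @param axis numeric length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
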