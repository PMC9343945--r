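#' Rigid transforms
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' `x' = R x + t`.  Coordinates are millimetres throughout the package
#' (mm-ms-kg unit system).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `hbm_transform`.
#' @examples
#' tr <- rigid_transform(rotation_z(90))
#' apply_transform(tr, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "hbm_transform")
}

#' @export
print.hbm_transform <- function(x, ...) {
  cat("Rigid transform (mm)\n")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("r1", "r2", "r3", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the global axes, angle in degrees.
#'
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rotation_z
#' @export
rotation_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotation_z
#' @export
rotation_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Rotation about an axis through a point
#'
#' Builds the rigid transform that rotates about an axis direction passing
#' through `centre` (a fixed point of the transform).
#'
#' @param axis length-3 direction vector (normalized internally).
#' @param angle_deg angle in degrees, right-handed about `axis`.
#' @param centre point on the rotation axis (mm).
#' @return `hbm_transform`.
#' @export
rotation_about_point <- function(axis, angle_deg, centre = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigid_transform(R, as.numeric(centre - R %*% centre))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first `hbm_transform` objects.
#' @return `hbm_transform`.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Apply a rigid transform to points
#'
#' @param transform `hbm_transform`.
#' @param points n x 3 matrix (or length-3 vector) of coordinates in mm.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Minimal rotation aligning one direction with another
#'
#' The rotation about `u x v` taking unit vector along `u` onto the unit
#' vector along `v`; identity when they already coincide.  Used to bend
#' vertebrae onto a new spine tangent without introducing axial twist.
#'
#' @param u,v length-3 direction vectors.
#' @return 3x3 rotation matrix.
#' @export
minimal_rotation <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  a <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(a^2)); d <- sum(u * v)
  if (s < 1e-15) {
    if (d > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    a <- a / sqrt(sum(a^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- a / s
  angle <- atan2(s, d)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
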