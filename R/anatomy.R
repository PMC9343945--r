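#' Least-squares sphere fit
#'
#' Fits a sphere to 3-D points by linear least squares on the algebraic
#' form `|x|^2 = 2 c.x + (r^2 - |c|^2)`.  This is how the hip reference
#' point (H-point) is constructed: the centre of a sphere approximated to
#' the femoral head surface.
#'
#' @param points n x 3 matrix of surface points (mm), n >= 4, not all
#'   coplanar.
#' @return List with `centre` (mm), `radius` (mm) and `rms` residual of
#'   radial distances (mm).
#' @export
fit_sphere <- function(points) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3)
  if (nrow(p) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate point configuration (coplanar or coincident points); ",
         "cannot fit a sphere")
  sol <- qr.coef(qrA, b)
  centre <- sol[1:3]
  r2 <- sol[4] + sum(centre^2)
  if (r2 <= 0) stop("degenerate point configuration; cannot fit a sphere")
  radius <- sqrt(r2)
  d <- sqrt(rowSums((p - matrix(centre, nrow(p), 3, byrow = TRUE))^2))
  list(centre = unname(centre), radius = unname(radius),
       rms = sqrt(mean((d - radius)^2)))
}

#' Set the model coordinate origin from the H-point
#'
#' Axes follow the ISO convention (x forward, y left, z up).  For seated
#' models the origin is placed at the H-point; for standing models at the
#' foot sole directly under the H-point, so the H-point ends up at
#' `(0, 0, h)` with `h` its height above the sole.  The operation is a pure
#' translation and is idempotent.
#'
#' @param assembly `hbm_assembly`.
#' @param posture `"seated"` or `"standing"`.
#' @param hpoint H-point coordinates (mm), typically from [fit_sphere()] on
#'   femoral-head surface nodes.
#' @param sole_z z-coordinate of the foot sole plane (mm); required for
#'   standing models.
#' @return Translated `hbm_assembly`.
#' @export
set_model_origin <- function(assembly, posture = c("seated", "standing"),
                             hpoint, sole_z = NULL) {
  posture <- match.arg(posture)
  hpoint <- as.numeric(hpoint)
  stopifnot(length(hpoint) == 3)
  shift <- if (posture == "seated") {
    -hpoint
  } else {
    if (is.null(sole_z)) stop("standing posture requires sole_z")
    c(-hpoint[1], -hpoint[2], -sole_z)
  }
  m <- node_matrix(assembly)
  set_node_matrix(assembly, m + matrix(shift, nrow(m), 3, byrow = TRUE))
}

#' Rigid rotation of a model about the global z then y axes
#'
#' Implements the pre-impact rigid transformation of the body model:
#' rotation about global z by `z_rot`, then about global y by `y_rot`, both
#' through the origin.  Angles in degrees.
#'
#' @param assembly `hbm_assembly`.
#' @param z_rot,y_rot angles in degrees.
#' @return Rotated `hbm_assembly`; pairwise distances are preserved.
#' @export
rigid_transform_model <- function(assembly, z_rot = 0, y_rot = 0) {
  R <- rotation_y(y_rot) %*% rotation_z(z_rot)
  set_node_matrix(assembly, node_matrix(assembly) %*% t(R))
}

#' Volumetric scaling of a bone node set
#'
#' Per-axis scaling about an anchor point, used when bone dimensions are
#' assumed proportional to the outer body surface.
#'
#' @param nodes n x 3 matrix of node coordinates (mm).
#' @param scale length-3 positive scale factors (sx, sy, sz); a scalar is
#'   recycled.
#' @param anchor point the scaling is performed about (mm); defaults to the
#'   centroid of `nodes`.
#' @return Scaled n x 3 matrix.
#' @export
scale_bone_volumetric <- function(nodes, scale, anchor = NULL) {
  p <- as.matrix(nodes)
  s <- rep_len(as.numeric(scale), 3)
  if (any(s <= 0)) stop("scale factors must be positive")
  if (is.null(anchor)) anchor <- colMeans(p)
  ctr <- matrix(as.numeric(anchor), nrow(p), 3, byrow = TRUE)
  (p - ctr) %*% diag(s) + ctr
}

#' Stature-ratio scale factor
#'
#' The ratio of target to source stature expressed as a percentage, used
#' e.g. to scale the scapula of the male variant (statures 1750 mm male /
#' 1620 mm female give 108% to the nearest integer).
#'
#' @param stature_target,stature_source statures in mm, > 0.
#' @return List with `percent` (exact `100 * target / source`) and
#'   `percent_int` (nearest integer).
#' @export
stature_ratio_scale <- function(stature_target, stature_source) {
  stopifnot(stature_target > 0, stature_source > 0)
  p <- 100 * stature_target / stature_source
  list(percent = p, percent_int = as.integer(round(p)))
}

#' Clavicle scale factor from joint distances
#'
#' Scale factor that brings the current sternoclavicular-to-
#' acromioclavicular joint distance to the target distance; applied as a
#' uniform [scale_bone_volumetric()] about the sternoclavicular joint.
#'
#' @param current,target joint distances in mm, > 0.
#' @return Scalar factor `target / current`.
#' @export
clavicle_scale <- function(current, target) {
  stopifnot(current > 0, target > 0)
  target / current
}

#' Reorient occupant skeletal landmark groups into a standing posture
#'
#' The standing (vulnerable-road-user) variants keep the occupant skeleton
#' but reorient it rigidly, bone group by bone group; the target landmarks
#' of the skeletal parts are therefore rigid transforms of the occupant
#' landmarks.  The pelvis transform must include the posture rotation about
#' the y-axis through the hip joint centre (42 degrees for the female
#' lineup member, 39 for the male); the ribcage and thoracic spine move
#' under one common transform, so their relative geometry is unchanged.
#'
#' @param groups named list of landmark coordinate matrices (n x 3), one
#'   per skeletal group.
#' @param transforms named list of `hbm_transform`, one per group (same
#'   names); missing a group's transform is an error.
#' @return Named list of transformed coordinate matrices; intra-group
#'   pairwise distances are preserved.
#' @export
reorient_skeleton_vru <- function(groups, transforms) {
  missing <- setdiff(names(groups), names(transforms))
  if (length(missing))
    stop("no rigid transform supplied for skeletal group(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(names(groups), function(g)
    apply_transform(transforms[[g]], groups[[g]]))
  names(out) <- names(groups)
  out
}

#' Pelvis posture rotation
#'
#' Convenience constructor for the pelvis reorientation used when deriving
#' standing variants: a rotation about the global y-axis through the hip
#' joint centre.
#'
#' @param angle_deg rotation angle in degrees (positive pitches the pelvis
#'   per the right-hand rule about +y).
#' @param hip_centre hip joint centre (mm).
#' @return `hbm_transform`.
#' @export
pelvis_rotation <- function(angle_deg, hip_centre) {
  rotation_about_point(c(0, 1, 0), angle_deg, hip_centre)
}
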