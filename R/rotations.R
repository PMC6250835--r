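## Rotation helpers shared by the model (forward kinematics) and the
## marker-based kinematics pipeline. All matrices are 3x3 proper rotations
## acting on column vectors; angles are radians unless noted.

#' Elementary rotation matrices
#'
#' @param theta rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues' formula)
#'
#' @param axis unit 3-vector.
#' @param theta rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > 1e-9) stop("rotation axis must be a unit vector")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Check that a matrix is a proper rotation
#' @keywords internal
is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Cardan Y-X'-Z'' decomposition of a relative rotation
#'
#' Decomposes a proper rotation as \code{R = Ry(ty) Rx(tx) Rz(tz)} with
#' moving (intrinsic) axes, the convention used for limb joints where the
#' first (Y) angle is flexion/extension, the second (X) ad/abduction and the
#' third (Z) internal/external rotation. Near gimbal lock
#' (\code{|cos(tx)| < 1e-6}) the third angle is indeterminate; it is set to
#' zero and the result is flagged with a warning.
#'
#' @param R a 3x3 proper rotation matrix (parent -> child).
#' @param tol orthogonality tolerance for the input check.
#' @return Numeric vector \code{c(ty, tx, tz)} in degrees, with attribute
#'   \code{"gimbal"} TRUE if gimbal proximity was detected.
#' @examples
#' cardan_yxz(diag(3))                     # c(0, 0, 0)
#' cardan_yxz(rot_y(30 * pi / 180))        # c(30, 0, 0)
#' @export
cardan_yxz <- function(R, tol = 1e-6) {
  if (!is_rotation(R, tol)) stop("input is not a proper rotation matrix")
  ## R = Ry(ty) Rx(tx) Rz(tz):
  ##   R[2,3] = -sin(tx)
  ##   R[1,3] =  sin(ty) cos(tx);  R[3,3] = cos(ty) cos(tx)
  ##   R[2,1] =  cos(tx) sin(tz);  R[2,2] = cos(tx) cos(tz)
  sx <- -R[2, 3]
  sx <- max(-1, min(1, sx))
  tx <- asin(sx)
  gimbal <- abs(cos(tx)) < 1e-6
  if (gimbal) {
    warning("gimbal proximity in Cardan Y-X'-Z'' decomposition; third angle set to 0")
    ## with cos(tx) ~ 0 only ty +/- tz is determined; attribute all to ty
    ty <- atan2(R[3, 1] * sign(sx), R[1, 1])
    tz <- 0
  } else {
    ty <- atan2(R[1, 3], R[3, 3])
    tz <- atan2(R[2, 1], R[2, 2])
  }
  out <- c(ty, tx, tz) * 180 / pi
  names(out) <- c("y", "x", "z")
  attr(out, "gimbal") <- gimbal
  out
}

#' Compose a rotation from Cardan Y-X'-Z'' angles
#'
#' Inverse of [cardan_yxz()].
#'
#' @param angles_deg numeric vector \code{c(ty, tx, tz)} in degrees.
#' @return A 3x3 rotation matrix.
#' @export
cardan_yxz_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rot_y(a[1]) %*% rot_x(a[2]) %*% rot_z(a[3])
}

#' Unwrap an angle series (degrees)
#'
#' Removes artificial +/-360 degree jumps so that no inter-frame step
#' exceeds 180 degrees.
#' @param x numeric vector of angles in degrees.
#' @keywords internal
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  corr <- cumsum(round(d / 360)) * -360
  x + c(0, corr)
}
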