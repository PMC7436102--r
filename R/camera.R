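#' Pinhole camera intrinsics
#'
#' Focal lengths and principal point are expressed in pixels. Pixel centers
#' sit at integer coordinates, the origin is the top-left pixel (1,1), `u`
#' runs along columns (right) and `v` along rows (down), matching how images
#' are stored as `array(height, width, 3)` matrices.
#'
#' @param fx,fy focal lengths in pixels (must be positive).
#' @param cx,cy principal point in pixels (must lie inside the image).
#' @param width,height image size in pixels.
#' @return An object of class `mv_intrinsics`.
#' @export
mv_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  if (cx < 1 || cx > width || cy < 1 || cy > height) {
    stop("principal point (", cx, ", ", cy, ") lies outside the image")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "mv_intrinsics")
}

#' Rigid camera pose (world to camera)
#'
#' Maps world points (mm, z-up, table plane at z = 0) into the camera frame
#' (x right, y down, z along the optical axis): `x_cam = R x_world + t`.
#'
#' @param R 3x3 orthonormal rotation, `det(R) = 1` within 1e-9.
#' @param t translation 3-vector in mm.
#' @return An object of class `mv_pose`.
#' @export
mv_pose <- function(R, t) {
  if (!is_rotation(R)) stop("R is not a rotation matrix (det 1, orthonormal)")
  t <- as.numeric(t)
  stopifnot(length(t) == 3, all(is.finite(t)))
  structure(list(R = R, t = t), class = "mv_pose")
}

#' @export
print.mv_pose <- function(x, ...) {
  cat("mv_pose: camera center (mm) =",
      paste(sprintf("%.2f", camera_center(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Camera center in world coordinates
#' @param pose an [mv_pose()].
#' @return 3-vector, mm.
#' @export
camera_center <- function(pose) {
  as.numeric(-t(pose$R) %*% pose$t)
}

#' Compose / invert poses
#'
#' `pose_relative(pose1, pose2)` returns the pose mapping camera-1 coordinates
#' to camera-2 coordinates; `pose_compose(rel, pose1)` rebuilds `pose2`.
#' @param pose1,pose2 world-to-camera poses.
#' @return an `mv_pose`.
#' @export
pose_relative <- function(pose1, pose2) {
  Rr <- pose2$R %*% t(pose1$R)
  tr <- pose2$t - Rr %*% pose1$t
  mv_pose(orthonormalize_rotation(Rr), tr)
}

#' @rdname pose_relative
#' @param rel relative pose (camera-1 to camera-2).
#' @export
pose_compose <- function(rel, pose1) {
  mv_pose(orthonormalize_rotation(rel$R %*% pose1$R),
          as.numeric(rel$R %*% pose1$t) + rel$t)
}

#' Project world points to pixel coordinates
#'
#' @param X N x 3 matrix of world points (mm).
#' @param pose world-to-camera [mv_pose()].
#' @param K [mv_intrinsics()].
#' @return N x 2 matrix of (u, v) pixels; rows with non-positive depth are NA.
#' @export
project_points <- function(X, pose, K) {
  X <- rbind(X)
  Xc <- X %*% t(pose$R) + matrix(pose$t, nrow(X), 3, byrow = TRUE)
  z <- Xc[, 3]
  uv <- cbind(K$fx * Xc[, 1] / z + K$cx, K$fy * Xc[, 2] / z + K$cy)
  uv[z <= 0, ] <- NA_real_
  uv
}

# Unit-free ray directions in the world frame for pixel coords (u, v); the
# returned directions have unit z-depth in the camera frame, so the ray
# parameter equals the camera-frame depth.
pixel_rays_world <- function(u, v, pose, K) {
  d_cam <- cbind((u - K$cx) / K$fx, (v - K$cy) / K$fy, 1)
  d_cam %*% pose$R  # = t(R) applied row-wise
}

#' Construct a camera pose looking at a target point
#'
#' The camera sits at distance `distance_mm` from `target`, at the given
#' elevation above the table plane (90 = straight down) and azimuth
#' (direction from which it looks, degrees CCW from +x). Roll is fixed so the
#' image x-axis stays horizontal in the world.
#'
#' @param elevation_deg angle between the optical axis and the table plane.
#' @param azimuth_deg horizontal direction of the camera from the target.
#' @param distance_mm camera-to-target distance, mm.
#' @param target 3-vector look-at point (default origin).
#' @return an [mv_pose()].
#' @export
look_at_pose <- function(elevation_deg, azimuth_deg = 90, distance_mm = 400,
                         target = c(0, 0, 0)) {
  e <- deg2rad(elevation_deg); a <- deg2rad(azimuth_deg)
  C <- target + distance_mm * c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
  z_cam <- unitize(target - C)
  x_cam <- cross3(z_cam, c(0, 0, 1))
  if (vnorm(x_cam) < 1e-8) x_cam <- c(-sin(a), cos(a), 0) else x_cam <- unitize(x_cam)
  y_cam <- cross3(z_cam, x_cam)
  R <- rbind(x_cam, y_cam, z_cam)
  dimnames(R) <- NULL
  mv_pose(orthonormalize_rotation(R), as.numeric(-R %*% C))
}
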