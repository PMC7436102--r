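#' Gravity sample from the IMU
#'
#' Direction of gravity ("down") expressed in the camera coordinate frame
#' (x right, y down, z forward). The vector is unit-normalized on
#' construction.
#'
#' @param g_cam numeric 3-vector, any non-zero magnitude.
#' @return An object of class `mv_gravity` holding the unit vector.
#' @export
mv_gravity <- function(g_cam) {
  g_cam <- as.numeric(g_cam)
  stopifnot(length(g_cam) == 3, all(is.finite(g_cam)))
  if (vnorm(g_cam) < 1e-12) stop("gravity vector must be non-zero")
  structure(list(g_cam = unitize(g_cam)), class = "mv_gravity")
}

as_gravity <- function(g) if (inherits(g, "mv_gravity")) g else mv_gravity(g)

# Gravity implied by a camera pose: world down (0,0,-1) seen in the camera.
gravity_from_pose <- function(pose) {
  mv_gravity(as.numeric(pose$R %*% c(0, 0, -1)))
}

#' Table normal from gravity
#'
#' Assuming the table is horizontal, its upward unit normal in the camera
#' frame is simply the negated gravity direction.
#'
#' @param g an [mv_gravity()] (or raw 3-vector).
#' @return unit 3-vector, the table's up-normal in camera coordinates.
#' @export
table_normal_from_gravity <- function(g) {
  -as_gravity(g)$g_cam
}

#' Camera elevation angle from gravity
#'
#' Angle between the optical axis and the table plane, in degrees. 90 means
#' the camera looks straight down at the table (nadir); 0 means it looks
#' parallel to it.
#'
#' @param g an [mv_gravity()] (or raw 3-vector).
#' @return elevation in `[0, 90]` degrees.
#' @export
camera_elevation_deg <- function(g) {
  g <- as_gravity(g)$g_cam
  # angle between optical axis (0,0,1) and the down direction
  theta <- rad2deg(acos(max(-1, min(1, g[3]))))
  max(0, 90 - theta)
}

#' Select the 90/75-degree frame pair from a video stream
#'
#' Given a sequence of frames with per-frame gravity samples, picks the frame
#' closest to 90 degrees elevation and the frame closest to 75 degrees —
#' the capture geometry used for two-view reconstruction.
#'
#' @param gravities list of [mv_gravity()] (or raw 3-vectors), one per frame.
#' @param targets the two target elevations, degrees.
#' @param tolerance_deg maximum allowed residual from a target before the
#'   stream is declared insufficient (default 10).
#' @return list with `index_90`, `index_75` (1-based, distinct),
#'   `residual_deg` (length 2) and `elevations_deg`.
#' @export
select_frame_pair <- function(gravities, targets = c(90, 75),
                              tolerance_deg = 10) {
  if (length(gravities) < 2) stop("need at least 2 frames")
  elev <- vapply(gravities, camera_elevation_deg, numeric(1))
  i90 <- which.min(abs(elev - targets[1]))
  # force distinct indices: pick the best remaining frame for the second target
  cand <- setdiff(seq_along(elev), i90)
  i75 <- cand[which.min(abs(elev[cand] - targets[2]))]
  res <- c(abs(elev[i90] - targets[1]), abs(elev[i75] - targets[2]))
  if (any(res > tolerance_deg)) {
    stop("insufficient coverage: best frames are ",
         sprintf("%.1f and %.1f", res[1], res[2]),
         " degrees from the 90/75 targets (tolerance ", tolerance_deg, ")")
  }
  list(index_90 = i90, index_75 = i75, residual_deg = res,
       elevations_deg = elev)
}
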