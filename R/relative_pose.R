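#' Gravity-aided relative pose of the second view
#'
#' The IMU gravity vector fixes the camera tilt analytically: any rotation
#' `R2` consistent with gravity satisfies `R2 (0,0,-1) = g2` and can be
#' written `A2 Rz(phi)` with `A2` the minimal rotation taking world-down onto
#' `g2`. Only the residual yaw about the gravity axis (1 DoF) and the
#' translation (3 DoF, metric scale inherited from the card) remain, and are
#' estimated from correspondences lying on or near the table plane. This is
#' what makes the gravity-aided pose cheaper and more stable than a full
#' 6-DoF estimation.
#'
#' @param pose1 [mv_pose()] of the first view in the world (card) frame.
#' @param g1,g2 [mv_gravity()] samples of the two views.
#' @param correspondences either a list with `uv1`, `uv2` (N x 2 pixel
#'   matrices; `uv1` is lifted to the table plane through `pose1`), or with
#'   `world` (N x 3 known world points, e.g. card corners) and `uv2`.
#' @param K an [mv_intrinsics()].
#' @param n_yaw_grid coarse grid size for the 1-D yaw search.
#' @return [mv_pose()] of view 2 (world to camera), with attributes
#'   `yaw_deg` (residual yaw) and `rms_px` (reprojection RMS).
#' @export
relative_pose_gravity_aided <- function(pose1, g1, g2, correspondences, K,
                                        n_yaw_grid = 72) {
  g1 <- as_gravity(g1); g2 <- as_gravity(g2)
  if (sum(g1$g_cam * g2$g_cam) < -1 + 1e-9) {
    stop("gravity vectors are anti-parallel: impossible tilt between views")
  }
  co <- correspondences
  if (!is.null(co$world)) {
    X <- rbind(co$world)
  } else {
    if (is.null(co$uv1)) stop("correspondences need either world or uv1")
    X <- lift_to_plane(co$uv1, pose1, K)
  }
  px <- rbind(co$uv2)
  if (nrow(X) < 4) stop("need at least 4 correspondences, got ", nrow(X))

  A2 <- gravity_frame(g2$g_cam)
  fx <- K$fx; fy <- K$fy; cx <- K$cx; cy <- K$cy
  u <- px[, 1]; v <- px[, 2]

  solve_t <- function(R2) {
    # linear least squares for t from the projection equations
    r1X <- X %*% R2[1, ]; r2X <- X %*% R2[2, ]; r3X <- X %*% R2[3, ]
    A <- rbind(cbind(fx, 0, -(u - cx)), cbind(0, fy, -(v - cy)))
    b <- c((u - cx) * r3X - fx * r1X, (v - cy) * r3X - fy * r2X)
    qr.solve(A, b)
  }
  reproj_sse <- function(phi) {
    R2 <- A2 %*% rot_z(phi)
    t2 <- solve_t(R2)
    uv <- project_points(X, mv_pose(orthonormalize_rotation(R2), t2), K)
    if (anyNA(uv)) return(1e12)
    sum((uv - px)^2)
  }
  grid <- seq(-pi, pi, length.out = n_yaw_grid + 1)[-1]
  sse <- vapply(grid, reproj_sse, numeric(1))
  phi0 <- grid[which.min(sse)]
  step <- 2 * pi / n_yaw_grid
  opt <- stats::optimize(reproj_sse, c(phi0 - step, phi0 + step),
                         tol = 1e-12)
  phi <- opt$minimum
  R2 <- orthonormalize_rotation(A2 %*% rot_z(phi))
  pose2 <- mv_pose(R2, solve_t(A2 %*% rot_z(phi)))
  pose2 <- refine_pose_yaw_t(X, px, K, A2, phi, pose2$t)
  uv <- project_points(X, pose2, K)
  attr(pose2, "yaw_deg") <- rad2deg(phi)
  attr(pose2, "rms_px") <- sqrt(mean(rowSums((uv - px)^2)))
  pose2
}

# Any rotation A with A (0,0,-1) = g: the minimal one, or a 180-degree flip
# about x when g is exactly world-up in the camera frame (nadir view). The
# choice is arbitrary — the yaw degree of freedom absorbs it.
gravity_frame <- function(g) {
  if (sum(g * c(0, 0, -1)) < -1 + 1e-9) {
    return(diag(c(1, -1, -1)))
  }
  rotation_between(c(0, 0, -1), g)
}

# Polish (phi, t) jointly on the true reprojection error, keeping the tilt
# fixed by gravity.
refine_pose_yaw_t <- function(X, px, K, A2, phi0, t0) {
  obj <- function(par) {
    p <- mv_pose(orthonormalize_rotation(A2 %*% rot_z(par[1])), par[2:4])
    uv <- project_points(X, p, K)
    if (anyNA(uv)) return(1e12)
    sum((uv - px)^2)
  }
  fit <- stats::optim(c(phi0, t0), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  mv_pose(orthonormalize_rotation(A2 %*% rot_z(fit$par[1])), fit$par[2:4])
}

#' Lift pixels of a posed view onto the table plane z = 0
#'
#' @param uv N x 2 pixels.
#' @param pose the view's [mv_pose()].
#' @param K an [mv_intrinsics()].
#' @return N x 3 world points.
#' @export
lift_to_plane <- function(uv, pose, K) {
  uv <- rbind(uv)
  C <- camera_center(pose)
  D <- pixel_rays_world(uv[, 1], uv[, 2], pose, K)
  s <- -C[3] / D[, 3]
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("some rays do not intersect the table plane in front of the camera")
  }
  matrix(C, nrow(uv), 3, byrow = TRUE) + D * s
}

#' Refine the second view's pose against table-plane image content
#'
#' The card-based pose is accurate to a fraction of a pixel, but the
#' plane-sweep matcher converts any residual warp misalignment directly
#' into height bias. This refinement measures unconstrained 2D matches (a
#' local NCC search around the plane-induced prediction) for textured
#' background pixels — which lie on the table plane — and re-solves the
#' gravity-constrained yaw + translation so the plane homography fits the
#' actual image content.
#'
#' @param image1,image2 the two views.
#' @param pose1,pose2 current poses (pose2 is refined).
#' @param K an [mv_intrinsics()].
#' @param g2 view-2 [mv_gravity()].
#' @param bg_mask logical H x W matrix marking table-plane (non-food)
#'   pixels in view 1; the card region counts as plane.
#' @param n_points number of control points sampled from the mask.
#' @param search_px radius of the local 2D search, px.
#' @param window NCC window for the local search (odd).
#' @return refined [mv_pose()] of view 2.
#' @export
refine_relative_pose_dense <- function(image1, image2, pose1, pose2, K, g2,
                                       bg_mask, n_points = 350,
                                       search_px = 2.5, window = 9) {
  g1m <- luminance(image1); g2m <- luminance(image2)
  H <- nrow(g1m); W <- ncol(g1m)
  r <- (window - 1) %/% 2
  idx <- which(bg_mask)
  # keep points away from the border and prefer textured neighbourhoods
  uu <- (idx - 1) %/% H + 1
  vv <- (idx - 1) %% H + 1
  ok <- uu > r + 3 & uu < W - r - 3 & vv > r + 3 & vv < H - r - 3
  idx <- idx[ok]; uu <- uu[ok]; vv <- vv[ok]
  if (length(idx) > n_points) {
    keep <- round(seq(1, length(idx), length.out = n_points))
    idx <- idx[keep]; uu <- uu[keep]; vv <- vv[keep]
  }
  if (length(idx) < 8) return(pose2)
  X <- lift_to_plane(cbind(uu, vv), pose1, K)
  pred <- project_points(X, pose2, K)
  good <- !is.na(pred[, 1]) & pred[, 1] > r + 3 & pred[, 1] < W - r - 3 &
    pred[, 2] > r + 3 & pred[, 2] < H - r - 3
  uu <- uu[good]; vv <- vv[good]; X <- X[good, , drop = FALSE]
  pred <- pred[good, , drop = FALSE]
  n <- nrow(pred)
  if (n < 8) return(pose2)
  # reference patches in view 1 (n x window^2)
  og <- as.matrix(expand.grid(du = -r:r, dv = -r:r))
  patch1 <- matrix(0, n, nrow(og))
  for (j in seq_len(nrow(og))) {
    patch1[, j] <- g1m[cbind(vv + og[j, 2], uu + og[j, 1])]
  }
  p1c <- patch1 - rowMeans(patch1)
  p1n <- sqrt(rowSums(p1c^2))
  offs <- seq(-search_px, search_px, by = 0.5)
  no <- length(offs)
  scores <- array(-Inf, c(n, no, no))
  for (iu in seq_len(no)) for (iv in seq_len(no)) {
    patch2 <- matrix(0, n, nrow(og))
    for (j in seq_len(nrow(og))) {
      patch2[, j] <- bilinear_sample(g2m, pred[, 1] + offs[iu] + og[j, 1],
                                     pred[, 2] + offs[iv] + og[j, 2])
    }
    p2c <- patch2 - rowMeans(patch2)
    scores[, iu, iv] <- rowSums(p1c * p2c) /
      pmax(p1n * sqrt(rowSums(p2c^2)), 1e-12)
  }
  flat <- matrix(scores, n, no * no)
  bk <- max.col(flat, ties.method = "first")
  bu <- (bk - 1) %% no + 1
  bv <- (bk - 1) %/% no + 1
  best_s <- flat[cbind(seq_len(n), bk)]
  step <- offs[2] - offs[1]
  # separable parabolic sub-pixel refinement of the score peak
  sub <- function(bi, axis) {
    d <- numeric(n)
    inn <- if (axis == 1) bu > 1 & bu < no else bv > 1 & bv < no
    ii <- which(inn)
    if (!length(ii)) return(d)
    pick <- function(sh) {
      if (axis == 1) scores[cbind(ii, bu[ii] + sh, bv[ii])]
      else scores[cbind(ii, bu[ii], bv[ii] + sh)]
    }
    sm <- pick(-1L); sp <- pick(1L)
    den <- sm - 2 * best_s[ii] + sp
    d[ii] <- ifelse(is.finite(sm) & is.finite(sp) & den < -1e-12,
                    pmax(-1, pmin(1, 0.5 * (sm - sp) / den)), 0)
    d
  }
  du_star <- offs[bu] + sub(bu, 1) * step
  dv_star <- offs[bv] + sub(bv, 2) * step
  keep <- best_s > 0.6 & abs(offs[bu]) < search_px & abs(offs[bv]) < search_px
  if (sum(keep) < 8) return(pose2)
  uv2 <- pred[keep, , drop = FALSE] + cbind(du_star, dv_star)[keep, , drop = FALSE]
  relative_pose_gravity_aided(pose1, gravity_from_pose(pose1), g2,
                              list(world = X[keep, , drop = FALSE],
                                   uv2 = uv2), K)
}
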