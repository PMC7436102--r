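# Dense two-view matching by plane-sweep NCC and linear triangulation.

# Sliding-window box sum via 2D cumulative sums; NA-free input expected.
box_sum <- function(M, r) {
  H <- nrow(M); W <- ncol(M)
  cs <- apply(rbind(0, M), 2, cumsum)
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  i1 <- pmax(1, seq_len(H) - r); i2 <- pmin(H, seq_len(H) + r)
  j1 <- pmax(1, seq_len(W) - r); j2 <- pmin(W, seq_len(W) + r)
  cs[i2 + 1, j2 + 1, drop = FALSE] - cs[i1, j2 + 1, drop = FALSE] -
    cs[i2 + 1, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
}

# One sweep direction: for each pixel of `ref`, find the table-height
# hypothesis maximizing windowed NCC against `other` warped through the
# plane z = h, then refine sub-pixel by parabolic interpolation over h.
sweep_heights <- function(gray_ref, gray_oth, pose_ref, pose_oth, K,
                          heights, window, min_ncc) {
  H <- nrow(gray_ref); W <- ncol(gray_ref)
  r <- (window - 1) %/% 2
  n_px <- H * W
  u <- rep(seq_len(W), each = H)
  v <- rep(seq_len(H), W)
  C <- camera_center(pose_ref)
  D <- pixel_rays_world(u, v, pose_ref, K)
  area <- box_sum(matrix(1, H, W), r)
  s_ref <- box_sum(gray_ref, r)
  s_ref2 <- box_sum(gray_ref^2, r)
  var_ref <- s_ref2 - s_ref^2 / area
  nh <- length(heights)
  scores <- matrix(-Inf, n_px, nh)
  for (k in seq_len(nh)) {
    h <- heights[k]
    s <- (h - C[3]) / D[, 3]
    P <- matrix(C, n_px, 3, byrow = TRUE) + D * s
    uv2 <- project_points(P, pose_oth, K)
    ok <- s > 0 & !is.na(uv2[, 1]) &
      uv2[, 1] >= 1 & uv2[, 1] <= W & uv2[, 2] >= 1 & uv2[, 2] <= H
    wimg <- rep(0, n_px)
    wimg[ok] <- bilinear_sample(gray_oth, uv2[ok, 1], uv2[ok, 2])
    Wm <- matrix(wimg, H, W)
    Vm <- matrix(as.numeric(ok), H, W)
    n_ok <- box_sum(Vm, r)
    s_w <- box_sum(Wm, r)
    s_w2 <- box_sum(Wm^2, r)
    s_rw <- box_sum(gray_ref * Wm, r)
    full <- n_ok == area
    cov <- s_rw - s_ref * s_w / area
    var_w <- s_w2 - s_w^2 / area
    ncc <- cov / sqrt(pmax(var_ref * var_w, 1e-12))
    ncc[!full | var_w < 1e-6 | var_ref < 1e-6] <- -Inf
    scores[, k] <- as.numeric(ncc)
  }
  best_k <- max.col(scores, ties.method = "first")
  best_s <- scores[cbind(seq_len(n_px), best_k)]
  # sub-pixel height by parabola through the three scores around the peak
  hstep <- if (nh > 1) heights[2] - heights[1] else 0
  h_hat <- heights[best_k]
  inn <- best_k > 1 & best_k < nh & is.finite(best_s)
  if (any(inn) && hstep > 0) {
    sm <- scores[cbind(which(inn), best_k[inn] - 1L)]
    sp <- scores[cbind(which(inn), best_k[inn] + 1L)]
    den <- sm - 2 * best_s[inn] + sp
    dlt <- ifelse(is.finite(sm) & is.finite(sp) & den < -1e-12,
                  0.5 * (sm - sp) / den, 0)
    h_hat[inn] <- h_hat[inn] + pmax(-1, pmin(1, dlt)) * hstep
  }
  valid <- is.finite(best_s) & best_s >= min_ncc
  s <- (h_hat - C[3]) / D[, 3]
  P <- matrix(C, n_px, 3, byrow = TRUE) + D * s
  uv2 <- project_points(P, pose_oth, K)
  valid <- valid & !is.na(uv2[, 1])
  list(u = u, v = v, uv2 = uv2, height = h_hat, score = best_s,
       valid = valid)
}

# Apply the slope-aware pass to one sweep direction and rebuild the match
# fields from the refined heights.
refine_pass <- function(sw, gray_ref, gray_oth, pose_ref, pose_oth, K,
                        window, min_ncc) {
  h_in <- ifelse(sw$valid, sw$height, NA_real_)
  rf <- refine_sweep(gray_ref, gray_oth, pose_ref, pose_oth, K, h_in, window)
  C <- camera_center(pose_ref)
  D <- pixel_rays_world(sw$u, sw$v, pose_ref, K)
  s <- (rf$height - C[3]) / D[, 3]
  P <- matrix(C, length(sw$u), 3, byrow = TRUE) + D * s
  uv2 <- project_points(P, pose_oth, K)
  valid <- sw$valid & is.finite(rf$score) & rf$score >= min_ncc &
    !is.na(uv2[, 1])
  list(u = sw$u, v = sw$v, uv2 = uv2, height = rf$height,
       score = rf$score, valid = valid)
}

# Slope-aware refinement pass: re-sweeps a small height offset around the
# first-pass surface, warping every pixel with its own (smoothed) height so
# the NCC window follows the local surface slope instead of assuming a
# fronto-parallel plane. Returns refined heights.
refine_sweep <- function(gray_ref, gray_oth, pose_ref, pose_oth, K, h0,
                         window, deltas = seq(-3, 3, by = 0.5)) {
  H <- nrow(gray_ref); W <- ncol(gray_ref)
  r <- (window - 1) %/% 2
  n_px <- H * W
  hm <- matrix(h0, H, W)
  # fill unmatched pixels from neighbours, then smooth lightly
  for (it in 1:8) {
    if (!anyNA(hm)) break
    v <- !is.na(hm)
    hz <- hm; hz[!v] <- 0
    acc <- box_sum(hz, 1); cnt <- box_sum(matrix(as.numeric(v), H, W), 1)
    fill <- !v & cnt > 0
    hm[fill] <- acc[fill] / cnt[fill]
  }
  hm[is.na(hm)] <- 0
  hs <- box_sum(hm, 2) / box_sum(matrix(1, H, W), 2)
  u <- rep(seq_len(W), each = H)
  v <- rep(seq_len(H), W)
  C <- camera_center(pose_ref)
  D <- pixel_rays_world(u, v, pose_ref, K)
  area <- box_sum(matrix(1, H, W), r)
  s_ref <- box_sum(gray_ref, r)
  var_ref <- box_sum(gray_ref^2, r) - s_ref^2 / area
  nd <- length(deltas)
  scores <- matrix(-Inf, n_px, nd)
  for (k in seq_len(nd)) {
    h <- as.numeric(hs) + deltas[k]
    s <- (h - C[3]) / D[, 3]
    P <- matrix(C, n_px, 3, byrow = TRUE) + D * s
    uv2 <- project_points(P, pose_oth, K)
    ok <- s > 0 & !is.na(uv2[, 1]) &
      uv2[, 1] >= 1 & uv2[, 1] <= W & uv2[, 2] >= 1 & uv2[, 2] <= H
    wimg <- rep(0, n_px)
    wimg[ok] <- bilinear_sample(gray_oth, uv2[ok, 1], uv2[ok, 2])
    Wm <- matrix(wimg, H, W)
    n_ok <- box_sum(matrix(as.numeric(ok), H, W), r)
    s_w <- box_sum(Wm, r)
    var_w <- box_sum(Wm^2, r) - s_w^2 / area
    cov <- box_sum(gray_ref * Wm, r) - s_ref * s_w / area
    ncc <- cov / sqrt(pmax(var_ref * var_w, 1e-12))
    ncc[n_ok != area | var_w < 1e-6 | var_ref < 1e-6] <- -Inf
    scores[, k] <- as.numeric(ncc)
  }
  best_k <- max.col(scores, ties.method = "first")
  best_s <- scores[cbind(seq_len(n_px), best_k)]
  dstep <- deltas[2] - deltas[1]
  d_hat <- deltas[best_k]
  inn <- best_k > 1 & best_k < nd & is.finite(best_s)
  if (any(inn)) {
    sm <- scores[cbind(which(inn), best_k[inn] - 1L)]
    sp <- scores[cbind(which(inn), best_k[inn] + 1L)]
    den <- sm - 2 * best_s[inn] + sp
    off <- ifelse(is.finite(sm) & is.finite(sp) & den < -1e-12,
                  0.5 * (sm - sp) / den, 0)
    d_hat[inn] <- d_hat[inn] + pmax(-1, pmin(1, off)) * dstep
  }
  list(height = as.numeric(hs) + d_hat, score = best_s)
}

#' Dense stereo matching between a metrically posed image pair
#'
#' Plane-sweep block matching: table-height hypotheses `z = h` induce
#' homography warps of view 2 into view 1; per-pixel normalized cross
#' correlation over an odd window selects the best hypothesis, refined to
#' sub-pixel by parabolic interpolation, with a symmetric left-right
#' consistency check. Textureless images yield an empty correspondence set
#' with a warning, not an error.
#'
#' @param image1,image2 `array(H, W, 3)` images in `[0, 1]`.
#' @param pose1,pose2 world-to-camera [mv_pose()] of the two views.
#' @param K shared [mv_intrinsics()].
#' @param window odd NCC window size in px (default 11).
#' @param lr_tol_px left-right consistency tolerance (default 1).
#' @param height_range_mm sweep range of table heights (mm).
#' @param height_step_mm sweep resolution (mm).
#' @param min_ncc minimum accepted correlation score.
#' @param refine_iters slope-aware refinement passes (default 2): heights
#'   are re-estimated with per-pixel warps that follow the current surface
#'   estimate, progressively removing the fronto-parallel bias on sloped
#'   food surfaces; 0 disables.
#' @param refine_window NCC window of the refinement passes (defaults to
#'   `window`; smaller windows reduce boundary mixing once the surface
#'   estimate is close).
#' @return list of matrices `uv1` (pixels in view 1), `uv2` (sub-pixel
#'   matches in view 2), vector `score`, plus `height_mm` hypotheses kept.
#' @export
dense_match <- function(image1, image2, pose1, pose2, K, window = 11,
                        lr_tol_px = 1.0, height_range_mm = c(-4, 84),
                        height_step_mm = 1.0, min_ncc = 0.5,
                        refine_iters = 2L, refine_window = window) {
  if (window %% 2 != 1) stop("window must be odd")
  g1 <- luminance(image1); g2 <- luminance(image2)
  if (stats::sd(g1) < 1e-4 || stats::sd(g2) < 1e-4) {
    warning("textureless image: no reliable matches")
    return(list(uv1 = matrix(0, 0, 2), uv2 = matrix(0, 0, 2),
                score = numeric(0)))
  }
  heights <- seq(height_range_mm[1], height_range_mm[2], by = height_step_mm)
  fwd <- sweep_heights(g1, g2, pose1, pose2, K, heights, window, min_ncc)
  bwd <- sweep_heights(g2, g1, pose2, pose1, K, heights, window, min_ncc)
  for (it in seq_len(refine_iters)) {
    fwd <- refine_pass(fwd, g1, g2, pose1, pose2, K, refine_window, min_ncc)
    bwd <- refine_pass(bwd, g2, g1, pose2, pose1, K, refine_window, min_ncc)
  }
  H <- nrow(g1)
  sel <- which(fwd$valid)
  if (!length(sel)) {
    warning("no matches passed the score threshold")
    return(list(uv1 = matrix(0, 0, 2), uv2 = matrix(0, 0, 2),
                score = numeric(0)))
  }
  # left-right check: the backward match at the (rounded) matched pixel must
  # land within lr_tol_px of the original pixel
  u2r <- pmin(pmax(round(fwd$uv2[sel, 1]), 1), ncol(g1))
  v2r <- pmin(pmax(round(fwd$uv2[sel, 2]), 1), H)
  bidx <- (u2r - 1) * H + v2r
  ok_b <- bwd$valid[bidx]
  du <- bwd$uv2[bidx, 1] - fwd$u[sel]
  dv <- bwd$uv2[bidx, 2] - fwd$v[sel]
  keep <- ok_b & sqrt(du^2 + dv^2) <= lr_tol_px
  sel <- sel[keep]
  list(uv1 = cbind(u = fwd$u[sel], v = fwd$v[sel]),
       uv2 = fwd$uv2[sel, , drop = FALSE],
       score = fwd$score[sel])
}

#' Linear two-view triangulation
#'
#' Per-point linear least squares on the projection equations (the DLT
#' system), fully vectorized; stores per-point reprojection residuals and
#' flags points behind either camera, which are excluded.
#'
#' @param correspondences list with `uv1`, `uv2` (N x 2 pixels).
#' @param pose1,pose2 [mv_pose()] of the two views.
#' @param K an [mv_intrinsics()].
#' @return object of class `mv_point_cloud`: `points` (N x 3 mm), `source_px`
#'   (pixels in view 1), `residual_px`, `n_excluded`.
#' @export
triangulate <- function(correspondences, pose1, pose2, K) {
  uv1 <- rbind(correspondences$uv1); uv2 <- rbind(correspondences$uv2)
  stopifnot(nrow(uv1) == nrow(uv2))
  baseline <- vnorm(camera_center(pose1) - camera_center(pose2))
  if (baseline < 1e-6) stop("baseline is degenerate (< 1e-6 mm): no parallax")
  n <- nrow(uv1)
  if (n == 0) {
    return(structure(list(points = matrix(0, 0, 3),
                          source_px = matrix(0, 0, 2),
                          residual_px = numeric(0), n_excluded = 0L),
                     class = "mv_point_cloud"))
  }
  rows <- function(pose, uv) {
    R <- pose$R; t <- pose$t
    a1 <- cbind(K$fx * R[1, 1] - (uv[, 1] - K$cx) * R[3, 1],
                K$fx * R[1, 2] - (uv[, 1] - K$cx) * R[3, 2],
                K$fx * R[1, 3] - (uv[, 1] - K$cx) * R[3, 3])
    b1 <- (uv[, 1] - K$cx) * t[3] - K$fx * t[1]
    a2 <- cbind(K$fy * R[2, 1] - (uv[, 2] - K$cy) * R[3, 1],
                K$fy * R[2, 2] - (uv[, 2] - K$cy) * R[3, 2],
                K$fy * R[2, 3] - (uv[, 2] - K$cy) * R[3, 3])
    b2 <- (uv[, 2] - K$cy) * t[3] - K$fy * t[2]
    list(a = list(a1, a2), b = list(b1, b2))
  }
  r1 <- rows(pose1, uv1); r2 <- rows(pose2, uv2)
  As <- c(r1$a, r2$a); bs <- c(r1$b, r2$b)
  # normal equations accumulated vectorized; solved per point via Cramer
  M11 <- M12 <- M13 <- M22 <- M23 <- M33 <- rep(0, n)
  v1 <- v2 <- v3 <- rep(0, n)
  for (k in 1:4) {
    a <- As[[k]]; b <- bs[[k]]
    M11 <- M11 + a[, 1]^2;  M12 <- M12 + a[, 1] * a[, 2]
    M13 <- M13 + a[, 1] * a[, 3]; M22 <- M22 + a[, 2]^2
    M23 <- M23 + a[, 2] * a[, 3]; M33 <- M33 + a[, 3]^2
    v1 <- v1 + a[, 1] * b; v2 <- v2 + a[, 2] * b; v3 <- v3 + a[, 3] * b
  }
  det3 <- M11 * (M22 * M33 - M23^2) - M12 * (M12 * M33 - M23 * M13) +
    M13 * (M12 * M23 - M22 * M13)
  cx1 <- (M22 * M33 - M23^2); cx2 <- (M13 * M23 - M12 * M33)
  cx3 <- (M12 * M23 - M13 * M22)
  cy2 <- (M11 * M33 - M13^2); cy3 <- (M12 * M13 - M11 * M23)
  cz3 <- (M11 * M22 - M12^2)
  X <- cbind((v1 * cx1 + v2 * cx2 + v3 * cx3) / det3,
             (v1 * cx2 + v2 * cy2 + v3 * cy3) / det3,
             (v1 * cx3 + v2 * cy3 + v3 * cz3) / det3)
  # depths in both cameras; exclude points behind either
  z1 <- X %*% pose1$R[3, ] + pose1$t[3]
  z2 <- X %*% pose2$R[3, ] + pose2$t[3]
  ok <- is.finite(rowSums(X)) & z1 > 0 & z2 > 0
  p1 <- project_points(X, pose1, K)
  p2 <- project_points(X, pose2, K)
  res <- sqrt((rowSums((p1 - uv1)^2) + rowSums((p2 - uv2)^2)) / 2)
  structure(list(points = X[ok, , drop = FALSE],
                 source_px = uv1[ok, , drop = FALSE],
                 residual_px = res[ok],
                 n_excluded = as.integer(sum(!ok))),
            class = "mv_point_cloud")
}
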