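# Reference-card detection and planar (card-plane) pose estimation. The card
# anchors the metric world frame: its center is the origin, its long edge the
# world x-axis, the table plane z = 0.

luminance <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

# Binary closing (dilate then erode) with a square structuring element of
# radius r, computed with box sums.
binary_close <- function(mask, r) {
  if (r < 1) return(mask)
  M <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  dil <- box_sum(M, r) > 0
  area <- box_sum(matrix(1, nrow(mask), ncol(mask)), r)
  box_sum(matrix(as.numeric(dil), nrow(mask), ncol(mask)), r) >= area
}

# 4-connected components of a logical matrix by iterative label propagation.
# Returns an integer matrix (0 outside, 1..n components).
connected_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    new[-1, ] <- pmax(new[-1, ], lab[-H, ] * mask[-1, ])
    new[-H, ] <- pmax(new[-H, ], lab[-1, ] * mask[-H, ])
    new[, -1] <- pmax(new[, -1], lab[, -W] * mask[, -1])
    new[, -W] <- pmax(new[, -W], lab[, -1] * mask[, -W])
    if (identical(new, lab)) break
    lab <- new
  }
  lab[mask] <- as.integer(factor(lab[mask]))
  lab
}

# Direct linear transform homography from N >= 4 2D points to 2D points,
# with Hartley normalization. Returns 3x3 H (maps src homogeneous to dst).
homography_dlt <- function(src, dst) {
  stopifnot(nrow(src) >= 4, nrow(src) == nrow(dst))
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3,
                byrow = TRUE)
    list(T = T, p = cbind(p[, 1] * s - s * ctr[1], p[, 2] * s - s * ctr[2]))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  h <- svd(A, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

apply_homography <- function(H, pts) {
  ph <- cbind(pts, 1) %*% t(H)
  cbind(ph[, 1] / ph[, 3], ph[, 2] / ph[, 3])
}

bilinear_sample <- function(M, u, v) {
  H <- nrow(M); W <- ncol(M)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  u0 <- pmin(pmax(u0, 1), W - 1); v0 <- pmin(pmax(v0, 1), H - 1)
  i00 <- (u0 - 1) * H + v0
  M[i00] * (1 - fu) * (1 - fv) + M[i00 + H] * fu * (1 - fv) +
    M[i00 + 1] * (1 - fu) * fv + M[i00 + H + 1] * fu * fv
}

quad_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(2, 3, 4, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

quad_area <- function(p) abs(quad_area_signed(p))

#' Detect the reference card in an image
#'
#' The card is the brightest large region in the frame (guaranteed by the
#' synthetic renderer; a real detector would sit behind the same contract).
#' Its boundary is extracted, reduced to a convex quadrilateral, and each
#' edge is refined by total-least-squares line fitting for sub-pixel corner
#' accuracy. The dark magnetic stripe orients the corner ordering, so the
#' first returned corner is always the card-frame top-left.
#'
#' @param image `array(H, W, 3)` in `[0, 1]`.
#' @param card a [card_spec()].
#' @param brightness_threshold luminance cut separating card from scene.
#' @param min_area_px minimum component area to be considered a card.
#' @return object of class `mv_card_detection`: `found`, `corners_px`
#'   (4 x 2, order TL, TR, BR, BL in the card frame), `confidence` in
#'   `[0, 1]`. When no plausible quadrilateral exists, `found` is `FALSE`
#'   and `reason` says why — absence is distinguishable from low confidence.
#' @export
detect_card <- function(image, card = card_spec(),
                        brightness_threshold = 0.8, min_area_px = 60,
                        closing_px = 4) {
  L <- luminance(image)
  # morphological closing bridges the dark stripe so the card stays one
  # component
  comp <- connected_components(binary_close(L > brightness_threshold,
                                            closing_px))
  if (max(comp) == 0) {
    return(structure(list(found = FALSE, reason = "card not found"),
                     class = "mv_card_detection"))
  }
  sizes <- tabulate(comp[comp > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_area_px) {
    return(structure(list(found = FALSE, reason = "card not found"),
                     class = "mv_card_detection"))
  }
  sel <- comp == best
  idx <- which(sel)
  H <- nrow(L)
  pu <- (idx - 1) %/% H + 1
  pv <- (idx - 1) %% H + 1
  hull <- grDevices::chull(pu, pv)
  hu <- pu[hull]; hv <- pv[hull]
  # corner 1-2: the hull diameter; corners 3-4: max triangle area per side
  dmat <- as.matrix(stats::dist(cbind(hu, hv)))
  dia <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  a <- dia[1]; b <- dia[2]
  cross_side <- (hu - hu[a]) * (hv[b] - hv[a]) - (hv - hv[a]) * (hu[b] - hu[a])
  pick_far <- function(side_sel) {
    if (!any(side_sel)) return(NA_integer_)
    ar <- abs(cross_side)
    ar[!side_sel] <- -1
    which.max(ar)
  }
  c1 <- pick_far(cross_side > 0)
  c2 <- pick_far(cross_side < 0)
  if (is.na(c1) || is.na(c2)) {
    return(structure(list(found = FALSE,
                          reason = "no convex quadrilateral found"),
                     class = "mv_card_detection"))
  }
  corners <- cbind(hu[c(a, c1, b, c2)], hv[c(a, c1, b, c2)])
  # order corners around the centroid for a consistent cycle
  ctr <- colMeans(corners)
  ord <- order(atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1]))
  corners <- corners[ord, ]
  if (quad_area(corners) < 4 * min_area_px / 5) {
    return(structure(list(found = FALSE,
                          reason = "no convex quadrilateral found"),
                     class = "mv_card_detection"))
  }

  # refine: boundary pixels assigned to nearest quad edge, TLS line fits
  interior <- sel
  interior[-1, ] <- interior[-1, ] & sel[-H, ]
  interior[-H, ] <- interior[-H, ] & sel[-1, ]
  interior[, -1] <- interior[, -1] & sel[, -ncol(L)]
  interior[, -ncol(L)] <- interior[, -ncol(L)] & sel[, -1]
  bidx <- which(sel & !interior)
  bu <- (bidx - 1) %/% H + 1
  bv <- (bidx - 1) %% H + 1
  fit_rms <- 0
  refined <- corners
  edges <- cbind(1:4, c(2, 3, 4, 1))
  # distance of every boundary pixel to each edge segment
  seg_dist <- sapply(1:4, function(e) {
    p1 <- corners[edges[e, 1], ]; p2 <- corners[edges[e, 2], ]
    dv <- p2 - p1
    tt <- pmin(1, pmax(0, ((bu - p1[1]) * dv[1] + (bv - p1[2]) * dv[2]) /
                            sum(dv^2)))
    sqrt((bu - (p1[1] + tt * dv[1]))^2 + (bv - (p1[2] + tt * dv[2]))^2)
  })
  nearest <- max.col(-seg_dist)
  lines <- vector("list", 4)
  for (e in 1:4) {
    pts <- cbind(bu, bv)[nearest == e & seg_dist[cbind(seq_along(bu), nearest)] < 2.5, , drop = FALSE]
    # drop pixels close to the two endpoint corners: they belong to both edges
    for (ci in edges[e, ]) {
      keep <- sqrt(rowSums(sweep(pts, 2, corners[ci, ])^2)) > 2.5
      pts <- pts[keep, , drop = FALSE]
    }
    if (nrow(pts) < 2) { lines[e] <- list(NULL); next }
    ctr_e <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr_e))
    nrm <- sv$v[, 2]  # line normal
    cc <- -sum(nrm * ctr_e)       # n . p + c = 0
    # boundary pixel centers lie ~0.5 px inside the physical edge: push the
    # fitted line half a pixel outward (away from the component centroid)
    s0 <- sum(nrm * ctr) + cc
    cc <- cc + 0.5 * sign(s0)
    lines[[e]] <- c(nrm, cc)
    fit_rms <- fit_rms + mean((cbind(pts, 1) %*% c(nrm, -sum(nrm * ctr_e)))^2)
  }
  if (!any(vapply(lines, is.null, logical(1)))) {
    for (ci in 1:4) {
      e_prev <- (ci - 2) %% 4 + 1  # edge from corner ci-1 to ci
      e_next <- ci                 # edge from ci to ci+1
      A <- rbind(lines[[e_prev]][1:2], lines[[e_next]][1:2])
      bb <- -c(lines[[e_prev]][3], lines[[e_next]][3])
      if (abs(det(A)) > 1e-8) refined[ci, ] <- solve(A, bb)
    }
    fit_rms <- sqrt(fit_rms / 4)
  }

  # photometric sub-pixel refinement: locate the luminance crossing along
  # each edge normal (anti-aliased edges carry sub-pixel information)
  photo <- refine_edges_photometric(L, refined)
  if (!is.null(photo)) {
    refined <- photo$corners
    fit_rms <- photo$rms
  }

  # plausible aspect ratio: opposite edges similar, long/short within bounds
  el <- sqrt(rowSums((refined[edges[, 2], ] - refined[edges[, 1], ])^2))
  ratio <- max(mean(el[c(1, 3)]), mean(el[c(2, 4)])) /
    max(min(mean(el[c(1, 3)]), mean(el[c(2, 4)])), 1e-9)
  if (ratio > 4 || max(el) / max(min(el), 1e-9) > 6) {
    return(structure(list(found = FALSE,
                          reason = "no quadrilateral of plausible aspect ratio"),
                     class = "mv_card_detection"))
  }

  # orient with the magnetic stripe: try all cyclic shifts and reversals,
  # the correct assignment puts dark pixels in the stripe band and bright
  # ones in the mirrored band near the opposite long edge
  loc <- card_corners_local(card)[, 1:2]
  wg <- expand.grid(x = seq(-0.8, 0.8, length.out = 9) * card$width_mm / 2,
                    frac = 1:2)
  top <- card$height_mm / 2
  ys <- c(mean(top - card$stripe_from_top_mm),       # stripe band
          -mean(top - card$stripe_from_top_mm))      # mirrored band
  # a camera above the plane always sees the TL,TR,BR,BL cycle with the same
  # image-plane winding (positive shoelace area in (u, v) coordinates with v
  # down); the mirrored cycle would imply a camera below the table, so only
  # orientation-preserving candidates are considered
  cands <- list()
  for (rev in c(FALSE, TRUE)) {
    cyc <- if (rev) refined[4:1, ] else refined
    if (quad_area_signed(cyc) <= 0) next
    for (sh in 0:3) cands[[length(cands) + 1]] <- cyc[(0:3 + sh) %% 4 + 1, ]
  }
  Lm <- L
  score <- vapply(cands, function(q) {
    Hc <- tryCatch(homography_dlt(loc, q), error = function(e) NULL)
    if (is.null(Hc)) return(Inf)
    s1 <- apply_homography(Hc, cbind(wg$x[wg$frac == 1], ys[1]))
    s2 <- apply_homography(Hc, cbind(wg$x[wg$frac == 2], ys[2]))
    mean(bilinear_sample(Lm, s1[, 1], s1[, 2])) -
      mean(bilinear_sample(Lm, s2[, 1], s2[, 2]))
  }, numeric(1))
  bestq <- cands[[which.min(score)]]
  # refine the chosen ordering's corners identically (they are permutations)
  structure(list(found = TRUE,
                 corners_px = bestq,
                 confidence = max(0, min(1, 1 - fit_rms)),
                 stripe_contrast = -min(score)),
            class = "mv_card_detection")
}

# Sub-pixel edge localization: for sample points along each quad edge, the
# luminance profile across the edge is sampled bilinearly and the crossing
# of the inside/outside mid-level located by linear interpolation; each edge
# line is then refit by total least squares through the crossing points.
# Returns NULL when too few reliable crossings exist (keeps the pixel-level
# fit).
refine_edges_photometric <- function(L, corners, n_samples = 25) {
  ctr <- colMeans(corners)
  offs <- seq(-1.5, 1.5, by = 0.3)
  lines <- vector("list", 4)
  rms_acc <- c()
  for (e in 1:4) {
    p1 <- corners[e, ]; p2 <- corners[e %% 4 + 1, ]
    ts <- seq(0.15, 0.85, length.out = n_samples)
    base <- cbind(p1[1] + ts * (p2[1] - p1[1]), p1[2] + ts * (p2[2] - p1[2]))
    nrm <- c(p2[2] - p1[2], p1[1] - p2[1])
    nrm <- nrm / max(vnorm(nrm), 1e-12)
    if (sum((ctr - p1) * nrm) > 0) nrm <- -nrm  # outward
    pts <- NULL
    for (i in seq_len(nrow(base))) {
      su <- base[i, 1] + offs * nrm[1]
      sv <- base[i, 2] + offs * nrm[2]
      if (any(su < 2 | su > ncol(L) - 1 | sv < 2 | sv > nrow(L) - 1)) next
      prof <- bilinear_sample(L, su, sv)
      ni <- length(prof)
      inside <- mean(prof[1:3]); outside <- mean(prof[(ni - 2):ni])
      if (abs(inside - outside) < 0.15) next
      mid <- (inside + outside) / 2
      below <- (prof - mid) * sign(inside - mid)
      cross <- which(below[-ni] > 0 & below[-1] <= 0)
      if (!length(cross)) next
      j <- cross[1]
      frac <- below[j] / (below[j] - below[j + 1])
      off_star <- offs[j] + frac * (offs[j + 1] - offs[j])
      pts <- rbind(pts, base[i, ] + off_star * nrm)
    }
    if (is.null(pts) || nrow(pts) < 8) return(NULL)
    ctr_e <- colMeans(pts)
    sv2 <- svd(sweep(pts, 2, ctr_e))
    nl <- sv2$v[, 2]
    lines[[e]] <- c(nl, -sum(nl * ctr_e))
    rms_acc <- c(rms_acc, sqrt(mean((cbind(pts, 1) %*% lines[[e]])^2)))
  }
  out <- corners
  for (ci in 1:4) {
    e_prev <- (ci - 2) %% 4 + 1
    e_next <- ci
    A <- rbind(lines[[e_prev]][1:2], lines[[e_next]][1:2])
    bb <- -c(lines[[e_prev]][3], lines[[e_next]][3])
    if (abs(det(A)) < 1e-8) return(NULL)
    out[ci, ] <- solve(A, bb)
  }
  list(corners = out, rms = mean(rms_acc))
}

#' Metric camera pose from coplanar world points (planar PnP)
#'
#' Standard planar pose: homography from the plane's 2D coordinates to
#' pixels, decomposed as `K [r1 r2 t]` with the scale fixed by the rotation
#' columns and the sign by cheirality (points in front of the camera). The
#' rotation is projected to the nearest orthonormal matrix and the full pose
#' polished by minimizing reprojection error.
#'
#' @param world_xy N x 2 coordinates on the plane z = 0 (mm).
#' @param px N x 2 observed pixels.
#' @param K an [mv_intrinsics()].
#' @param refine run the nonlinear polish (default TRUE).
#' @return an [mv_pose()] (world to camera, camera above the plane).
#' @export
pose_from_plane_points <- function(world_xy, px, K, refine = TRUE) {
  H <- homography_dlt(world_xy, px)
  Km <- matrix(c(K$fx, 0, K$cx, 0, K$fy, K$cy, 0, 0, 1), 3, 3, byrow = TRUE)
  M <- solve(Km) %*% H
  lam <- 2 / (vnorm(M[, 1]) + vnorm(M[, 2]))
  if (lam * M[3, 3] < 0) lam <- -lam  # plane origin must be in front
  r1 <- lam * M[, 1]; r2 <- lam * M[, 2]
  R <- orthonormalize_rotation(cbind(r1, r2, cross3(r1, r2)))
  t <- lam * M[, 3]
  pose <- mv_pose(R, t)
  if (camera_center(pose)[3] <= 0) {
    stop("planar pose: recovered camera is below the plane")
  }
  if (refine) pose <- refine_pose(cbind(world_xy, 0), px, K, pose)
  pose
}

# Gauss-Newton-style polish of a pose against observed pixels (numeric
# gradients via optim; the problem is tiny).
refine_pose <- function(X, px, K, pose0) {
  obj <- function(par) {
    w <- par[1:3]
    th <- vnorm(w)
    Rd <- if (th < 1e-12) diag(3) else {
      k <- w / th
      kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                   byrow = TRUE)
      diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx
    }
    p <- mv_pose(orthonormalize_rotation(Rd %*% pose0$R), pose0$t + par[4:6])
    uv <- project_points(X, p, K)
    if (anyNA(uv)) return(1e12)
    sum((uv - px)^2)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  par <- fit$par
  w <- par[1:3]; th <- vnorm(w)
  Rd <- if (th < 1e-12) diag(3) else {
    k <- w / th
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx
  }
  mv_pose(orthonormalize_rotation(Rd %*% pose0$R), pose0$t + par[4:6])
}

#' Camera pose from a card detection
#'
#' @param det an [detect_card()] result with `found = TRUE`.
#' @param card the [card_spec()] giving the physical corner coordinates.
#' @param K an [mv_intrinsics()].
#' @param min_area_px reject detections whose quadrilateral is nearly
#'   degenerate (area below this threshold).
#' @return an [mv_pose()] in the card/world frame (card center = origin).
#' @export
pose_from_card <- function(det, card = card_spec(), K, min_area_px = 50) {
  if (!isTRUE(det$found)) {
    stop("cannot estimate pose: ", det$reason %||% "card not found")
  }
  if (quad_area(det$corners_px) < min_area_px) {
    stop("card quadrilateral is near-degenerate (area < ", min_area_px,
         " px^2)")
  }
  pose_from_plane_points(card_corners_local(card)[, 1:2], det$corners_px, K)
}
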