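#' Reference card specification
#'
#' Physical size of the reference object placed on the table, default the
#' ISO/IEC 7810 ID-1 credit-card format. The rendered card carries a dark
#' magnetic stripe parallel to its long edge; the stripe breaks the 180-degree
#' symmetry of a plain rectangle so the detector can orient the corners.
#'
#' @param width_mm,height_mm card dimensions in mm.
#' @return object of class `mv_card_spec`.
#' @export
card_spec <- function(width_mm = 85.60, height_mm = 53.98) {
  stopifnot(width_mm > 0, height_mm > 0)
  # the stripe sits 8-19 mm below the top edge: far enough from the edge
  # that sub-pixel edge profiling at desk-scale resolution stays clean
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 stripe_from_top_mm = c(8, 19)),
            class = "mv_card_spec")
}

# Card corner positions in the card (= world) frame, canonical order
# TL, TR, BR, BL: x along the long edge, y along the short edge, z = 0.
card_corners_local <- function(spec) {
  w <- spec$width_mm / 2; h <- spec$height_mm / 2
  matrix(c(-w, h, 0,  w, h, 0,  w, -h, 0,  -w, -h, 0), 4, 3, byrow = TRUE)
}

card_corners_world <- function(spec, center = c(0, 0), yaw_deg = 0) {
  Rz <- rot_z(deg2rad(yaw_deg))
  sweep(card_corners_local(spec) %*% t(Rz), 2, c(center, 0), "+")
}

#' Scene specification for the synthetic generator
#'
#' Describes a two-view tabletop meal scene: parametric food solids on a
#' textured plane, a reference card, and camera views. The default capture
#' geometry is the 90/75-degree elevation pair at 400 mm used by the
#' two-view acquisition protocol.
#'
#' @param solids list of [food_solid()] (at least one).
#' @param views list of view definitions from [view_at()] or
#'   [stereo_rig_views()]; at least two.
#' @param card a [card_spec()], or `NULL` for no card.
#' @param card_center,card_yaw_deg card placement on the table. The card
#'   center is the world origin when it sits at `c(0, 0)`.
#' @param K an [mv_intrinsics()].
#' @param noise_sigma additive Gaussian pixel noise (image units in `[0,1]`).
#' @param target look-at point for the cameras.
#' @param supersample anti-aliasing factor: each image pixel averages
#'   `supersample^2` rays, emulating the sensor's pixel integration
#'   (default 2; set 1 for fast hard-edged renders). Ground-truth masks and
#'   correspondences always use the central ray.
#' @return object of class `mv_scene_spec`.
#' @export
scene_spec <- function(solids,
                       views = list(view_at(90), view_at(75)),
                       card = card_spec(),
                       card_center = c(0, 0), card_yaw_deg = 0,
                       K = default_intrinsics(),
                       noise_sigma = 0.0,
                       target = c(0, 60, 0),
                       supersample = 2L) {
  stopifnot(length(solids) >= 1, length(views) >= 2, supersample >= 1)
  for (s in solids) stopifnot(inherits(s, "mv_food_solid"))
  structure(list(solids = solids, views = views, card = card,
                 card_center = as.numeric(card_center),
                 card_yaw_deg = card_yaw_deg, K = K,
                 noise_sigma = noise_sigma, target = as.numeric(target),
                 supersample = as.integer(supersample)),
            class = "mv_scene_spec")
}

#' @rdname scene_spec
#' @param elevation_deg,azimuth_deg,distance_mm camera placement relative to
#'   the scene target (see [look_at_pose()]).
#' @export
view_at <- function(elevation_deg, azimuth_deg = 90, distance_mm = 400) {
  list(type = "angle", elevation_deg = elevation_deg,
       azimuth_deg = azimuth_deg, distance_mm = distance_mm)
}

#' @rdname scene_spec
#' @param baseline_mm distance between the two rig cameras (e.g., 14 for a
#'   dual-camera phone, 200 to emulate the two-view baseline).
#' @export
stereo_rig_views <- function(baseline_mm, distance_mm = 400,
                             elevation_deg = 90) {
  list(list(type = "rig", baseline_mm = baseline_mm, side = -1,
            distance_mm = distance_mm, elevation_deg = elevation_deg),
       list(type = "rig", baseline_mm = baseline_mm, side = +1,
            distance_mm = distance_mm, elevation_deg = elevation_deg))
}

#' @rdname scene_spec
#' @export
default_intrinsics <- function() {
  mv_intrinsics(fx = 190, fy = 190, cx = 100.5, cy = 75.5,
                width = 200, height = 150)
}

view_pose <- function(vdef, target) {
  if (vdef$type == "angle") {
    return(look_at_pose(vdef$elevation_deg, vdef$azimuth_deg,
                        vdef$distance_mm, target))
  }
  # rig: nadir-style pose translated sideways; both cameras share orientation
  base <- look_at_pose(vdef$elevation_deg, 90, vdef$distance_mm, target)
  C <- camera_center(base) + t(base$R) %*% c(vdef$side * vdef$baseline_mm / 2, 0, 0)
  mv_pose(base$R, as.numeric(-base$R %*% C))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- rendering core -------------------------------------------------------

# Albedo lookup for hit points. id: 0 none (sky), 1 table, 2 card,
# 2 + k solid k. tex_seed keys the whole scene's texture set.
scene_albedo <- function(scene_or_spec, P, id, tex_seed) {
  n <- length(id)
  rgb <- matrix(0.15, n, 3)  # sky fallback
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  tab <- id == 1
  if (any(tab)) {
    rgb[tab, ] <- textured_albedo(x[tab], y[tab], c(0.46, 0.40, 0.33),
                                  tex_seed + 11, amp = 0.24, cell = 17)
  }
  cd <- id == 2
  if (any(cd)) {
    spec <- scene_or_spec$card
    loc <- to_card_frame(scene_or_spec, x[cd], y[cd])
    top <- spec$height_mm / 2
    stripe <- loc[, 2] <= top - spec$stripe_from_top_mm[1] &
      loc[, 2] >= top - spec$stripe_from_top_mm[2]
    base <- textured_albedo(x[cd], y[cd], c(0.93, 0.93, 0.91),
                            tex_seed + 23, amp = 0.07, cell = 4)
    dark <- textured_albedo(x[cd], y[cd], c(0.10, 0.10, 0.11),
                            tex_seed + 29, amp = 0.06, cell = 4)
    base[stripe, ] <- dark[stripe, ]
    rgb[cd, ] <- base
  }
  for (k in seq_along(scene_or_spec$solids)) {
    sel <- id == 2 + k
    if (!any(sel)) next
    sol <- scene_or_spec$solids[[k]]
    # add a height-dependent shift so vertical walls are textured too
    rgb[sel, ] <- textured_albedo(x[sel] + 0.71 * z[sel],
                                  y[sel] + 0.37 * z[sel], sol$color,
                                  tex_seed + 101 * sol$texture_seed,
                                  amp = 0.20, cell = 7)
  }
  rgb
}

to_card_frame <- function(spec_like, x, y) {
  yaw <- deg2rad(spec_like$card_yaw_deg %||% 0)
  dx <- x - spec_like$card_center[1]
  dy <- y - spec_like$card_center[2]
  cbind(cos(yaw) * dx + sin(yaw) * dy, -sin(yaw) * dx + cos(yaw) * dy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First-hit raycast through pixel coords (u, v) (vectors). Returns hit ids
# (0 sky, 1 table, 2 card, 2+k solid k), ray parameters and world points.
raycast <- function(spec_like, pose, K, u, v) {
  C <- camera_center(pose)
  if (C[3] <= 0) stop("degenerate pose: camera is not above the table plane")
  D <- pixel_rays_world(u, v, pose, K)
  n <- length(u)
  s_best <- rep(Inf, n)
  id <- integer(n)
  # table plane z = 0
  dz <- D[, 3]
  s_pl <- ifelse(dz < -1e-12, -C[3] / dz, Inf)
  hit <- s_pl < s_best
  s_best[hit] <- s_pl[hit]; id[hit] <- 1L
  for (k in seq_along(spec_like$solids)) {
    s_k <- solid_ray_intersect(spec_like$solids[[k]], C, D)
    hit <- s_k < s_best
    s_best[hit] <- s_k[hit]; id[hit] <- 2L + k
  }
  P <- matrix(C, n, 3, byrow = TRUE) + D * s_best
  P[!is.finite(s_best), ] <- NA_real_
  # card: a sub-region of the table plane
  if (!is.null(spec_like$card)) {
    tab <- id == 1L
    if (any(tab)) {
      loc <- to_card_frame(spec_like, P[tab, 1], P[tab, 2])
      on_card <- abs(loc[, 1]) <= spec_like$card$width_mm / 2 &
        abs(loc[, 2]) <= spec_like$card$height_mm / 2
      id[tab][on_card] <- 2L
    }
  }
  list(id = id, s = s_best, P = P, C = C)
}

render_one_view <- function(spec_like, pose, K, noise_sigma, noise_seed,
                            tex_seed) {
  W <- K$width; H <- K$height
  u <- rep(seq_len(W), each = H)
  v <- rep(seq_len(H), W)
  rc <- raycast(spec_like, pose, K, u, v)
  ss <- spec_like$supersample %||% 1L
  vote_id <- rc$id
  if (ss <= 1L) {
    alb <- scene_albedo(spec_like, rc$P, rc$id, tex_seed)
  } else {
    # average albedo over a supersampled ray grid (pixel integration), and
    # define the ground-truth label as the pixel's majority content so masks
    # agree with what the anti-aliased image actually shows
    offs <- (seq_len(ss) - (ss + 1) / 2) / ss
    alb <- matrix(0, length(u), 3)
    max_id <- 2L + length(spec_like$solids)
    counts <- matrix(0L, length(u), max_id + 1L)
    for (du in offs) for (dv in offs) {
      rs <- raycast(spec_like, pose, K, u + du, v + dv)
      alb <- alb + scene_albedo(spec_like, rs$P, rs$id, tex_seed)
      counts[cbind(seq_along(u), rs$id + 1L)] <-
        counts[cbind(seq_along(u), rs$id + 1L)] + 1L
    }
    alb <- alb / (ss * ss)
    vote_id <- max.col(counts, ties.method = "first") - 1L
    # break exact ties in favour of the center ray's id
    tied <- counts[cbind(seq_along(u), vote_id + 1L)] ==
      counts[cbind(seq_along(u), rc$id + 1L)]
    vote_id[tied] <- rc$id[tied]
  }
  if (noise_sigma > 0) {
    alb <- alb + with_seed(noise_seed,
                           matrix(stats::rnorm(length(alb), 0, noise_sigma),
                                  nrow(alb), 3))
    alb[] <- pmin(1, pmax(0, alb))
  }
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- matrix(alb[, ch], H, W)
  labels <- matrix(pmax(0L, vote_id - 2L), H, W)
  card_mask <- matrix(vote_id == 2L, H, W)
  list(image = img, labels = labels, card_mask = card_mask,
       depth = matrix(rc$s, H, W), hit_id = rc$id, hit_P = rc$P,
       pose = pose)
}

#' Generate a synthetic two-view scene with analytic ground truth
#'
#' Renders every view of the specification by exact ray casting (pinhole
#' projection with z-buffering, flat-shaded procedural textures), and stores
#' per-view ground truth: camera pose, gravity vector, segmentation masks,
#' card corner positions and per-solid analytic volumes. The same spec and
#' seed always produce bit-identical scenes.
#'
#' @param spec a [scene_spec()].
#' @param seed integer; fixes the pixel-noise and texture randomness.
#' @return object of class `mv_scene`; `views[[i]]` holds `image`, `labels`,
#'   `card_mask`, `pose`, `gravity`, `K`.
#' @export
make_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mv_scene_spec"))
  seed <- as.integer(seed)
  tex_seed <- (seed * 19L) %% 100000L
  views <- vector("list", length(spec$views))
  for (i in seq_along(spec$views)) {
    pose <- view_pose(spec$views[[i]], spec$target)
    rv <- render_one_view(spec, pose, spec$K, spec$noise_sigma,
                          noise_seed = seed * 1000L + i, tex_seed = tex_seed)
    rv$gravity <- gravity_from_pose(pose)
    rv$K <- spec$K
    for (k in seq_along(spec$solids)) {
      if (!any(rv$labels == k)) {
        stop("solid '", spec$solids[[k]]$label,
             "' is not visible in view ", i)
      }
    }
    views[[i]] <- rv
  }
  structure(list(
    spec = spec, seed = seed, tex_seed = tex_seed,
    solids = spec$solids, card = spec$card,
    card_center = spec$card_center, card_yaw_deg = spec$card_yaw_deg,
    card_corners = if (!is.null(spec$card))
      card_corners_world(spec$card, spec$card_center, spec$card_yaw_deg),
    volumes_ml = vapply(spec$solids, analytic_volume_ml, numeric(1)),
    labels = vapply(spec$solids, function(s) s$label, character(1)),
    K = spec$K, noise_sigma = spec$noise_sigma,
    views = views), class = "mv_scene")
}

#' @export
print.mv_scene <- function(x, ...) {
  cat("mv_scene:", length(x$solids), "solid(s),", length(x$views),
      "view(s); analytic volumes (ml):",
      paste(sprintf("%.1f", x$volumes_ml), collapse = ", "), "\n")
  invisible(x)
}

#' Rendered view plus exact correspondences to view 1
#'
#' Returns the stored rendering of a view together with exact sub-pixel
#' correspondences: for every pixel of view 1 whose surface point is also
#' visible in this view (checked by re-casting a ray and comparing first
#' hits, i.e., a z-buffer test), the matching sub-pixel location.
#'
#' @param scene an [make_scene()] result.
#' @param view_index which view (1-based).
#' @return list with `image`, `labels`, `card_mask`, `pose`, `gravity`, and
#'   `correspondences`: a list of matrices `uv1` (integer pixels in view 1),
#'   `uv2` (sub-pixel matches in this view), `world` (ground-truth 3D points)
#'   and vector `id` (0 background/table, -1 card, k > 0 solid k).
#' @export
render_view <- function(scene, view_index) {
  stopifnot(inherits(scene, "mv_scene"))
  if (view_index < 1 || view_index > length(scene$views)) {
    stop("view_index out of range")
  }
  v <- scene$views[[view_index]]
  out <- v[c("image", "labels", "card_mask", "pose", "gravity", "K")]
  out$correspondences <- scene_correspondences(scene, view_index)
  out
}

#' @rdname render_view
#' @param tol_mm 3D agreement tolerance of the mutual-visibility test.
#' @export
scene_correspondences <- function(scene, view_index, tol_mm = 0.1) {
  v1 <- scene$views[[1]]
  v2 <- scene$views[[view_index]]
  K <- scene$K
  W <- K$width; H <- K$height
  ok <- is.finite(v1$hit_P[, 1]) & v1$hit_id >= 1L
  P <- v1$hit_P[ok, , drop = FALSE]
  uv2 <- project_points(P, v2$pose, K)
  inb <- !is.na(uv2[, 1]) & uv2[, 1] >= 1 & uv2[, 1] <= W &
    uv2[, 2] >= 1 & uv2[, 2] <= H
  idx <- which(ok)[inb]
  P <- P[inb, , drop = FALSE]
  uv2 <- uv2[inb, , drop = FALSE]
  if (view_index == 1) {
    vis <- rep(TRUE, nrow(P))
  } else {
    rc <- raycast(scene$spec, v2$pose, K, uv2[, 1], uv2[, 2])
    dd <- sqrt(rowSums((rc$P - P)^2))
    vis <- is.finite(dd) & dd < tol_mm
  }
  idx <- idx[vis]
  u1 <- (idx - 1L) %/% H + 1L
  v1pix <- (idx - 1L) %% H + 1L
  id <- v1$hit_id[idx] - 2L      # 1..n solids; 0 card; -1 table
  id <- ifelse(id == -1L, 0L, ifelse(id == 0L, -1L, id))
  list(uv1 = cbind(u = u1, v = v1pix),
       uv2 = uv2[vis, , drop = FALSE],
       world = P[vis, , drop = FALSE],
       id = id)
}
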