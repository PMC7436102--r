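# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# The canonical two-item meal scene: a mashed-potato mound (spherical cap,
# 141.37 ml) and a beef patty (cylinder, 44.33 ml) on the textured table
# beside the reference card, rendered at 90/75 degrees.
golden_scene_spec <- function(noise = 0, supersample = 2) {
  scene_spec(solids = list(
    food_solid("spherical_cap", list(r = 60, h = 30),
               base_center = c(-40, 95), label = "mashed_potato",
               texture_seed = 3),
    food_solid("cylinder", list(r = 28, h = 18),
               base_center = c(52, 110), label = "beef_patty",
               texture_seed = 6)),
    noise_sigma = noise, supersample = supersample)
}

golden_scene <- function(seed = 1) {
  cached(paste0("golden", seed), make_scene(golden_scene_spec(), seed))
}

golden_seeds <- function() {
  list(seed_stroke(1, cbind(110:125, 90)),
       seed_stroke(2, cbind(70:80, 100)))
}

toy_taxonomy <- function() {
  as_taxonomy(data.frame(
    fine = c("spaghetti_bolognese", "penne_arrabiata", "beef_patty",
             "chicken_breast", "broccoli", "carrot_sticks", "rice_pilaf",
             "mashed_potato"),
    hyper2 = c("pasta", "pasta", "meat", "meat", "vegetables", "vegetables",
               "starch", "starch"),
    hyper1 = c("carbs", "carbs", "protein", "protein", "veg", "veg",
               "carbs", "carbs"),
    stringsAsFactors = FALSE))
}

toy_nutrients <- function() {
  as_nutrient_table(data.frame(
    key = c("spaghetti_bolognese", "penne_arrabiata", "beef_patty",
            "chicken_breast", "broccoli", "mashed_potato", "meat"),
    kcal_per_100ml = c(120, 110, 220, 150, 35, 85, 190),
    cho_g = c(15, 16, 0, 0, 5, 12, 1),
    pro_g = c(6, 4, 19, 28, 3, 2, 22),
    fat_g = c(4, 3, 16, 3.5, 0.5, 3, 11),
    stringsAsFactors = FALSE))
}

# Flat-color two-disk image for segmentation tests.
two_disk_image <- function(size = 60, bg = 0.35) {
  img <- array(bg, c(size, size, 3))
  g <- expand.grid(v = seq_len(size), u = seq_len(size))
  d1 <- matrix((g$u - 18)^2 + (g$v - 20)^2 <= 9^2, size, size)
  d2 <- matrix((g$u - 42)^2 + (g$v - 38)^2 <= 11^2, size, size)
  img[, , 1][d1] <- 0.8; img[, , 2][d1] <- 0.2; img[, , 3][d1] <- 0.2
  img[, , 1][d2] <- 0.2; img[, , 2][d2] <- 0.7; img[, , 3][d2] <- 0.3
  truth <- matrix(0L, size, size)
  truth[d1] <- 1L; truth[d2] <- 2L
  list(image = img, truth = truth, d1 = d1, d2 = d2)
}

# One interior seed stroke per ground-truth item: a short horizontal run of
# pixels around the item's most interior row.
strokes_from_truth <- function(truth, len = 6) {
  lapply(seq_len(max(truth)), function(k) {
    idx <- which(truth == k)
    H <- nrow(truth)
    uu <- (idx - 1) %/% H + 1
    vv <- (idx - 1) %% H + 1
    cu <- round(stats::median(uu)); cv <- round(stats::median(vv))
    # walk to an interior pixel if the medians fall outside the mask
    if (truth[cv, cu] != k) {
      j <- which.min((uu - cu)^2 + (vv - cv)^2)
      cu <- uu[j]; cv <- vv[j]
    }
    us <- cu + seq(-len %/% 2, len %/% 2)
    keep <- us >= 1 & us <= ncol(truth) & truth[cv, us] == k
    seed_stroke(k, cbind(us[keep], cv))
  })
}

# Correspondence-set lookup keyed by view-1 pixel.
corr_key <- function(uv) paste(uv[, 1], uv[, 2], sep = ",")

# Volume estimates for one scene from its exact correspondences (optionally
# with Gaussian pixel noise on the view-2 side), using the stored poses.
volumes_from_exact <- function(scene, noise_px = 0, noise_seed = 1,
                               max_points = 12000, grid_mm = 1) {
  co <- scene_correspondences(scene, 2)
  n <- nrow(co$uv1)
  if (n > max_points) {
    keep <- round(seq(1, n, length.out = max_points))
    co <- list(uv1 = co$uv1[keep, ], uv2 = co$uv2[keep, ],
               world = co$world[keep, ], id = co$id[keep])
  }
  uv2 <- co$uv2
  if (noise_px > 0) {
    uv2 <- uv2 + withr::with_seed(noise_seed,
      matrix(stats::rnorm(length(uv2), 0, noise_px), nrow(uv2), 2))
  }
  p1 <- scene$views[[1]]$pose; p2 <- scene$views[[2]]$pose
  cl <- triangulate(list(uv1 = co$uv1, uv2 = uv2), p1, p2, scene$K)
  # triangulate can drop points; map ids through the kept source pixels
  ids <- co$id[match(corr_key(cl$source_px), corr_key(co$uv1))]
  pl <- fit_table_plane(cl, c(0, 0, 1), ids <= 0)
  vols <- vapply(seq_along(scene$solids), function(k) {
    integrate_volume(cl, pl, ids == k, grid_mm, k)$volume_ml
  }, numeric(1))
  list(est = vols, truth = scene$volumes_ml)
}

# Small independent geometry helpers (kept separate from the package's
# internals so tests do not reach into unexported code).
rot_z_mat <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

card_corners_local_pts <- function(spec) {
  w <- spec$width_mm / 2; h <- spec$height_mm / 2
  cbind(c(-w, w, w, -w), c(h, h, -h, -h))
}

rotation_angle_deg <- function(R1, R2) {
  c0 <- (sum(diag(t(R1) %*% R2)) - 1) / 2
  acos(max(-1, min(1, c0))) * 180 / pi
}
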