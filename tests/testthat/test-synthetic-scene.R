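# Scene generator: analytic volumes, determinism, gravity/mask/correspondence
# consistency.

test_that("analytic volumes match closed forms and bad solids are rejected", {
  cap <- food_solid("spherical_cap", list(r = 60, h = 30))
  expect_equal(analytic_volume_ml(cap), pi * 30^2 * (3 * 60 - 30) / 3 / 1000)
  expect_equal(round(analytic_volume_ml(cap), 2), 141.37)
  expect_equal(analytic_volume_ml(
    food_solid("cuboid", list(lx = 40, ly = 40, lz = 20))), 32.0)
  expect_equal(analytic_volume_ml(
    food_solid("cylinder", list(r = 28, h = 18))), pi * 28^2 * 18 / 1000)
  expect_equal(analytic_volume_ml(
    food_solid("half_ellipsoid", list(a = 30, b = 40, c = 20))),
    2 / 3 * pi * 30 * 40 * 20 / 1000)
  expect_error(food_solid("cylinder", list(r = -5, h = 10), label = "bad1"),
               "bad1")
  expect_error(food_solid("spherical_cap", list(r = 20, h = 30),
                          label = "bad2"), "bad2")
})

test_that("same spec and seed give bit-identical scenes", {
  s1 <- make_scene(golden_scene_spec(noise = 0.01), 42)
  s2 <- make_scene(golden_scene_spec(noise = 0.01), 42)
  expect_identical(s1$views[[1]]$image, s2$views[[1]]$image)
  expect_identical(s1$views[[2]]$labels, s2$views[[2]]$labels)
  s3 <- make_scene(golden_scene_spec(noise = 0.01), 43)
  expect_false(identical(s1$views[[1]]$image, s3$views[[1]]$image))
})

test_that("gravity consistency: camera rotation maps g_cam back to world down", {
  sc <- golden_scene()
  for (v in sc$views) {
    down <- as.numeric(t(v$pose$R) %*% v$gravity$g_cam)
    expect_equal(down, c(0, 0, -1), tolerance = 1e-12)
  }
})

test_that("stored view elevations follow the 90/75 capture protocol", {
  sc <- golden_scene()
  expect_equal(camera_elevation_deg(sc$views[[1]]$gravity), 90)
  expect_equal(camera_elevation_deg(sc$views[[2]]$gravity), 75,
               tolerance = 1e-9)
})

test_that("food masks never overlap the card mask", {
  sc <- golden_scene()
  for (v in sc$views) {
    expect_false(any(v$labels > 0 & v$card_mask))
    for (k in seq_along(sc$solids)) expect_gt(sum(v$labels == k), 0)
  }
})

test_that("nadir view projects the card to an axis-aligned rectangle", {
  sc <- golden_scene()
  uv <- project_points(sc$card_corners, sc$views[[1]]$pose, sc$K)
  # opposite edges parallel to the pixel axes up to numerical noise
  expect_equal(uv[1, 2], uv[2, 2], tolerance = 1e-9)
  expect_equal(uv[3, 2], uv[4, 2], tolerance = 1e-9)
  expect_equal(uv[2, 1], uv[3, 1], tolerance = 1e-9)
})

test_that("table-plane correspondences satisfy the plane homography", {
  sc <- golden_scene()
  co <- scene_correspondences(sc, 2)
  tab <- which(co$id == 0)[1:50]
  # oracle: the homography induced by z = 0 built directly from the poses
  Km <- matrix(c(sc$K$fx, 0, sc$K$cx, 0, sc$K$fy, sc$K$cy, 0, 0, 1),
               3, 3, byrow = TRUE)
  P_of <- function(pose) Km %*% cbind(pose$R[, 1:2], pose$t)
  H <- P_of(sc$views[[2]]$pose) %*% solve(P_of(sc$views[[1]]$pose))
  x1 <- cbind(co$uv1[tab, 1], co$uv1[tab, 2], 1)
  x2h <- x1 %*% t(H)
  expect_equal(x2h[, 1] / x2h[, 3], co$uv2[tab, 1], tolerance = 1e-6)
  expect_equal(x2h[, 2] / x2h[, 3], co$uv2[tab, 2], tolerance = 1e-6)
})

test_that("z-buffering removes occluded points from the correspondence set", {
  spec <- scene_spec(solids = list(
    food_solid("cuboid", list(lx = 70, ly = 70, lz = 45),
               base_center = c(0, 95), label = "slab")),
    supersample = 1)
  sc <- make_scene(spec, 3)
  # a table point hidden behind the slab in view 2: extend the view-2 ray
  # through a point on the slab's top face down to the plane; it lands in
  # the slab's occlusion shadow
  top <- c(0, 70, 45)
  uv2 <- project_points(rbind(top), sc$views[[2]]$pose, sc$K)
  P_occ <- lift_to_plane(uv2, sc$views[[2]]$pose, sc$K)
  uv1 <- project_points(P_occ, sc$views[[1]]$pose, sc$K)
  px <- round(uv1)
  co <- scene_correspondences(sc, 2)
  hit <- which(co$uv1[, 1] == px[1] & co$uv1[, 2] == px[2])
  expect_length(hit, 0)
  # sanity: that pixel is plain table in view 1, so only occlusion (not
  # labeling) removed it
  expect_equal(sc$views[[1]]$labels[px[2], px[1]], 0L)
})

test_that("depth-field integration of each solid matches its volume within 1%", {
  solids <- list(
    food_solid("spherical_cap", list(r = 60, h = 30)),
    food_solid("cylinder", list(r = 28, h = 18)),
    food_solid("cuboid", list(lx = 40, ly = 40, lz = 20)),
    food_solid("half_ellipsoid", list(a = 35, b = 30, c = 22)))
  g <- expand.grid(x = seq(-69.75, 69.75, by = 0.5),
                   y = seq(-69.75, 69.75, by = 0.5))  # cell centers
  for (s in solids) {
    v <- sum(solid_height(s, g$x, g$y)) * 0.25 / 1000
    expect_lt(abs(v / analytic_volume_ml(s) - 1), 0.01)
  }
})

test_that("degenerate camera poses are rejected", {
  spec <- golden_scene_spec()
  spec$views[[2]] <- view_at(-30)  # below the table
  expect_error(make_scene(spec, 1), "above the table")
})

test_that("scene serialization round-trips through PPM/PGM/JSON", {
  sc <- golden_scene()
  dir <- file.path(tempdir(), "scene_rt")
  write_scene_dir(sc, dir)
  rt <- read_scene_dir(dir)
  expect_equal(rt$volumes_ml, unname(sc$volumes_ml))
  expect_identical(rt$views[[1]]$labels, unclass(sc$views[[1]]$labels))
  expect_lt(max(abs(rt$views[[1]]$image - sc$views[[1]]$image)), 1 / 255)
  expect_equal(rt$views[[2]]$pose$R, sc$views[[2]]$pose$R, tolerance = 1e-9)
  expect_equal(rt$views[[2]]$gravity$g_cam, sc$views[[2]]$gravity$g_cam,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("classification set: counts, separability, determinism", {
  tax <- as_taxonomy(data.frame(
    fine = c("a", "b", "c", "d"), hyper2 = c("x", "x", "y", "y"),
    hyper1 = c("p", "p", "q", "q")))
  set <- make_classification_set(tax, n_per_class = 8, seed = 5,
                                 noise_sigma = 0)
  expect_length(set$images, 32)
  expect_equal(dim(set$labels), c(32L, 3L))
  expect_setequal(names(set$labels), c("fine", "hyper2", "hyper1"))
  means <- t(vapply(seq(1, 32, by = 8), function(i) {
    vapply(1:3, function(ch) mean(set$images[[i]][, , ch]), numeric(1))
  }, numeric(3)))
  expect_gt(min(stats::dist(means)), 0.02)  # pairwise distinct class colors
  set2 <- make_classification_set(tax, n_per_class = 8, seed = 5,
                                  noise_sigma = 0)
  expect_identical(set$images, set2$images)
  expect_error(make_classification_set(tax, n_per_class = 0), "n_per_class")
})
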