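# Plane fitting and volume integration.

make_cloud <- function(points, px = NULL) {
  structure(list(points = points,
                 source_px = if (is.null(px))
                   cbind(seq_len(nrow(points)), 1) else px,
                 residual_px = rep(0, nrow(points)),
                 n_excluded = 0L), class = "mv_point_cloud")
}

test_that("plane fit: gravity normal kept bit-for-bit, offset from median", {
  sc <- golden_scene()
  co <- scene_correspondences(sc, 2)
  cl <- triangulate(list(uv1 = co$uv1, uv2 = co$uv2),
                    sc$views[[1]]$pose, sc$views[[2]]$pose, sc$K)
  ids <- co$id[match(corr_key(cl$source_px), corr_key(co$uv1))]
  nrm <- c(0, 0, 1)
  pl <- fit_table_plane(cl, nrm, ids <= 0)
  expect_identical(pl$normal, nrm)
  expect_lt(abs(pl$d), 0.5)
})

test_that("median offset resists 30% food contamination of the background", {
  pts <- rbind(
    withr::with_seed(1, cbind(runif(700, -100, 100), runif(700, -100, 100),
                              rnorm(700, 0, 0.2))),
    withr::with_seed(2, cbind(runif(300, -50, 50), runif(300, -50, 50),
                              runif(300, 5, 30))))
  pl <- fit_table_plane(make_cloud(pts), c(0, 0, 1), rep(TRUE, 1000))
  expect_lt(abs(pl$d), 2)
})

test_that("too few background points is an error", {
  pts <- matrix(rnorm(15), 5, 3)
  expect_error(fit_table_plane(make_cloud(pts), c(0, 0, 1), rep(TRUE, 5)),
               ">= 10")
})

test_that("volume of a dense cap cloud is within 5% of the closed form", {
  cap <- food_solid("spherical_cap", list(r = 60, h = 30))
  g <- expand.grid(x = seq(-60, 60, 1.3), y = seq(-60, 60, 1.3))
  h <- solid_height(cap, g$x, g$y)
  sel <- h > 0
  pts <- cbind(g$x[sel], g$y[sel], h[sel])
  pl <- structure(list(normal = c(0, 0, 1), d = 0), class = "mv_plane")
  v <- integrate_volume(make_cloud(pts), pl, TRUE, 1.0)
  expect_lt(abs(v$volume_ml / analytic_volume_ml(cap) - 1), 0.05)
  expect_equal(v$grid_resolution_mm, 1.0)
  expect_gt(v$footprint_area_mm2, 0)
})

test_that("points on the plane integrate to zero volume", {
  pts <- withr::with_seed(3, cbind(runif(400, -40, 40), runif(400, -40, 40),
                                   0))
  pl <- structure(list(normal = c(0, 0, 1), d = 0), class = "mv_plane")
  expect_equal(integrate_volume(make_cloud(pts), pl, TRUE, 1)$volume_ml, 0)
})

test_that("disjoint items are additive within 1%", {
  cap <- food_solid("spherical_cap", list(r = 40, h = 20),
                    base_center = c(-60, 0))
  box <- food_solid("cuboid", list(lx = 40, ly = 40, lz = 15),
                    base_center = c(60, 0))
  g <- expand.grid(x = seq(-110, 110, 1.1), y = seq(-55, 55, 1.1))
  h <- solid_height(cap, g$x, g$y) + solid_height(box, g$x, g$y)
  pts <- cbind(g$x, g$y, h)
  item <- ifelse(solid_height(cap, g$x, g$y) > 0, 1L,
                 ifelse(solid_height(box, g$x, g$y) > 0, 2L, 0L))
  pl <- structure(list(normal = c(0, 0, 1), d = 0), class = "mv_plane")
  cl <- make_cloud(pts)
  v1 <- integrate_volume(cl, pl, item == 1L, 1, 1)$volume_ml
  v2 <- integrate_volume(cl, pl, item == 2L, 1, 2)$volume_ml
  vall <- integrate_volume(cl, pl, item > 0L, 1, 0)$volume_ml
  expect_lt(abs((v1 + v2) / vall - 1), 0.01)
})

test_that("empty masks warn and report zero volume", {
  pts <- matrix(rnorm(30), 10, 3)
  pl <- structure(list(normal = c(0, 0, 1), d = 0), class = "mv_plane")
  expect_warning(v <- integrate_volume(make_cloud(pts), pl, rep(FALSE, 10)),
                 "empty")
  expect_equal(v$volume_ml, 0)
})

test_that("metric gauge: scaling the world scales volumes cubically", {
  sc <- golden_scene()
  co <- scene_correspondences(sc, 2)
  pick <- round(seq(1, nrow(co$uv1), length.out = 6000))
  co <- list(uv1 = co$uv1[pick, ], uv2 = co$uv2[pick, ], id = co$id[pick])
  vols <- function(s) {
    p1 <- sc$views[[1]]$pose; p2 <- sc$views[[2]]$pose
    p1s <- mv_pose(p1$R, p1$t * s); p2s <- mv_pose(p2$R, p2$t * s)
    cl <- triangulate(co, p1s, p2s, sc$K)
    ids <- co$id[match(corr_key(cl$source_px), corr_key(co$uv1))]
    pl <- fit_table_plane(cl, c(0, 0, 1), ids <= 0)
    integrate_volume(cl, pl, ids == 1, 1 * s, 1)$volume_ml
  }
  expect_equal(vols(2) / vols(1), 8, tolerance = 0.02)
})
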