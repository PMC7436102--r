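# Card detection and planar pose estimation.

test_that("detected corners land within 0.5 px of the projected truth", {
  sc <- golden_scene()
  v <- sc$views[[1]]  # fronto-parallel (nadir) view
  det <- detect_card(v$image, sc$card)
  expect_true(det$found)
  gt <- project_points(sc$card_corners, v$pose, sc$K)
  expect_lt(max(sqrt(rowSums((det$corners_px - gt)^2))), 0.5)
  expect_gte(det$confidence, 0)
  expect_lte(det$confidence, 1)
})

test_that("absence of a card is signalled distinctly", {
  img <- array(0.3, c(80, 100, 3))
  det <- detect_card(img, card_spec())
  expect_false(det$found)
  expect_match(det$reason, "not found")
  expect_error(pose_from_card(det, card_spec(), default_intrinsics()),
               "not found")
})

test_that("a card rotated 180 degrees yields the same pose", {
  spec0 <- golden_scene_spec()
  spec180 <- golden_scene_spec()
  spec180$card_yaw_deg <- 180
  s0 <- make_scene(spec0, 2)
  s180 <- make_scene(spec180, 2)
  d0 <- detect_card(s0$views[[1]]$image, s0$card)
  d180 <- detect_card(s180$views[[1]]$image, s180$card)
  p0 <- pose_from_card(d0, s0$card, s0$K)
  p180 <- pose_from_card(d180, s180$card, s180$K)
  # the card is physically symmetric up to the stripe; rotating it 180
  # degrees rotates the recovered world frame with it, so the camera centers
  # agree after undoing the yaw
  c0 <- camera_center(p0)
  c180 <- as.numeric(rot_z_mat(pi) %*% camera_center(p180))
  expect_equal(c0, c180, tolerance = 0.5)
})

test_that("pose from exact corner projections is accurate to 0.1 deg / 1 mm", {
  sc <- golden_scene()
  for (vi in 1:2) {
    v <- sc$views[[vi]]
    gt_px <- project_points(sc$card_corners, v$pose, sc$K)
    pose <- pose_from_plane_points(card_corners_local_pts(sc$card), gt_px,
                                   sc$K)
    expect_lt(rotation_angle_deg(pose$R, v$pose$R), 0.1)
    expect_lt(sqrt(sum((pose$t - v$pose$t)^2)), 1)
  }
})

test_that("camera at 90 deg elevation is recovered at 90 +/- 0.1 deg", {
  sc <- golden_scene()
  v <- sc$views[[1]]
  gt_px <- project_points(sc$card_corners, v$pose, sc$K)
  pose <- pose_from_plane_points(card_corners_local_pts(sc$card), gt_px,
                                 sc$K)
  g <- mv_gravity(as.numeric(pose$R %*% c(0, 0, -1)))
  expect_equal(camera_elevation_deg(g), 90, tolerance = 0.1)
})

test_that("translation error under 0.5 px corner noise stays below 2% of distance", {
  # Monte-Carlo bound frozen from the implementation's own runs: with 0.5 px
  # Gaussian noise on the four corners, the median translation error over
  # 100 seeds stays well under 2% of the camera distance
  sc <- golden_scene()
  v <- sc$views[[2]]
  gt_px <- project_points(sc$card_corners, v$pose, sc$K)
  dist_mm <- sqrt(sum(camera_center(v$pose)^2))
  errs <- vapply(1:100, function(s) {
    px <- gt_px + withr::with_seed(s,
      matrix(stats::rnorm(8, 0, 0.5), 4, 2))
    p <- pose_from_plane_points(card_corners_local_pts(sc$card), px, sc$K)
    sqrt(sum((p$t - v$pose$t)^2))
  }, numeric(1))
  expect_lt(stats::median(errs) / dist_mm, 0.02)
})

test_that("near-degenerate quadrilaterals are rejected", {
  det <- structure(list(found = TRUE,
                        corners_px = cbind(c(50, 52, 52, 50),
                                           c(50, 50, 51, 51)),
                        confidence = 1), class = "mv_card_detection")
  expect_error(pose_from_card(det, card_spec(), default_intrinsics()),
               "degenerate")
})

test_that("metric gauge: scaling the card scales the translation", {
  sc <- golden_scene()
  v <- sc$views[[1]]
  gt_px <- project_points(sc$card_corners, v$pose, sc$K)
  p1 <- pose_from_plane_points(card_corners_local_pts(sc$card), gt_px, sc$K)
  big <- card_spec(sc$card$width_mm * 2, sc$card$height_mm * 2)
  p2 <- pose_from_plane_points(card_corners_local_pts(big), gt_px, sc$K)
  expect_equal(p2$t, 2 * p1$t, tolerance = 1e-6)
  expect_lt(rotation_angle_deg(p1$R, p2$R), 1e-6)
})
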