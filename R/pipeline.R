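#' Pipeline configuration
#'
#' Collects every stage's tunables with documented defaults. In
#' `single_camera` mode the reference card must be visible in both views
#' (it fixes the metric scale and the world frame); in `stereo_rig` mode
#' the known `baseline_mm` fixes the scale and the card is optional.
#'
#' @param mode "single_camera" or "stereo_rig".
#' @param K an [mv_intrinsics()].
#' @param card a [card_spec()].
#' @param baseline_mm rig baseline (required in stereo_rig mode).
#' @param seeds optional list of [seed_stroke()]; when absent the automatic
#'   segmenter fallback is used.
#' @param tau_grow,tau_merge segmentation thresholds (see
#'   [region_grow_merge()]).
#' @param match list of [dense_match()] settings.
#' @param grid_mm volume-integration grid (see [integrate_volume()]).
#' @param model optional trained `mv_hier_model` for recognition.
#' @param item_labels optional character vector naming item 1..N directly
#'   (bypasses recognition).
#' @param level_weights,fallback_threshold weighted-inference settings.
#' @param nutrient_table optional `mv_nutrient_table`; without it the
#'   pipeline stops after volumes.
#' @param taxonomy optional `mv_taxonomy`.
#' @param keep_intermediates optional directory: when set, every stage's
#'   output is persisted there.
#' @param verbose print per-stage timings.
#' @return a config list.
#' @export
pipeline_config <- function(mode = c("single_camera", "stereo_rig"),
                            K = default_intrinsics(), card = card_spec(),
                            baseline_mm = NULL, seeds = NULL,
                            tau_grow = 20, tau_merge = 12,
                            match = list(), grid_mm = 1.0,
                            model = NULL, item_labels = NULL,
                            level_weights = c(1, 1, 1),
                            fallback_threshold = 0.5,
                            nutrient_table = NULL, taxonomy = NULL,
                            keep_intermediates = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "stereo_rig" && is.null(baseline_mm)) {
    stop("stereo_rig mode needs baseline_mm")
  }
  # defaults differ from dense_match()'s own: at the synthetic working
  # resolution (~2 mm per pixel) an 11 px window spans > 20 mm of table and
  # flattens sloped surfaces, so the pipeline uses a 7 px window, a lower
  # score floor and a slightly wider LR tolerance (sub-pixel interpolation
  # quantization exceeds 1 px near rims at this resolution)
  m_def <- list(window = 7, lr_tol_px = 1.5, height_range_mm = c(-4, 84),
                height_step_mm = 1.0, min_ncc = 0.3, refine_iters = 3L,
                refine_window = 5)
  if (mode == "stereo_rig") {
    # rig world frame is anchored on camera 1, so the table lies near
    # z = -capture_distance; sweep coarsely over plausible distances and let
    # the refinement passes recover the sub-step detail
    m_def$height_range_mm <- c(-620, -250)
    m_def$height_step_mm <- 4
  }
  m_def[names(match)] <- match
  list(mode = mode, K = K, card = card, baseline_mm = baseline_mm,
       seeds = seeds, tau_grow = tau_grow, tau_merge = tau_merge,
       match = m_def, grid_mm = grid_mm, model = model,
       item_labels = item_labels, level_weights = level_weights,
       fallback_threshold = fallback_threshold,
       nutrient_table = nutrient_table, taxonomy = taxonomy,
       keep_intermediates = keep_intermediates, verbose = verbose)
}

run_stage <- function(state, name, hint, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         if (nzchar(hint)) paste0(" [hint: ", hint, "]"), call. = FALSE)
  })
  if (isTRUE(state$verbose)) {
    message(sprintf("[%s] %.2fs", name, proc.time()[3] - t0))
  }
  state$timings[[name]] <- proc.time()[3] - t0
  assign("timings", state$timings, envir = state)
  out
}

# pixels inside the convex quadrilateral `quad` (4 x 2, any consistent
# winding), as a logical H x W matrix; `margin` dilates the quad outward.
quad_mask <- function(quad, H, W, margin = 0) {
  ctr <- colMeans(quad)
  u <- rep(seq_len(W), each = H)
  v <- rep(seq_len(H), W)
  inside <- rep(TRUE, H * W)
  for (e in 1:4) {
    p1 <- quad[e, ]; p2 <- quad[e %% 4 + 1, ]
    nrm <- c(p2[2] - p1[2], p1[1] - p2[1])
    nrm <- nrm / max(vnorm(nrm), 1e-12)
    if (sum((ctr - p1) * nrm) < 0) nrm <- -nrm
    inside <- inside & ((u - p1[1]) * nrm[1] + (v - p1[2]) * nrm[2] >= -margin)
  }
  matrix(inside, H, W)
}

#' Run the full two-view pipeline
#'
#' Orchestrates card detection, metric pose recovery (gravity-aided for the
#' second view), segmentation, dense matching, triangulation, table-plane
#' fitting, per-item volume integration, recognition and nutrient
#' computation. Any stage error is re-raised with the stage name and a
#' remediation hint. Re-running with the same inputs and config yields an
#' identical report.
#'
#' @param image1,image2 the two views, `array(H, W, 3)` in `[0, 1]`.
#' @param gravity1,gravity2 per-view [mv_gravity()] samples.
#' @param config a [pipeline_config()].
#' @return list: `meal` (an `mv_meal_estimate`, or `NULL` when no nutrient
#'   table is configured), `volumes` (list of `mv_volume_estimate`),
#'   `segmentation`, `cloud`, `plane`, `poses`, `recognition`, `timings`.
#' @export
run_pipeline <- function(image1, image2, gravity1, gravity2, config) {
  st <- new.env()
  st$timings <- list()
  st$verbose <- isTRUE(config$verbose)
  K <- config$K
  g1 <- as_gravity(gravity1); g2 <- as_gravity(gravity2)

  if (config$mode == "single_camera") {
    det1 <- run_stage(st, "detect_card_view1",
                      "place the reference card fully inside both views",
                      detect_card(image1, config$card))
    if (!isTRUE(det1$found)) {
      stop("pipeline stage 'detect_card_view1': ", det1$reason,
           " [hint: single-camera mode requires the reference card; use ",
           "stereo_rig mode with a known baseline otherwise]", call. = FALSE)
    }
    pose1 <- run_stage(st, "pose_view1", "check camera intrinsics",
                       pose_from_card(det1, config$card, K))
    # gravity fixes the tilt of view 1 exactly; the card corners then only
    # need to supply yaw, translation and metric scale
    pose1 <- run_stage(st, "pose_view1_gravity", "check gravity vectors",
                       relative_pose_gravity_aided(
                         pose1, g1, g1,
                         list(world = card_corners_local(config$card),
                              uv2 = det1$corners_px), K))
    det2 <- run_stage(st, "detect_card_view2",
                      "place the reference card fully inside both views",
                      detect_card(image2, config$card))
    if (!isTRUE(det2$found)) {
      stop("pipeline stage 'detect_card_view2': ", det2$reason,
           " [hint: the card must be visible in the second view too]",
           call. = FALSE)
    }
    pose2 <- run_stage(st, "pose_view2_gravity", "check gravity vectors",
                       relative_pose_gravity_aided(
                         pose1, g1, g2,
                         list(world = card_corners_local(config$card),
                              uv2 = det2$corners_px), K))
  } else {
    R1 <- gravity_frame(g1$g_cam)
    pose1 <- mv_pose(orthonormalize_rotation(R1), c(0, 0, 0))
    Rrel <- if (vnorm(g1$g_cam - g2$g_cam) < 1e-12) diag(3) else
      rotation_between(g1$g_cam, g2$g_cam)
    rel <- mv_pose(orthonormalize_rotation(Rrel),
                   as.numeric(-Rrel %*% c(config$baseline_mm, 0, 0)))
    pose2 <- pose_compose(rel, pose1)
    det1 <- NULL
  }

  seg <- run_stage(st, "segmentation",
                   "provide seed strokes for ambiguous scenes",
                   if (!is.null(config$seeds)) {
                     region_grow_merge(image1, config$seeds,
                                       config$tau_grow, config$tau_merge)
                   } else auto_segment(image1))
  n_items <- max(seg)

  if (config$mode == "single_camera") {
    pose2 <- run_stage(st, "refine_pose_dense",
                       "background must show textured table surface",
                       refine_relative_pose_dense(image1, image2, pose1,
                                                  pose2, K, g2, seg == 0L))
  }

  mp <- config$match
  if (config$mode == "stereo_rig") {
    # the rig frame is anchored on camera 1, so the table depth is unknown:
    # locate it with a coarse sweep over plausible capture distances, then
    # narrow the fine sweep around the fitted plane
    coarse <- run_stage(st, "estimate_table_depth",
                        "check baseline_mm and capture distance", {
      cm <- dense_match(image1, image2, pose1, pose2, K,
                        window = mp$window, lr_tol_px = 2 * mp$lr_tol_px,
                        height_range_mm = mp$height_range_mm,
                        height_step_mm = max(4, mp$height_step_mm),
                        min_ncc = mp$min_ncc, refine_iters = 0L)
      cl0 <- triangulate(cm, pose1, pose2, K)
      src0 <- (cl0$source_px[, 1] - 1) * dim(image1)[1] + cl0$source_px[, 2]
      bg0 <- as.integer(seg)[src0] == 0L
      n0 <- as.numeric(t(pose1$R) %*% table_normal_from_gravity(g1))
      fit_table_plane(cl0, n0, bg0)
    })
    mp$height_range_mm <- coarse$d + c(-15, 85)
    mp$height_step_mm <- min(mp$height_step_mm, 1)
  }
  matches <- run_stage(st, "dense_match", "images may lack texture",
                       dense_match(image1, image2, pose1, pose2, K,
                                   window = mp$window,
                                   lr_tol_px = mp$lr_tol_px,
                                   height_range_mm = mp$height_range_mm,
                                   height_step_mm = mp$height_step_mm,
                                   min_ncc = mp$min_ncc,
                                   refine_iters = mp$refine_iters,
                                   refine_window = mp$refine_window))
  cloud <- run_stage(st, "triangulate", "check the relative pose",
                     triangulate(matches, pose1, pose2, K))

  H <- dim(image1)[1]; W <- dim(image1)[2]
  src_lin <- (cloud$source_px[, 1] - 1) * H + cloud$source_px[, 2]
  pt_label <- as.integer(seg)[src_lin]
  bg <- pt_label == 0L
  if (config$mode == "single_camera" && !is.null(det1)) {
    cmask <- quad_mask(det1$corners_px, H, W, margin = 3)
    bg <- bg & !as.logical(cmask)[src_lin]
  }
  n_world <- as.numeric(t(pose1$R) %*% table_normal_from_gravity(g1))
  plane <- run_stage(st, "fit_plane",
                     "too little visible table around the food",
                     fit_table_plane(cloud, n_world, bg))

  volumes <- run_stage(st, "integrate_volumes", "check segmentation labels",
                       lapply(seq_len(n_items), function(k) {
                         integrate_volume(cloud, plane, pt_label == k,
                                          config$grid_mm, item_id = k)
                       }))

  recog <- NULL
  if (!is.null(config$model)) {
    recog <- run_stage(st, "recognition", "train or load a model first", {
      lapply(seq_len(n_items), function(k) {
        sel <- which(seg == k)
        vs <- range((sel - 1) %% H + 1); us <- range((sel - 1) %/% H + 1)
        crop <- image1[vs[1]:vs[2], us[1]:us[2], , drop = FALSE]
        probs <- predict_probs(config$model, list(crop))
        weighted_inference(lapply(probs, function(p) p[1, ]),
                           config$level_weights, config$fallback_threshold,
                           config$model$taxonomy)
      })
    })
  }

  meal <- NULL
  if (!is.null(config$nutrient_table)) {
    meal <- run_stage(st, "nutrition",
                      "provide item_labels or a recognition model", {
      items <- lapply(seq_len(n_items), function(k) {
        cat_name <- if (!is.null(config$item_labels)) {
          config$item_labels[k]
        } else if (!is.null(recog)) recog[[k]]$chosen_label
        if (is.null(cat_name)) {
          stop("no category for item ", k)
        }
        list(category = cat_name, volume = volumes[[k]])
      })
      assemble_meal(items, config$nutrient_table, config$taxonomy)
    })
  }

  out <- list(meal = meal, volumes = volumes, segmentation = seg,
              cloud = cloud, plane = plane,
              poses = list(pose1 = pose1, pose2 = pose2),
              card_detections = if (config$mode == "single_camera")
                list(det1, det2),
              recognition = recog, timings = st$timings)
  if (!is.null(config$keep_intermediates)) {
    dir.create(config$keep_intermediates, showWarnings = FALSE,
               recursive = TRUE)
    write_pgm16(seg, file.path(config$keep_intermediates, "segmentation.pgm"))
    write_ply(cloud, file.path(config$keep_intermediates, "cloud.ply"))
    jsonlite::write_json(
      list(plane = list(normal = plane$normal, d = plane$d),
           volumes = lapply(volumes, function(v)
             list(item_id = v$item_id, volume_ml = v$volume_ml)),
           timings = st$timings),
      file.path(config$keep_intermediates, "stages.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(meal)) {
      meal_to_json(meal, file.path(config$keep_intermediates, "meal.json"))
    }
  }
  out
}

#' Run the pipeline directly on a synthetic scene
#'
#' Convenience wrapper: takes views 1 and 2 of an [make_scene()] scene and
#' their stored gravity samples and calls [run_pipeline()].
#'
#' @param scene an `mv_scene`.
#' @param config a [pipeline_config()]; the scene's intrinsics are used.
#' @return see [run_pipeline()].
#' @export
run_pipeline_on_scene <- function(scene, config = pipeline_config()) {
  config$K <- scene$K
  if (!is.null(scene$card)) config$card <- scene$card
  run_pipeline(scene$views[[1]]$image, scene$views[[2]]$image,
               scene$views[[1]]$gravity, scene$views[[2]]$gravity, config)
}
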