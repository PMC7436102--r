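# Plain-text image and point-cloud I/O. Scenes are serialized as portable
# pixmaps (PPM P3 for color, PGM P2 with maxval 65535 for 16-bit label
# masks) plus a JSON sidecar; point clouds as ascii PLY. All formats are
# text, self-describing and readable without extra packages.

#' Write / read plain (ascii) PPM and 16-bit PGM images
#'
#' @param img `array(H, W, 3)` with values in `[0, 1]` (PPM), or an integer
#'   matrix of labels (PGM).
#' @param path file path.
#' @return `read_ppm` returns an `array(H, W, 3)` in `[0,1]`; `read_pgm` an
#'   integer matrix.
#' @export
write_ppm <- function(img, path) {
  H <- dim(img)[1]; W <- dim(img)[2]
  q <- img
  q[] <- round(pmin(1, pmax(0, img)) * 255)
  # interleave channels row-major: r g b r g b ...
  px <- matrix(0L, 3 * W, H)
  for (ch in 1:3) px[seq(ch, by = 3, length.out = W), ] <- t(q[, , ch])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(W, H), "255"), con)
  write(px, con, ncolumns = 12)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(tok[1] == "P3")
  W <- as.integer(tok[2]); H <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) / maxv
  img <- array(0, c(H, W, 3))
  m <- matrix(vals, nrow = 3 * W)
  for (ch in 1:3) img[, , ch] <- t(m[seq(ch, by = 3, length.out = W), ])
  img
}

#' @rdname write_ppm
#' @param labels integer matrix (values 0..65535).
#' @export
write_pgm16 <- function(labels, path) {
  H <- nrow(labels); W <- ncol(labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(W, H), "65535"), con)
  write(t(labels), con, ncolumns = 16)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_pgm16 <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(tok[1] == "P2")
  W <- as.integer(tok[2]); H <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  matrix(vals, H, W, byrow = TRUE)
}

#' Serialize a synthetic scene to a directory
#'
#' Writes `view<i>.ppm` images, `mask<i>.pgm` label masks and a `scene.json`
#' sidecar (intrinsics, row-major rotations, translations, gravity vectors,
#' card corners, analytic volumes, labels).
#'
#' @param scene an [make_scene()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. `read_scene_dir` returns a list with the same
#'   images, masks and metadata.
#' @export
write_scene_dir <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    seed = scene$seed,
    intrinsics = scene$K[c("fx", "fy", "cx", "cy", "width", "height")],
    noise_sigma = scene$noise_sigma,
    labels = as.list(scene$labels),
    volumes_ml = as.list(scene$volumes_ml),
    card = if (!is.null(scene$card))
      list(width_mm = scene$card$width_mm, height_mm = scene$card$height_mm,
           center = scene$card_center, yaw_deg = scene$card_yaw_deg,
           corners_world = unclass(scene$card_corners)),
    views = lapply(seq_along(scene$views), function(i) {
      v <- scene$views[[i]]
      list(rotation_row_major = as.numeric(t(v$pose$R)),
           translation_mm = v$pose$t,
           gravity_cam = v$gravity$g_cam)
    }))
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(scene$views)) {
    write_ppm(scene$views[[i]]$image, file.path(dir, sprintf("view%d.ppm", i)))
    write_pgm16(scene$views[[i]]$labels,
                file.path(dir, sprintf("mask%d.pgm", i)))
  }
  invisible(dir)
}

#' @rdname write_scene_dir
#' @export
read_scene_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = FALSE)
  views <- list()
  i <- 1
  repeat {
    f <- file.path(dir, sprintf("view%d.ppm", i))
    if (!file.exists(f)) break
    vm <- meta$views[[i]]
    R <- matrix(unlist(vm$rotation_row_major), 3, 3, byrow = TRUE)
    views[[i]] <- list(
      image = read_ppm(f),
      labels = read_pgm16(file.path(dir, sprintf("mask%d.pgm", i))),
      pose = mv_pose(orthonormalize_rotation(R), unlist(vm$translation_mm)),
      gravity = mv_gravity(unlist(vm$gravity_cam)))
    i <- i + 1
  }
  K <- meta$intrinsics
  list(K = mv_intrinsics(K$fx, K$fy, K$cx, K$cy, K$width, K$height),
       labels = unlist(meta$labels), volumes_ml = unlist(meta$volumes_ml),
       card = meta$card, noise_sigma = meta$noise_sigma, seed = meta$seed,
       views = views)
}

#' Write a point cloud as ascii PLY
#'
#' @param cloud an `mv_point_cloud` (see [triangulate()]).
#' @param path output file.
#' @export
write_ply <- function(cloud, path) {
  pts <- cloud$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(pts, trim = TRUE, digits = 7), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
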