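#' Fit the table plane with a gravity-fixed normal
#'
#' The plane normal is not estimated: it comes straight from the gravity
#' sensor (the table is assumed horizontal), and is returned bit-for-bit
#' unchanged. Only the offset is estimated, as the median of the normal
#' projections of the background (non-food) points — robust to food pixels
#' contaminating the background mask.
#'
#' @param cloud an `mv_point_cloud` (see [triangulate()]).
#' @param normal_prior unit 3-vector, the table's up-normal in the cloud's
#'   frame.
#' @param background logical vector over cloud points marking background
#'   (non-food) points, or indices.
#' @return object of class `mv_plane`: `normal` (the prior, unchanged) and
#'   `d` such that the plane is `{x : n . x = d}`.
#' @export
fit_table_plane <- function(cloud, normal_prior, background) {
  pts <- cloud$points[background, , drop = FALSE]
  if (nrow(pts) < 10) {
    stop("too few background points to fit the table plane (need >= 10, got ",
         nrow(pts), ")")
  }
  d <- stats::median(pts %*% normal_prior)
  structure(list(normal = normal_prior, d = as.numeric(d)),
            class = "mv_plane")
}

# Median nearest-neighbour distance (in cell units) of occupied cells,
# estimated on a deterministic subsample.
median_cell_spacing <- function(iu, iv, max_n = 400) {
  cells <- unique(cbind(iu, iv))
  if (nrow(cells) < 2) return(1)
  if (nrow(cells) > max_n) {
    cells <- cells[round(seq(1, nrow(cells), length.out = max_n)), ]
  }
  d <- as.matrix(stats::dist(cells))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# Signed height of points above a plane.
plane_height <- function(points, plane) {
  as.numeric(points %*% plane$normal) - plane$d
}

#' Integrate the volume of one food item above the table plane
#'
#' Item points are projected onto the plane, the footprint is gridded at
#' `grid_mm`, each cell's height is the median of its member points clipped
#' at zero, interior holes (cells with no support that are enclosed by the
#' footprint) are filled from their nearest supported neighbours, and the
#' volume is the sum of cell area times height. Exterior cells contribute
#' nothing.
#'
#' @param cloud an `mv_point_cloud`.
#' @param plane an `mv_plane` from [fit_table_plane()].
#' @param item logical vector or indices selecting the item's points.
#' @param grid_mm grid resolution in mm (default 1).
#' @param item_id identifier copied into the result.
#' @return object of class `mv_volume_estimate`: `item_id`, `volume_ml`,
#'   `footprint_area_mm2`, `grid_resolution_mm`.
#' @export
integrate_volume <- function(cloud, plane, item = TRUE, grid_mm = 1.0,
                             item_id = 1L) {
  stopifnot(grid_mm > 0)
  pts <- cloud$points[item, , drop = FALSE]
  if (nrow(pts) == 0) {
    warning("empty item mask: volume reported as 0")
    return(structure(list(item_id = item_id, volume_ml = 0,
                          footprint_area_mm2 = 0,
                          grid_resolution_mm = grid_mm),
                     class = "mv_volume_estimate"))
  }
  n <- plane$normal
  # orthonormal in-plane basis
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(a - sum(a * n) * n)
  e2 <- cross3(n, e1)
  pu <- as.numeric(pts %*% e1)
  pv <- as.numeric(pts %*% e2)
  h <- pmax(0, plane_height(pts, plane))
  iu <- floor(pu / grid_mm)
  iv <- floor(pv / grid_mm)
  iu <- iu - min(iu) + 1L
  iv <- iv - min(iv) + 1L
  nu <- max(iu); nv <- max(iv)
  cell <- (iu - 1L) * nv + iv
  med <- tapply(h, cell, stats::median)
  grid <- matrix(NA_real_, nv, nu)
  ids <- as.integer(names(med))
  grid[cbind((ids - 1L) %% nv + 1L, (ids - 1L) %/% nv + 1L)] <- med
  empty <- is.na(grid)
  # the cloud may be sparser than the grid; close the support mask at the
  # measured point spacing so the exterior flood cannot leak between samples
  supp <- !empty
  spacing <- median_cell_spacing(iu, iv)
  closed <- binary_close(supp, max(1L, as.integer(ceiling(0.6 * spacing))))
  # exterior: cells outside the closed footprint connected (4-conn) to the
  # bounding-box border; everything else empty is an interior hole
  free <- empty & !closed
  ext <- free & FALSE
  border <- free
  if (nv > 2 && nu > 2) border[2:(nv - 1), 2:(nu - 1)] <- FALSE
  ext[border] <- TRUE
  if (nv > 2 && nu > 2) {
    repeat {
      grown <- ext
      grown[-1, ] <- grown[-1, ] | ext[-nv, ]
      grown[-nv, ] <- grown[-nv, ] | ext[-1, ]
      grown[, -1] <- grown[, -1] | ext[, -nu]
      grown[, -nu] <- grown[, -nu] | ext[, -1]
      grown <- grown & free
      if (identical(grown, ext)) break
      ext <- grown
    }
  }
  # interior holes: nearest-neighbour fill by iterative neighbour averaging
  hole <- empty & !ext
  while (any(hole)) {
    g0 <- grid
    cnt <- matrix(0, nv, nu); acc <- matrix(0, nv, nu)
    shift <- function(M, dr, dc) {
      out <- matrix(NA_real_, nv, nu)
      r1 <- max(1, 1 + dr):min(nv, nv + dr)
      c1 <- max(1, 1 + dc):min(nu, nu + dc)
      out[r1, c1] <- M[r1 - dr, c1 - dc]
      out
    }
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      s <- shift(g0, d[1], d[2])
      has <- !is.na(s)
      acc[has] <- acc[has] + s[has]
      cnt <- cnt + has
    }
    fill <- hole & cnt > 0
    if (!any(fill)) break
    grid[fill] <- acc[fill] / cnt[fill]
    hole <- hole & !fill
  }
  filled <- !is.na(grid)
  vol_mm3 <- sum(grid[filled]) * grid_mm^2
  structure(list(item_id = item_id,
                 volume_ml = vol_mm3 / 1000,
                 footprint_area_mm2 = sum(filled) * grid_mm^2,
                 grid_resolution_mm = grid_mm),
            class = "mv_volume_estimate")
}

#' @export
print.mv_volume_estimate <- function(x, ...) {
  cat(sprintf("item %s: %.2f ml over %.0f mm^2 (grid %.2g mm)\n",
              x$item_id, x$volume_ml, x$footprint_area_mm2,
              x$grid_resolution_mm))
  invisible(x)
}
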