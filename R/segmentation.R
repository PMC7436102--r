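# Seeded region growing and merging, a pluggable automatic segmenter with a
# classical fallback, and the Fmin/Fsum evaluation metric.

# Perceptual color distance: Euclidean in CIE Lab (sRGB, D65), the usual
# Delta-E 1976. Input: N x 3 sRGB in [0, 1].
rgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

image_lab <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  rgb_to_lab(cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
                   as.numeric(image[, , 3])))
}

#' Seed stroke for semi-automatic segmentation
#'
#' A user's scribble over one food item, as (u, v) pixel coordinates
#' (polyline already rasterized).
#'
#' @param item_id positive integer identifying the food item.
#' @param pixels N x 2 matrix of (u, v) pixel coordinates.
#' @return object of class `mv_seed_stroke`.
#' @export
seed_stroke <- function(item_id, pixels) {
  pixels <- rbind(pixels)
  stopifnot(item_id >= 1, nrow(pixels) >= 1)
  structure(list(item_id = as.integer(item_id),
                 pixels = cbind(as.integer(pixels[, 1]),
                                as.integer(pixels[, 2]))),
            class = "mv_seed_stroke")
}

#' Seeded region growing and merging
#'
#' Each seed stroke is grown by a color-similarity flood (4-connected): a
#' pixel joins a region when its Lab color is within `tau_grow` of the
#' region's seed mean color. Pixels reachable by several regions go to the
#' closest in color. Adjacent regions whose mean colors differ by less than
#' `tau_merge` are then merged iteratively. Unclaimed pixels are background.
#' The result is invariant to stroke pixel order, and growth is keyed to the
#' fixed seed mean (not a running mean), which keeps it deterministic.
#'
#' @param image `array(H, W, 3)` in `[0, 1]`.
#' @param seeds list of [seed_stroke()] with distinct `item_id`s; strokes for
#'   different items must not overlap.
#' @param tau_grow Lab distance threshold for growth (default 20; the
#'   synthetic textures stay well inside it while distinct foods are far
#'   outside).
#' @param tau_merge Lab distance threshold for merging adjacent regions
#'   (default 12).
#' @return integer label matrix (`0` background, labels relabeled 1..N) with
#'   attributes `item_ids` (original item id per label) and `merged`.
#' @export
region_grow_merge <- function(image, seeds, tau_grow = 20, tau_merge = 12) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (length(seeds) < 1) stop("need at least one seed stroke")
  ids <- vapply(seeds, function(s) s$item_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate item_ids in seed strokes")
  occ <- matrix(0L, H, W)
  for (s in seeds) {
    if (any(s$pixels[, 1] < 1 | s$pixels[, 1] > W |
            s$pixels[, 2] < 1 | s$pixels[, 2] > H)) {
      stop("seed stroke for item ", s$item_id, " leaves the image")
    }
    lin <- (s$pixels[, 1] - 1L) * H + s$pixels[, 2]
    clash <- occ[lin] != 0L & occ[lin] != s$item_id
    if (any(clash)) {
      stop("overlapping seed strokes: items ",
           paste(unique(c(occ[lin][clash], s$item_id)), collapse = ", "))
    }
    occ[lin] <- s$item_id
  }
  lab <- image_lab(image)
  n_px <- H * W
  # region index per pixel (0 none); seeds fixed to their own region
  reg <- matrix(0L, H, W)
  seed_mean <- matrix(0, length(seeds), 3)
  for (i in seq_along(seeds)) {
    s <- seeds[[i]]
    lin <- (s$pixels[, 1] - 1L) * H + s$pixels[, 2]
    reg[lin] <- i
    seed_mean[i, ] <- colMeans(lab[lin, , drop = FALSE])
  }
  seed_only <- reg
  # synchronous flood from the seeds: a pixel joins the nearest (in color)
  # adjacent region whose reference mean is within tau
  flood <- function(ref_mean, tau) {
    dist_to <- sapply(seq_len(nrow(ref_mean)), function(i) {
      sqrt((lab[, 1] - ref_mean[i, 1])^2 + (lab[, 2] - ref_mean[i, 2])^2 +
             (lab[, 3] - ref_mean[i, 3])^2)
    })
    dist_to <- matrix(dist_to, n_px)
    eligible <- dist_to < tau  # strict: tau = 0 grows nothing
    reg <- seed_only
    repeat {
      cand_reg <- matrix(0L, H, W)
      cand_d <- matrix(Inf, H, W)
      consider <- function(rows_to, cols_to, rows_from, cols_from) {
        nb <- matrix(0L, H, W)
        nb[rows_to, cols_to] <- reg[rows_from, cols_from]
        sel <- which(reg == 0L & nb > 0L)
        sel <- sel[eligible[cbind(sel, nb[sel])]]
        if (!length(sel)) return(invisible())
        d <- dist_to[cbind(sel, nb[sel])]
        better <- d < cand_d[sel]
        cand_reg[sel[better]] <<- nb[sel][better]
        cand_d[sel[better]] <<- d[better]
        invisible()
      }
      consider(2:H, 1:W, 1:(H - 1), 1:W)
      consider(1:(H - 1), 1:W, 2:H, 1:W)
      consider(1:H, 2:W, 1:H, 1:(W - 1))
      consider(1:H, 1:(W - 1), 1:H, 2:W)
      newly <- cand_reg > 0L
      if (!any(newly)) break
      reg[newly] <- cand_reg[newly]
    }
    reg
  }
  # two-stage growth: a conservative half-threshold flood harvests each
  # item's core, whose mean is a far better color reference than the few
  # stroke pixels; the full-threshold flood then restarts from the seeds
  # against the core means
  core <- flood(seed_mean, tau_grow / 2)
  core_mean <- t(vapply(seq_along(seeds), function(i) {
    colMeans(lab[which(core == i), , drop = FALSE])
  }, numeric(3)))
  reg <- flood(core_mean, tau_grow)
  # boundary competition: an unclaimed pixel bordering a region joins it if
  # its color is closer to the (full) region mean than to the background
  # mean — this claims the mixed boundary pixels an anti-aliased camera
  # produces, without moving the growth threshold. Gated by 2 * tau_grow so
  # the degenerate tau_grow = 0 contract (seeds only) is preserved.
  if (tau_grow > 0 && max(reg) > 0) {
    for (pass in 1:1) {
      n_reg <- max(reg)
      reg_mean <- t(vapply(seq_len(n_reg), function(i) {
        colMeans(lab[which(reg == i), , drop = FALSE])
      }, numeric(3)))
      unc <- which(reg == 0L)
      if (!length(unc)) break
      bg_mean <- colMeans(lab[unc, , drop = FALSE])
      cand_reg <- matrix(0L, H, W); cand_d <- matrix(Inf, H, W)
      nb <- function(rows_to, cols_to, rows_from, cols_from) {
        nbm <- matrix(0L, H, W)
        nbm[rows_to, cols_to] <- reg[rows_from, cols_from]
        sel <- which(reg == 0L & nbm > 0L)
        if (!length(sel)) return(invisible())
        d_reg <- sqrt(rowSums((lab[sel, , drop = FALSE] -
                                 reg_mean[nbm[sel], , drop = FALSE])^2))
        d_bg <- sqrt(rowSums(sweep(lab[sel, , drop = FALSE], 2, bg_mean)^2))
        ok <- d_reg < 0.8 * d_bg & d_reg < 2 * tau_grow
        sel <- sel[ok]; d_reg <- d_reg[ok]
        better <- d_reg < cand_d[sel]
        cand_reg[sel[better]] <<- nbm[sel][better]
        cand_d[sel[better]] <<- d_reg[better]
        invisible()
      }
      nb(2:H, 1:W, 1:(H - 1), 1:W)
      nb(1:(H - 1), 1:W, 2:H, 1:W)
      nb(1:H, 2:W, 1:H, 1:(W - 1))
      nb(1:H, 1:(W - 1), 1:H, 2:W)
      newly <- cand_reg > 0L
      if (!any(newly)) break
      reg[newly] <- cand_reg[newly]
    }
  }

  # merge adjacent regions with similar mean colors
  merged_pairs <- list()
  repeat {
    nreg <- max(reg)
    if (nreg < 2) break
    means <- t(vapply(seq_len(nreg), function(i) {
      colMeans(lab[which(reg == i), , drop = FALSE])
    }, numeric(3)))
    adj <- matrix(FALSE, nreg, nreg)
    mark_adj <- function(a, b) {
      sel <- a > 0L & b > 0L & a != b
      if (any(sel)) {
        pr <- unique(cbind(a[sel], b[sel]))
        adj[pr] <<- TRUE; adj[pr[, 2:1, drop = FALSE]] <<- TRUE
      }
    }
    mark_adj(reg[-1, ], reg[-H, ])
    mark_adj(reg[, -1], reg[, -W])
    dd <- as.matrix(stats::dist(means))
    dd[!adj] <- Inf
    if (min(dd) >= tau_merge) break
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    keep <- min(ij); drop <- max(ij)
    merged_pairs[[length(merged_pairs) + 1]] <- c(ids[keep], ids[drop])
    reg[reg == drop] <- keep
    reg[reg > drop] <- reg[reg > drop] - 1L
    ids[keep] <- min(ids[keep], ids[drop])
    ids <- ids[-drop]
  }
  structure(reg, item_ids = ids, merged = merged_pairs)
}

#' Automatic (class-agnostic) segmentation via a pluggable backend
#'
#' Deliberately class-agnostic, mirroring a detector used purely for
#' instance masks. Backends are functions `image -> integer label matrix`;
#' the built-in fallback clusters Lab colors (k-means with deterministic
#' initialization), calls the cluster dominating the image border
#' "background", splits the rest into 4-connected components and drops tiny
#' ones. Any backend output is relabeled contiguously 1..N.
#'
#' @param image `array(H, W, 3)` in `[0, 1]`.
#' @param backend `NULL` for the fallback, or a function of the image.
#' @param k number of color clusters for the fallback.
#' @param min_area_px minimum component area kept.
#' @return integer label matrix, labels 1..N, 0 background.
#' @export
auto_segment <- function(image, backend = NULL, k = 4, min_area_px = 30) {
  if (!is.null(backend)) {
    nm <- deparse(substitute(backend))
    out <- tryCatch(backend(image), error = function(e) {
      stop("segmentation backend '", nm, "' failed: ", conditionMessage(e))
    })
    return(relabel_map(out))
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  lab <- image_lab(image)
  uniq <- unique(round(lab, 4))
  k_eff <- min(k, nrow(uniq))
  if (k_eff < 2) return(relabel_map(matrix(0L, H, W)))
  # deterministic init: spread centers over the luminance order
  ord <- order(uniq[, 1], uniq[, 2], uniq[, 3])
  centers <- uniq[ord[round(seq(1, nrow(uniq), length.out = k_eff))], ,
                  drop = FALSE]
  km <- suppressWarnings(stats::kmeans(lab, centers = centers,
                                       iter.max = 50))
  cl <- matrix(km$cluster, H, W)
  border <- c(cl[1, ], cl[H, ], cl[, 1], cl[, W])
  bg <- as.integer(names(which.max(table(border))))
  fg <- cl != bg
  comp <- connected_components(fg)
  sizes <- tabulate(comp[comp > 0])
  small <- which(sizes < min_area_px)
  comp[comp %in% small] <- 0L
  relabel_map(comp)
}

#' Normalize a label image to contiguous labels 1..N
#' @param labels integer matrix, 0 = background.
#' @return integer matrix with the same zero set and labels 1..N.
#' @export
relabel_map <- function(labels) {
  m <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  pos <- m > 0L
  if (any(pos)) m[pos] <- as.integer(factor(m[pos]))
  m
}

#' Segmentation F-scores: Fmin and Fsum
#'
#' Predicted items are matched one-to-one to ground-truth items by greedy
#' maximum pixel overlap. Each matched pair gets an F-score (harmonic mean
#' of pixel precision and recall); unmatched truth items score 0. `Fmin` is
#' the minimum per-item F over truth items; `Fsum` is the class-agnostic F
#' of all food pixels pooled (so unmatched predicted items count as
#' precision errors there).
#'
#' @param pred,truth integer label matrices of the same size; `truth` must
#'   contain at least one item.
#' @return named numeric vector `c(Fmin =, Fsum =)`, both in `[0, 1]`.
#' @export
fscore_min_sum <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("pred/truth size mismatch")
  nt <- max(truth)
  if (nt < 1) stop("truth has no items")
  np <- max(pred)
  f_item <- numeric(nt)
  if (np >= 1) {
    ov <- table(factor(pred[pred > 0 & truth > 0],
                       levels = seq_len(np)),
                factor(truth[pred > 0 & truth > 0], levels = seq_len(nt)))
    ov <- matrix(as.numeric(ov), np, nt)
    psz <- tabulate(pred[pred > 0], np)
    tsz <- tabulate(truth[truth > 0], nt)
    repeat {
      if (all(ov <= 0)) break
      ij <- which(ov == max(ov), arr.ind = TRUE)[1, ]
      tp <- ov[ij[1], ij[2]]
      f_item[ij[2]] <- 2 * tp / (psz[ij[1]] + tsz[ij[2]])
      ov[ij[1], ] <- -1
      ov[, ij[2]] <- -1
    }
  }
  tp <- sum(pred > 0 & truth > 0)
  fp <- sum(pred > 0 & truth == 0)
  fn <- sum(pred == 0 & truth > 0)
  fsum <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(Fmin = min(f_item), Fsum = fsum)
}

#' Seed strokes JSON I/O
#'
#' Strokes are stored as a JSON list of objects `{item_id, pixels: [[u,v],...]}`.
#' @param seeds list of [seed_stroke()].
#' @param path file path.
#' @return `read_seeds` returns a list of [seed_stroke()].
#' @export
write_seeds <- function(seeds, path) {
  jsonlite::write_json(lapply(seeds, function(s) {
    list(item_id = s$item_id, pixels = unname(apply(s$pixels, 1, as.list)))
  }), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    seed_stroke(s$item_id,
                do.call(rbind, lapply(s$pixels, function(p) unlist(p))))
  })
}
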