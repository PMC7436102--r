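# Hierarchical recognition: shared feature backbone + three parallel
# softmax heads (fine, hyper2, hyper1), joint cross-entropy training with
# plain SGD, weighted inference with hyper-category fallback, and top-k
# evaluation.

#' Default desk-scale feature backbone
#'
#' A fixed (untrained) feature extractor standing in for a deep backbone:
#' per-channel means over a `grid x grid` spatial partition plus global
#' per-channel mean and standard deviation. Linear heads over these
#' features separate color/texture families well, which is all the
#' synthetic classification set requires.
#'
#' @param grid spatial partition size (default 2).
#' @return object of class `mv_backbone`: `extract(images)` returning an
#'   N x d feature matrix, and `dim`.
#' @export
default_backbone <- function(grid = 2L) {
  extract_one <- function(img) {
    H <- dim(img)[1]; W <- dim(img)[2]
    ri <- pmin(grid, ceiling(seq_len(H) / (H / grid)))
    ci <- pmin(grid, ceiling(seq_len(W) / (W / grid)))
    f <- numeric(0)
    for (ch in 1:3) {
      m <- img[, , ch]
      f <- c(f, as.numeric(tapply(m, list(ri[row(m)], ci[col(m)]), mean)))
    }
    gm <- vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
    gs <- vapply(1:3, function(ch) stats::sd(img[, , ch]), numeric(1))
    # fixed input normalization (a constant affine layer, not data
    # statistics): image means live near 0.45 on [0,1]; rescaling puts the
    # features on a unit-ish scale so the fixed SGD recipe (lr 1e-2) moves
    # the logits at a useful rate
    (c(f, gm, gs) - 0.4) * 6
  }
  structure(list(extract = function(images) {
    t(vapply(images, extract_one, numeric(3 * grid^2 + 6)))
  }, dim = 3L * grid^2 + 6L), class = "mv_backbone")
}

#' Build the three-head hierarchical classifier
#'
#' One shared backbone feeding three parallel linear-softmax heads sized to
#' the taxonomy's level cardinalities (fine, hyper2, hyper1) — the
#' "replace the final layer by three parallel recognition layers" design.
#' Weights start at zero, so an untrained model outputs uniform
#' probabilities and forward passes are deterministic.
#'
#' @param taxonomy an `mv_taxonomy`.
#' @param backbone an `mv_backbone` (default [default_backbone()]).
#' @return object of class `mv_hier_model`.
#' @export
build_model <- function(taxonomy, backbone = default_backbone()) {
  stopifnot(inherits(taxonomy, "mv_taxonomy"))
  sizes <- taxonomy_sizes(taxonomy)
  W <- lapply(sizes, function(k) matrix(0, backbone$dim + 1L, k))
  structure(list(taxonomy = taxonomy, backbone = backbone, W = W,
                 level_names = names(sizes)), class = "mv_hier_model")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Per-level class probabilities for a batch of images
#'
#' @param model an `mv_hier_model`.
#' @param images list of `array(H, W, 3)` images.
#' @param center_crop crop each image to its central square first (the
#'   single-crop evaluation protocol).
#' @return list of three probability matrices (fine, hyper2, hyper1), rows
#'   summing to 1.
#' @export
predict_probs <- function(model, images, center_crop = FALSE) {
  if (center_crop) images <- lapply(images, crop_center_square)
  F <- model$backbone$extract(images)
  X <- cbind(1, F)
  lapply(model$W, function(w) softmax_rows(X %*% w))
}

crop_center_square <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- min(H, W)
  r0 <- (H - s) %/% 2; c0 <- (W - s) %/% 2
  img[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), , drop = FALSE]
}

label_indices <- function(taxonomy, labels) {
  lv <- taxonomy$levels
  idx <- list(fine = match(labels$fine, lv$fine),
              hyper2 = match(labels$hyper2, lv$hyper2),
              hyper1 = match(labels$hyper1, lv$hyper1))
  for (nm in names(idx)) {
    if (anyNA(idx[[nm]])) {
      bad <- unique(labels[[nm]][is.na(idx[[nm]])])
      stop("label(s) outside the taxonomy at level ", nm, ": ",
           paste(bad, collapse = ", "))
    }
  }
  idx
}

#' Train the hierarchical classifier with SGD
#'
#' Joint loss: weighted sum of the three per-level cross-entropies (equal
#' weights by default). Optimizer and schedule follow the published recipe:
#' plain stochastic gradient descent, learning rate 1e-2, batch size 32,
#' 20 epochs. An augmentation hook (list of image transforms applied to
#' each training image every epoch) is supported; runs are reproducible
#' under a fixed seed.
#'
#' @param model an `mv_hier_model` from [build_model()].
#' @param dataset list with `images` and `labels` (data.frame with fine,
#'   hyper2, hyper1) as produced by [make_classification_set()].
#' @param lr learning rate (default 1e-2).
#' @param batch_size default 32.
#' @param epochs default 20.
#' @param level_weights loss weights for (fine, hyper2, hyper1).
#' @param augment list of functions `image -> image`, applied in order.
#' @param seed RNG seed for shuffling (and stochastic transforms).
#' @return the trained model, with a `history` data.frame (per-epoch loss
#'   and per-level accuracy) attached.
#' @export
train_model <- function(model, dataset, lr = 1e-2, batch_size = 32,
                        epochs = 20, level_weights = c(1, 1, 1),
                        augment = list(), seed = 1L) {
  idx <- label_indices(model$taxonomy, dataset$labels)  # errors early
  n <- length(dataset$images)
  stopifnot(n >= 1)
  sizes <- taxonomy_sizes(model$taxonomy)
  Y <- lapply(seq_along(sizes), function(l) {
    y <- matrix(0, n, sizes[l])
    y[cbind(seq_len(n), idx[[l]])] <- 1
    y
  })
  static_feats <- if (!length(augment)) {
    cbind(1, model$backbone$extract(dataset$images))
  }
  hist <- vector("list", epochs)
  with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      X <- if (is.null(static_feats)) {
        imgs <- dataset$images
        for (f in augment) imgs <- lapply(imgs, f)
        cbind(1, model$backbone$extract(imgs))
      } else static_feats
      ep_loss <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1, n)]
        Xb <- X[bi, , drop = FALSE]
        m <- length(bi)
        for (l in seq_along(model$W)) {
          if (level_weights[l] == 0) next
          P <- softmax_rows(Xb %*% model$W[[l]])
          Yb <- Y[[l]][bi, , drop = FALSE]
          ep_loss <- ep_loss - level_weights[l] *
            sum(log(pmax(P[Yb > 0], 1e-300)))
          G <- crossprod(Xb, P - Yb) / m
          model$W[[l]] <- model$W[[l]] - lr * level_weights[l] * G
        }
      }
      probs <- lapply(model$W, function(w) softmax_rows(X %*% w))
      acc <- vapply(seq_along(probs), function(l) {
        mean(max.col(probs[[l]], ties.method = "first") == idx[[l]])
      }, numeric(1))
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                               acc_fine = acc[1], acc_hyper2 = acc[2],
                               acc_hyper1 = acc[3])
    }
  })
  model$history <- do.call(rbind, hist)
  model
}

#' Weighted inference over the three level predictions
#'
#' Each level's confidence is its weight times its maximum softmax
#' probability; the level with the highest weighted confidence provides the
#' final tag. If the fine-grained maximum probability falls below
#' `fallback_threshold`, the fine level is excluded before the comparison,
#' so an unknown fine-grained food still yields a correct hyper category.
#' The fallback test uses the unweighted probability, which keeps the rule
#' invariant to rescaling all weights. Ties break toward the finer level.
#'
#' @param probs list of three probability vectors (fine, hyper2, hyper1).
#' @param level_weights non-negative weights, not all zero (default uniform).
#' @param fallback_threshold fine-grained probability below which the fine
#'   level is skipped (default 0.5).
#' @param taxonomy optional `mv_taxonomy` used to attach category names.
#' @return object of class `mv_recognition`: per-level `argmax`,
#'   `confidence` (weighted), `chosen_level`, `chosen_index`,
#'   `chosen_label` (if taxonomy given), `chosen_confidence`.
#' @export
weighted_inference <- function(probs, level_weights = c(1, 1, 1),
                               fallback_threshold = 0.5, taxonomy = NULL) {
  stopifnot(length(probs) == 3)
  if (any(level_weights < 0) || all(level_weights == 0)) {
    stop("level_weights must be non-negative and not all zero")
  }
  for (p in probs) {
    if (abs(sum(p) - 1) > 1e-6) stop("probability vector does not sum to 1")
  }
  amax <- vapply(probs, which.max, integer(1))
  pmaxv <- vapply(probs, max, numeric(1))
  conf <- level_weights * pmaxv
  allowed <- c(pmaxv[1] >= fallback_threshold, TRUE, TRUE)
  cand <- which(allowed)
  # ties break toward the finer level: levels are ordered fine, hyper2,
  # hyper1, so the first maximum wins
  chosen <- cand[which.max(conf[cand])]
  label <- if (!is.null(taxonomy)) {
    taxonomy$levels[[chosen]][amax[chosen]]
  }
  structure(list(probs = probs, argmax = amax,
                 confidence = conf,
                 level_weights = level_weights,
                 fallback_threshold = fallback_threshold,
                 chosen_level = c("fine", "hyper2", "hyper1")[chosen],
                 chosen_index = amax[chosen],
                 chosen_label = label,
                 chosen_confidence = conf[chosen]),
            class = "mv_recognition")
}

#' Top-k accuracy per taxonomy level
#'
#' Single center-crop evaluation: each image is cropped to its central
#' square, classified once, and per-level top-1 and top-k hit rates are
#' reported. Ties in the score ordering are broken at random (seed the RNG
#' for reproducibility).
#'
#' @param model an `mv_hier_model`.
#' @param dataset list with `images` and three-level `labels`.
#' @param k the k of top-k (>= 1).
#' @return data.frame with columns level, top1, topk.
#' @export
topk_accuracy <- function(model, dataset, k = 3) {
  if (k < 1) stop("k must be >= 1")
  idx <- label_indices(model$taxonomy, dataset$labels)
  probs <- predict_probs(model, dataset$images, center_crop = TRUE)
  res <- lapply(seq_along(probs), function(l) {
    P <- probs[[l]]
    nc <- ncol(P)
    hits1 <- hitsk <- logical(nrow(P))
    for (i in seq_len(nrow(P))) {
      ord <- order(P[i, ], stats::runif(nc), decreasing = TRUE)
      hits1[i] <- ord[1] == idx[[l]][i]
      hitsk[i] <- idx[[l]][i] %in% ord[seq_len(min(k, nc))]
    }
    data.frame(level = c("fine", "hyper2", "hyper1")[l],
               top1 = mean(hits1), topk = mean(hitsk))
  })
  out <- do.call(rbind, res)
  attr(out, "k") <- k
  out
}

#' Save / load a trained model as JSON
#'
#' Checkpoints store the taxonomy table and the three head weight matrices;
#' the backbone is reconstructed by name (only the built-in grid-statistics
#' backbone is serializable).
#'
#' @param model an `mv_hier_model`.
#' @param path checkpoint path (JSON).
#' @return `load_model` returns an `mv_hier_model`.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(list(
    taxonomy = model$taxonomy$table,
    weights = lapply(model$W, function(w) unclass(as.data.frame(w))),
    backbone_dim = model$backbone$dim
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tax <- as_taxonomy(raw$taxonomy)
  grid <- as.integer(sqrt((raw$backbone_dim - 6) / 3))
  model <- build_model(tax, default_backbone(grid))
  model$W <- lapply(raw$weights, function(w) as.matrix(as.data.frame(w)))
  for (i in seq_along(model$W)) dimnames(model$W[[i]]) <- NULL
  model
}
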