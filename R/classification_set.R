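#' Generate a labeled synthetic classification set
#'
#' Stands in for web-collected food photographs at desk scale: every
#' fine-grained category of the taxonomy is assigned a distinct base color
#' and texture family, and images are noisy textured patches drawn from that
#' family. At high signal-to-noise the classes are linearly separable in mean
#' color, so a linear-head classifier must reach high training accuracy —
#' which is what the training smoke test checks. Labels carry the full
#' three-level path (hyper1, hyper2, fine).
#'
#' @param taxonomy an [load_taxonomy()] result with >= 2 fine classes.
#' @param n_per_class images per fine-grained class (>= 1).
#' @param seed integer; fixes all randomness.
#' @param size image side length, px.
#' @param noise_sigma per-pixel Gaussian noise (0 = clean).
#' @return list with `images` (list of `array(size, size, 3)`), `labels`
#'   (data.frame with columns fine, hyper2, hyper1).
#' @export
make_classification_set <- function(taxonomy, n_per_class, seed = 1L,
                                    size = 24L, noise_sigma = 0.02) {
  stopifnot(inherits(taxonomy, "mv_taxonomy"))
  classes <- taxonomy$table$fine
  if (length(classes) < 2) stop("taxonomy must have >= 2 fine-grained classes")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  with_seed(as.integer(seed), {
    images <- list()
    rows <- list()
    g <- expand.grid(v = seq_len(size), u = seq_len(size))
    for (ci in seq_along(classes)) {
      base <- class_base_color(ci)
      for (j in seq_len(n_per_class)) {
        off <- stats::runif(2, 0, 1000)
        alb <- textured_albedo(g$u * 2 + off[1], g$v * 2 + off[2], base,
                               seed = ci * 131 + 7, amp = 0.18, cell = 9)
        if (noise_sigma > 0) {
          alb[] <- pmin(1, pmax(0, alb + stats::rnorm(length(alb), 0,
                                                      noise_sigma)))
        }
        img <- array(0, c(size, size, 3))
        for (ch in 1:3) img[, , ch] <- matrix(alb[, ch], size, size)
        images[[length(images) + 1]] <- img
        rows[[length(rows) + 1]] <- taxonomy$table[ci, c("fine", "hyper2",
                                                         "hyper1")]
      }
    }
    list(images = images, labels = do.call(rbind, rows))
  })
}
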