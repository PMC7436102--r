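#' Sample a random meal scene specification
#'
#' Draws 1-3 food solids with shapes and sizes typical of plated servings
#' (mounds, patties, slabs, domes; footprints 40-120 mm, heights 12-35 mm,
#' volumes roughly 30-250 ml) placed on non-overlapping slots beside the
#' reference card. Used by the Monte-Carlo accuracy and baseline-ordering
#' experiments; every draw is reproducible from the seed.
#'
#' @param seed integer RNG seed.
#' @param n_solids number of items (default: drawn from 1-3).
#' @param views,K,noise_sigma,supersample forwarded to [scene_spec()].
#' @return an `mv_scene_spec`.
#' @export
sample_scene_spec <- function(seed, n_solids = NULL,
                              views = list(view_at(90), view_at(75)),
                              K = default_intrinsics(), noise_sigma = 0,
                              supersample = 1L) {
  with_seed(as.integer(seed), {
    if (is.null(n_solids)) n_solids <- sample(1:3, 1)
    stopifnot(n_solids >= 1, n_solids <= 3)
    slots <- list(c(-50, 90), c(50, 100), c(0, 135))[sample(1:3, n_solids)]
    kinds <- sample(c("spherical_cap", "cylinder", "cuboid",
                      "half_ellipsoid"), n_solids, replace = TRUE)
    solids <- lapply(seq_len(n_solids), function(i) {
      ctr <- slots[[i]] + stats::runif(2, -8, 8)
      p <- switch(kinds[i],
        spherical_cap = {
          r <- stats::runif(1, 40, 60)
          list(r = r, h = stats::runif(1, 0.4, 0.6) * r * 0.8)
        },
        cylinder = list(r = stats::runif(1, 20, 34),
                        h = stats::runif(1, 12, 28)),
        cuboid = list(lx = stats::runif(1, 35, 58),
                      ly = stats::runif(1, 35, 58),
                      lz = stats::runif(1, 12, 30)),
        half_ellipsoid = list(a = stats::runif(1, 26, 42),
                              b = stats::runif(1, 26, 42),
                              c = stats::runif(1, 15, 32)))
      food_solid(kinds[i], p, base_center = ctr,
                 label = paste0("item_", i),
                 texture_seed = sample.int(1000, 1))
    })
    scene_spec(solids, views = views, K = K, noise_sigma = noise_sigma,
               supersample = supersample)
  })
}
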