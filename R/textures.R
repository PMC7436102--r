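# Procedural value-noise textures. Deterministic given (coords, seed): the
# lattice values come from a sine-fract hash, interpolated with a quintic
# smoothstep, so every surface point has a reproducible albedo with enough
# local contrast for block matching.

hash01 <- function(ix, iy, seed) {
  s <- sin(ix * 127.1 + iy * 311.7 + seed * 74.7) * 43758.5453123
  s - floor(s)
}

smootherstep <- function(t) t * t * t * (t * (t * 6 - 15) + 10)

# Single octave of 2D value noise at scale `cell` (mm per lattice cell).
value_noise <- function(x, y, seed, cell) {
  gx <- x / cell; gy <- y / cell
  ix <- floor(gx); iy <- floor(gy)
  fx <- smootherstep(gx - ix); fy <- smootherstep(gy - iy)
  v00 <- hash01(ix, iy, seed);     v10 <- hash01(ix + 1, iy, seed)
  v01 <- hash01(ix, iy + 1, seed); v11 <- hash01(ix + 1, iy + 1, seed)
  a <- v00 + (v10 - v00) * fx
  b <- v01 + (v11 - v01) * fx
  a + (b - a) * fy
}

# Two-octave fractal noise in [0, 1]; coarse structure plus fine detail so
# NCC windows at the working resolution always see gradient.
fractal_noise <- function(x, y, seed, cell = 14) {
  (2 * value_noise(x, y, seed, cell) +
     value_noise(x, y, seed + 57, cell / 3.7)) / 3
}

# Albedo of a textured surface: base color plus achromatic (gray) noise.
# Additive luminance modulation gives the block matcher full contrast while
# moving the color only along L*, so the chroma separation that drives the
# segmenter is preserved. `amp` is the peak-to-peak luminance modulation.
textured_albedo <- function(x, y, base_rgb, seed, amp = 0.2, cell = 14) {
  n <- fractal_noise(x, y, seed, cell)
  m <- amp * (n - 0.5)
  cbind(pmin(1, pmax(0, base_rgb[1] + m)),
        pmin(1, pmax(0, base_rgb[2] + m)),
        pmin(1, pmax(0, base_rgb[3] + m)))
}

# Distinct, well-separated base colors for food classes; cycles with altered
# lightness after 10 hues.
class_base_color <- function(k) {
  # saturated hues kept far (Delta-E >= ~40) from the brown table so the
  # color-distance segmenter's growth threshold separates food from
  # background by construction
  hues <- matrix(c(
    0.80, 0.22, 0.18,  # tomato red
    0.25, 0.58, 0.20,  # pea green
    0.76, 0.64, 0.16,  # corn yellow
    0.45, 0.25, 0.62,  # eggplant purple
    0.18, 0.38, 0.75,  # blueberry
    0.85, 0.48, 0.12,  # roast orange
    0.10, 0.62, 0.58,  # teal herb
    0.78, 0.22, 0.55,  # beet magenta
    0.25, 0.80, 0.45,  # pea-shoot green
    0.60, 0.78, 0.08   # chartreuse
  ), ncol = 3, byrow = TRUE)
  i <- (k - 1) %% nrow(hues) + 1
  shade <- 0.85 + 0.15 * ((k - 1) %/% nrow(hues) %% 2)
  pmin(hues[i, ] * shade + 0.03, 0.78)
}
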