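#' Parametric food solid resting on the table plane
#'
#' Food items are modelled as simple solids sitting on the table (z = 0):
#' spherical caps (mounds of rice, puree), cylinders (patties, cakes),
#' cuboids (lasagna, bread) and half ellipsoids (dome-shaped servings). Each
#' has a closed-form volume, an analytic height field and an exact
#' ray-intersection routine, which is what makes synthetic scenes usable as
#' ground truth.
#'
#' @param shape_kind one of `"spherical_cap"`, `"cylinder"`, `"cuboid"`,
#'   `"half_ellipsoid"`.
#' @param shape_params named list of lengths in mm:
#'   spherical_cap `r` (radius of curvature) and `h` (cap height, `h <= r`);
#'   cylinder `r`, `h`; cuboid `lx`, `ly`, `lz`; half_ellipsoid semi-axes
#'   `a`, `b`, `c` (`c` vertical).
#' @param base_center length-2 position of the footprint center on the table
#'   plane, mm.
#' @param label fine-grained food category name.
#' @param color optional RGB base color (defaults to a palette keyed by
#'   `texture_seed`).
#' @param texture_seed integer controlling the procedural surface texture.
#' @return An object of class `mv_food_solid`.
#' @export
food_solid <- function(shape_kind, shape_params, base_center = c(0, 0),
                       label = "food", color = NULL, texture_seed = 1) {
  shape_kind <- match.arg(shape_kind,
                          c("spherical_cap", "cylinder", "cuboid",
                            "half_ellipsoid"))
  p <- shape_params
  need <- switch(shape_kind,
                 spherical_cap = c("r", "h"),
                 cylinder = c("r", "h"),
                 cuboid = c("lx", "ly", "lz"),
                 half_ellipsoid = c("a", "b", "c"))
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("solid '", label, "': missing shape parameter(s) ",
         paste(missing, collapse = ", "))
  }
  vals <- unlist(p[need])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("solid '", label, "': all shape parameters must be positive lengths")
  }
  if (shape_kind == "spherical_cap" && p$h > p$r + 1e-9) {
    stop("solid '", label, "': cap height h must not exceed radius r")
  }
  if (is.null(color)) color <- class_base_color(texture_seed)
  structure(list(shape_kind = shape_kind, shape_params = p,
                 base_center = as.numeric(base_center), label = label,
                 color = as.numeric(color),
                 texture_seed = as.integer(texture_seed)),
            class = "mv_food_solid")
}

#' Closed-form volume of a food solid, in ml
#'
#' Spherical cap: `pi h^2 (3r - h) / 3`; cylinder `pi r^2 h`; cuboid
#' `lx ly lz`; half ellipsoid `2/3 pi a b c`. 1 ml = 1000 mm^3.
#' @param solid an [food_solid()].
#' @return volume in millilitres.
#' @export
analytic_volume_ml <- function(solid) {
  p <- solid$shape_params
  mm3 <- switch(solid$shape_kind,
    spherical_cap = pi * p$h^2 * (3 * p$r - p$h) / 3,
    cylinder = pi * p$r^2 * p$h,
    cuboid = p$lx * p$ly * p$lz,
    half_ellipsoid = 2 / 3 * pi * p$a * p$b * p$c)
  mm3 / 1000
}

#' Analytic height field of a solid over the table plane
#' @param solid an [food_solid()].
#' @param x,y vectors of table-plane coordinates, mm.
#' @return heights in mm (0 outside the footprint).
#' @export
solid_height <- function(solid, x, y) {
  p <- solid$shape_params
  dx <- x - solid$base_center[1]
  dy <- y - solid$base_center[2]
  switch(solid$shape_kind,
    spherical_cap = {
      rho2 <- dx^2 + dy^2
      zc <- p$h - p$r  # sphere center height (non-positive)
      rim2 <- p$r^2 - zc^2
      h <- ifelse(rho2 <= rim2, zc + sqrt(pmax(0, p$r^2 - rho2)), 0)
      pmax(0, h)
    },
    cylinder = ifelse(dx^2 + dy^2 <= p$r^2, p$h, 0),
    cuboid = ifelse(abs(dx) <= p$lx / 2 & abs(dy) <= p$ly / 2, p$lz, 0),
    half_ellipsoid = {
      q <- pmax(0, 1 - (dx / p$a)^2 - (dy / p$b)^2)
      p$c * sqrt(q)
    })
}

# Smallest positive root of A s^2 + B s + C = 0 satisfying a predicate on s;
# all arguments vectors. Returns Inf where there is no valid root.
.quad_first_root <- function(A, B, C, valid_fn) {
  disc <- B^2 - 4 * A * C
  s <- rep(Inf, length(B))
  ok <- disc >= 0 & A > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    s1 <- (-B[ok] - sq) / (2 * A[ok])
    s2 <- (-B[ok] + sq) / (2 * A[ok])
    v1 <- s1 > 1e-9 & valid_fn(s1, ok)
    v2 <- s2 > 1e-9 & valid_fn(s2, ok)
    pick <- ifelse(v1, s1, ifelse(v2, s2, Inf))
    s[ok] <- pick
  }
  s
}

# Exact ray/solid intersection. C: camera center (3), D: N x 3 world ray
# directions. Returns the ray parameter of the first hit (Inf = miss);
# surfaces below the table plane are never hit (solids rest on z = 0).
solid_ray_intersect <- function(solid, C, D) {
  p <- solid$shape_params
  x0 <- solid$base_center[1]; y0 <- solid$base_center[2]
  n <- nrow(D)
  zs <- function(s, idx) C[3] + s * D[idx, 3]

  if (solid$shape_kind == "spherical_cap") {
    ctr <- c(x0, y0, p$h - p$r)
    oc <- sweep(matrix(C, n, 3, byrow = TRUE), 2, ctr)
    A <- rowSums(D^2)
    B <- 2 * rowSums(D * oc)
    Cc <- rowSums(oc^2) - p$r^2
    return(.quad_first_root(A, B, Cc, function(s, idx) zs(s, idx) >= -1e-9))
  }

  if (solid$shape_kind == "half_ellipsoid") {
    sc <- c(p$a, p$b, p$c)
    o <- (C - c(x0, y0, 0)) / sc
    Ds <- sweep(D, 2, sc, "/")
    A <- rowSums(Ds^2)
    B <- 2 * (Ds %*% o)[, 1]
    Cc <- sum(o^2) - 1
    return(.quad_first_root(A, B, Cc, function(s, idx) zs(s, idx) >= -1e-9))
  }

  if (solid$shape_kind == "cylinder") {
    ox <- C[1] - x0; oy <- C[2] - y0
    A <- D[, 1]^2 + D[, 2]^2
    B <- 2 * (ox * D[, 1] + oy * D[, 2])
    Cc <- ox^2 + oy^2 - p$r^2
    side <- .quad_first_root(A, B, rep(Cc, n), function(s, idx) {
      z <- zs(s, idx); z >= -1e-9 & z <= p$h + 1e-9
    })
    s_top <- ifelse(abs(D[, 3]) > 1e-12, (p$h - C[3]) / D[, 3], Inf)
    px <- C[1] + s_top * D[, 1] - x0
    py <- C[2] + s_top * D[, 2] - y0
    top_ok <- is.finite(s_top) & s_top > 1e-9 & (px^2 + py^2 <= p$r^2)
    s_top[!top_ok] <- Inf
    return(pmin(side, s_top))
  }

  # cuboid: axis-aligned slab intersection over x, y slabs and z in [0, lz]
  lo <- c(x0 - p$lx / 2, y0 - p$ly / 2, 0)
  hi <- c(x0 + p$lx / 2, y0 + p$ly / 2, p$lz)
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  for (ax in 1:3) {
    d <- D[, ax]
    t1 <- (lo[ax] - C[ax]) / d
    t2 <- (hi[ax] - C[ax]) / d
    par <- abs(d) < 1e-12
    tl <- pmin(t1, t2); th <- pmax(t1, t2)
    inside <- C[ax] >= lo[ax] && C[ax] <= hi[ax]
    tl[par] <- if (inside) -Inf else Inf
    th[par] <- if (inside) Inf else -Inf
    tmin <- pmax(tmin, tl); tmax <- pmin(tmax, th)
  }
  hit <- tmin <= tmax & tmax > 1e-9
  s <- ifelse(hit, ifelse(tmin > 1e-9, tmin, tmax), Inf)
  s
}
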