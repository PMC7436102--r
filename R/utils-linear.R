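# Small 3D linear-algebra helpers shared by the geometry and rendering code.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Rotation about the z axis (right-handed, angle in radians).
rot_z <- function(phi) {
  c0 <- cos(phi); s0 <- sin(phi)
  matrix(c(c0, -s0, 0, s0, c0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Minimal rotation taking unit vector a onto unit vector b (Rodrigues).
# Errors if a and b are anti-parallel: the rotation is then not unique.
rotation_between <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  v <- cross3(a, b)
  c0 <- sum(a * b)
  if (c0 < -1 + 1e-10) {
    stop("rotation_between: vectors are anti-parallel, rotation is ambiguous")
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

# Nearest rotation matrix (Frobenius) via SVD; fixes det = +1.
orthonormalize_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

# Angle (degrees) between two rotations: magnitude of the residual rotation.
rotation_angle_deg <- function(R1, R2) {
  Rr <- t(R1) %*% R2
  c0 <- (sum(diag(Rr)) - 1) / 2
  rad2deg(acos(max(-1, min(1, c0))))
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < tol
}
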