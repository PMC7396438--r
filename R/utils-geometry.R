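## Internal geometry helpers: quaternions, dihedrals, internal-coordinate
## atom placement and sphere point sets. All angles in degrees at the API
## boundary, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternions are stored as \code{c(qw, qx, qy, qz)} with unit norm.
#'
#' @param q numeric length-4 unit quaternion.
#' @return 3x3 rotation matrix.
#' @export
quatToMatrix <- function(q) {
  stopifnot(length(q) == 4L)
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-6) stop("quaternion is not unit norm")
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

## axis (unit 3-vector), angle in degrees -> quaternion
axisAngleToQuat <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg) / 2
  u <- vunit(axis)
  q <- c(cos(a), sin(a) * u)
  if (q[1L] < 0) q <- -q
  q
}

#' Seeded uniform random unit quaternions
#'
#' Draws quaternions uniformly on the 3-sphere (normalised 4-variate
#' Gaussians), deterministic for a given seed; no global RNG state is
#' touched.
#'
#' @param n number of quaternions.
#' @param seed integer seed.
#' @return n x 4 matrix, rows \code{c(qw,qx,qy,qz)}, \code{qw >= 0}.
#' @export
randomQuaternions <- function(n, seed) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed), {
    m <- matrix(stats::rnorm(4L * n), ncol = 4L)
  })
  m <- m / sqrt(rowSums(m^2))
  flip <- m[, 1L] < 0
  m[flip, ] <- -m[flip, ]
  colnames(m) <- c("qw", "qx", "qy", "qz")
  m
}

## Signed torsion angle (degrees, IUPAC convention) defined by four points.
## Returns NA for degenerate (collinear) geometry.
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

## Natural-extension (NeRF) placement: position of atom d given the three
## preceding atoms and internal coordinates bond |cd|, angle b-c-d (deg),
## torsion a-b-c-d (deg).
placeAtom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  b2 <- vunit(c_ - b)
  n <- vunit(vcross(b - a, b2))
  m <- vcross(n, b2)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c_ + b2 * d2[1L] + m * d2[2L] + n * d2[3L]
}

## Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Minimum squared cross distances between two coordinate matrices.
crossDist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
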