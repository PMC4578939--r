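# Small geometry kernels shared across modules. All coordinates in nm unless
# a function's name or argument says otherwise.

#' Pairwise squared distances between two coordinate sets
#'
#' @param a,b numeric matrices with 3 columns (x, y, z).
#' @return matrix of squared distances, nrow(a) x nrow(b).
#' @keywords internal
dist2_cross <- function(a, b) {
  # |a|^2 + |b|^2 - 2 a.b, clamped at 0 against roundoff
  aa <- rowSums(a * a)
  bb <- rowSums(b * b)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Signed torsion angle for four points (IUPAC convention)
#'
#' Returns the angle in degrees in (-180, 180]. Cis (eclipsed) is 0, trans
#' is 180; the sign follows the right-hand rule about the b-c axis.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @keywords internal
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Angle at vertex b for points a-b-c, in degrees
#' @keywords internal
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Place a fourth atom from three reference atoms and internal coordinates
#'
#' Natural-extension (NeRF) placement: given positions a, b, c, returns the
#' position d with |c-d| = bond, angle b-c-d = angle_deg and torsion
#' a-b-c-d = torsion_deg.
#'
#' @param a,b,c numeric 3-vectors.
#' @param bond bond length (nm).
#' @param angle_deg bond angle at c (degrees).
#' @param torsion_deg torsion about b-c (degrees).
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  d_local <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n * n))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  c(rot %*% d_local) + c
}
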