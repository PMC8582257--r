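# Low-level vector geometry used by the internal-coordinate engine.
# All angles in degrees, distances in Angstrom.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  a / n
}

#' Angle between three points
#'
#' Valence angle at \code{b} spanned by \code{a} and \code{c}, in degrees.
#' @param a,b,c Numeric xyz vectors.
#' @return Angle in degrees within [0, 180].
#' @keywords internal
angle_points <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * .rad2deg
}

#' Signed dihedral of four points
#'
#' IUPAC convention: cis = 0, sign by the right-hand rule about the b->c axis;
#' invariant under reversal of the four points.
#' @param a,b,c,d Numeric xyz vectors.
#' @return Signed angle in degrees within (-180, 180].
#' @keywords internal
dihedral_points <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("undefined torsion: collinear reference atoms", call. = FALSE)
  }
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * .rad2deg
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle difference into (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Place atom X from references C (distance), B (angle vertex partner) and A
# (torsion reference): |X - C| = d, angle(X, C, B) = theta,
# dihedral(X, C, B, A) = phi. Classic internal-to-Cartesian step.
place_nerf <- function(A, B, C, d, theta, phi) {
  th <- theta * .deg2rad
  ph <- phi * .deg2rad
  bc <- vunit(C - B)
  n <- vcross(B - A, bc)
  if (vnorm(n) < 1e-10) {
    stop("collinear torsion reference atoms: frame undefined", call. = FALSE)
  }
  n <- vunit(n)
  m <- vcross(n, bc)
  d_local <- c(-d * cos(th), d * sin(th) * cos(ph), -d * sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Reflect point x through the plane spanned by p1, p2, p3.
reflect_point <- function(x, p1, p2, p3) {
  n <- vcross(p2 - p1, p3 - p1)
  if (vnorm(n) < 1e-10) {
    stop("collinear plane definition", call. = FALSE)
  }
  n <- vunit(n)
  x - 2 * sum((x - p1) * n) * n
}
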