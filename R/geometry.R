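## Internal vector geometry: distances, angles, dihedrals.
## Angles are returned in degrees; dihedrals lie in (-180, 180].

vnorm <- function(v) sqrt(sum(v * v))

dist_points <- function(a, b) vnorm(b - a)

# angle a-b-c at vertex b, degrees
angle_points <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-10 || nv < 1e-10) abort("undefined angle: coincident points")
  cosang <- sum(u * v) / (nu * nv)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

# dihedral a-b-c-d about axis b-c, degrees in (-180, 180]
dihedral_points <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    abort("undefined dihedral: collinear points")
  }
  m1 <- pracma::cross(n1, b2 / vnorm(b2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}
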