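# Internal-coordinate atom placement and rigid transforms.

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame: returns the position of a new atom D
#' given three placed atoms, so that |D - a| = `bond`, the angle D-a-b is
#' `angle` and the dihedral D-a-b-c is `dihedral` (both in degrees).
#'
#' @param a,b,c Numeric length-3 positions (a is the bonded parent).
#' @param bond Bond length in Angstrom.
#' @param angle Bond angle D-a-b in degrees.
#' @param dihedral Dihedral D-a-b-c in degrees.
#' @return Numeric length-3 position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  ab <- a - b
  bc <- b - c
  n <- vcross(bc, ab)
  if (sum(n^2) < 1e-12) stop("collinear reference atoms in place_atom")
  n <- n / sqrt(sum(n^2))
  u_ab <- ab / sqrt(sum(ab^2))
  m <- vcross(n, u_ab)
  # local displacement: along -u_ab rotated by (pi - angle), torsion dihedral
  d2 <- bond * sin(ang)
  a + u_ab * (-bond * cos(ang)) + m * (d2 * cos(dih)) + n * (d2 * sin(dih))
}

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rotation matrix about a coordinate axis
#' @param axis "x", "y" or "z".
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 rotation matrix (determinant +1).
#' @keywords internal
rotation_matrix <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3))
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# measured dihedral for testing/template checks, degrees in (-180, 180]
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}
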