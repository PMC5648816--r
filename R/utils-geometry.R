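# Small 3D geometry helpers shared across modules. All angles in degrees at
# the interface, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

unitize <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#' @param axis 3-vector (need not be unit length)
#' @param angle_deg rotation angle, degrees, right-handed about `axis`
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# z-y-z Euler rotation: R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma), degrees.
euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  }
  ry <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
  }
  rz(deg2rad(alpha)) %*% ry(deg2rad(beta)) %*% rz(deg2rad(gamma))
}

# Inverse of euler_zyz: angles (degrees) from a rotation matrix.
euler_from_matrix <- function(R) {
  beta <- acos(min(1, max(-1, R[3, 3])))
  if (abs(sin(beta)) < 1e-9) {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  rad2deg(c(alpha, beta, gamma))
}

# Place atom D given positions A, B, C, the bond length |D-C|, the angle
# B-C-D and the dihedral A-B-C-D (natural extension reference frame).
nerf_place <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ang <- deg2rad(angle_deg)
  dih <- deg2rad(dihedral_deg)
  bc <- unitize(C - B)
  n <- unitize(vcross(B - A, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitize(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

bond_angle <- function(A, B, C) {
  u <- unitize(A - B); v <- unitize(C - B)
  rad2deg(acos(min(1, max(-1, sum(u * v)))))
}
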