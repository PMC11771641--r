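# Low-level rigid-body geometry: rotations, superposition, dihedrals.
# All coordinates are in angstrom; angles at this level are radians unless
# a function name says degrees.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation about `axis` (need not be unit length) by `theta`
#' radians, right-handed.
#'
#' @param axis numeric length-3 axis vector.
#' @param theta rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, theta) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rot_z <- function(theta) rotation_about(c(0, 0, 1), theta)
rot_y <- function(theta) rotation_about(c(0, 1, 0), theta)
rot_x <- function(theta) rotation_about(c(1, 0, 0), theta)

# Signed angle from a to b about reference direction ref (radians).
signed_angle <- function(a, b, ref) {
  atan2(sum(cross3(a, b) * ref), sum(a * b))
}

# Wrap degrees into (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% t(src) + t` onto `dst`. Rows are atoms.
#'
#' @param src,dst n x 3 coordinate matrices, matched rows.
#' @return list with `R` (3x3, proper rotation), `t` (length 3), and `rmsd`.
#' @keywords internal
kabsch <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  A <- sweep(src, 2, cs)
  B <- sweep(dst, 2, cd)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cd - as.numeric(R %*% cs)
  fit <- t(R %*% t(src)) + matrix(tvec, nrow(src), 3, byrow = TRUE)
  list(R = R, t = tvec, rmsd = sqrt(mean(rowSums((fit - dst)^2))))
}

# Signed dihedral a-b-c-d in degrees, IUPAC convention.
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  wrap_deg(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# Place atom D given atoms A-B-C, bond length |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg). Standard internal-coordinate (Z-matrix) placement.
place_atom_internal <- function(a, b, c, dist, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- dist * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Distance from point p to segment [a, b].
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-20) return(vnorm(p - a))
  t0 <- max(0, min(1, sum((p - a) * ab) / len2))
  vnorm(p - (a + t0 * ab))
}

# Random proper rotation (uniform via QR of gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
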