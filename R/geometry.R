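# Internal-coordinate geometry: atom placement (natural-extension reference
# frame), torsion measurement, rigid transforms, rotation sampling.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle in degrees to (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Place an atom from internal coordinates
#'
#' Places atom D given three reference atoms A, B, C so that `|D - C| = bond`,
#' the angle B-C-D equals `angle` and the torsion A-B-C-D equals `torsion`
#' (degrees, IUPAC sign convention).
#'
#' @param a,b,c Numeric xyz coordinates of the three reference atoms.
#' @param bond Bond length C-D in Angstrom.
#' @param angle Bond angle B-C-D in degrees.
#' @param torsion Torsion A-B-C-D in degrees.
#' @return Numeric xyz of the placed atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)                      # orthonormal frame (bc, m, n)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Measure a torsion angle
#'
#' Signed dihedral of four points in degrees, in (-180, 180], IUPAC sign
#' convention (clockwise rotation of d relative to a, looking b to c, is
#' positive).
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates.
#' @return Torsion angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("collinear points: torsion undefined")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit(b2))
  wrap_angle(rad2deg(atan2(y, x)))
}

# --- rigid transforms -------------------------------------------------------

#' Create a rigid-body transform
#'
#' @param R 3x3 proper rotation matrix.
#' @param t Length-3 translation vector (Angstrom).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("R must be a proper orthonormal rotation")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @param xyz n x 3 matrix.
#' @param tf A [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  sweep(xyz %*% t(tf$R), 2, tf$t, "+")
}

compose_transform <- function(tf2, tf1) {
  # apply tf1 first, then tf2
  rigid_transform(tf2$R %*% tf1$R, as.numeric(tf2$R %*% tf1$t) + tf2$t)
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation (Shoemake quaternion method); consumes 3 runif draws.
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_rotation(q)
}

quat_to_rotation <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
           2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
           2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# --- superposition ----------------------------------------------------------

#' Kabsch optimal-superposition RMSD
#'
#' Least-squares RMSD between two ordered point sets after optimal rigid
#' superposition (proper rotation only; reflections are excluded).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3, rows in correspondence.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have equal dimensions")
  if (nrow(a) < 3) stop("need at least 3 points")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rot <- bc %*% R
  sqrt(mean(rowSums((ac - rot)^2)))
}

#' Direct (no-refit) ligand RMSD
#'
#' Root-mean-square deviation between two conformers of the same ligand in a
#' shared receptor frame, without superposition.  This is the per-pose
#' `rmsd_to_reference` used when docking keeps the receptor fixed.
#'
#' @param pose_xyz,reference_xyz n x 3 matrices in the same frame.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose_xyz, reference_xyz) {
  a <- as.matrix(pose_xyz); b <- as.matrix(reference_xyz)
  if (!all(dim(a) == dim(b)))
    stop("pose and reference must have the same number of atoms")
  sqrt(mean(rowSums((a - b)^2)))
}
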