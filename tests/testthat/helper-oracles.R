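# Independent oracles and shared fixtures for the test suite.

# Torsion by an independent route (projection formula with explicit acos and
# sign from the scalar triple product), distinct from the atan2 path used by
# the package.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(n1 * b3) < 0) ang <- -ang
  ang
}

# Independent placement of the fourth atom of a torsion using rotation
# matrices composed explicitly (Rodrigues), not the package's local frame.
oracle_fourth_atom <- function(a, b, c, bond, angle, torsion) {
  rot <- function(u, th) {
    u <- u / sqrt(sum(u^2)); K <- matrix(c(0, u[3], -u[2],
                                           -u[3], 0, u[1],
                                           u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  cb <- (b - c) / sqrt(sum((b - c)^2))
  d0 <- c + bond * cb                       # along c->b, then bend and twist
  ab <- b - a
  n <- ab - sum(ab * cb) * cb               # reference perpendicular
  n <- n / sqrt(sum(n^2))
  ax1 <- c(cb[2] * n[3] - cb[3] * n[2],
           cb[3] * n[1] - cb[1] * n[3],
           cb[1] * n[2] - cb[2] * n[1])
  d1 <- c + rot(ax1, angle * pi / 180) %*% (d0 - c)
  c + as.numeric(rot(cb, -(torsion + 180) * pi / 180) %*% (d1 - c))
}

# Brute-force intermolecular energy: plain double loop in R.
oracle_pair_energy <- function(lxyz, rxyz, lff, rff, cutoff = 12, diel = 4) {
  evdw <- 0; eelec <- 0
  for (i in seq_len(nrow(lxyz))) {
    for (j in seq_len(nrow(rxyz))) {
      d2 <- sum((lxyz[i, ] - rxyz[j, ])^2)
      if (d2 >= cutoff^2) next
      s <- (lff$sigma[i] + rff$sigma[j]) / 2
      e <- sqrt(lff$eps[i] * rff$eps[j])
      s6 <- (s^2 / d2)^3
      evdw <- evdw + 4 * e * (s6^2 - s6)
      eelec <- eelec + 332.0636 * lff$q[i] * rff$q[j] / (diel * d2)
    }
  }
  list(E_vdw = evdw, E_elec = eelec)
}

# Least-squares plane fit; returns max |distance| of the points to the plane.
oracle_plane_deviation <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  n <- svd(c0)$v[, 3]
  max(abs(c0 %*% n))
}

# A tiny structure with arbitrary atoms, for synthetic scoring tests.
fake_structure <- function(xyz, elems, resname = "GLY", atom = NULL, q = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(
    atom = if (is.null(atom)) paste0(elems, seq_len(n)) else atom,
    resno = seq_len(n), resname = resname, chain = "A", elem = elems,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  scaadock:::new_peptide(atoms, paste(rep("G", n), collapse = ""), "A")
}

# The 18 natural superantigen variants: FKLIXTYKZ with X = L/T/P (P5),
# Y = T/K/P (P7), Z = L/G (P9).
superantigen_variants <- function() {
  out <- character(0)
  for (x in c("L", "T", "P")) for (y in c("T", "K", "P")) for (z in c("L", "G"))
    out <- c(out, paste0("FKLI", x, "T", y, "K", z))
  out
}

# Shared planted fixture (built once per test run; construction is
# deterministic).
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$fx))
    fixture_env$fx <- make_planted_complex(c("Q", "V", "H"), seed = 1L)
  fixture_env$fx
}
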