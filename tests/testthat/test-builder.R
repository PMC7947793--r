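# Internal-coordinate peptide construction.

test_that("torsion measurement handles canonical arrangements", {
  a <- c(1, 1, 0); b <- c(1, 0, 0); c3 <- c(2, 0, 0)
  expect_equal(measure_dihedral(a, b, c3, c(2, 1, 0)), 0)      # cis
  expect_equal(measure_dihedral(a, b, c3, c(2, -1, 0)), 180)   # trans
  d90 <- oracle_fourth_atom(a, b, c3, 1.2, 109, 90)
  expect_equal(measure_dihedral(a, b, c3, d90), 90, tolerance = 1e-9)
  expect_error(measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("atom placement agrees with an independent construction", {
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(3); b <- a + rnorm(3); c3 <- b + rnorm(3)
    bond <- runif(1, 1, 2); ang <- runif(1, 60, 150); tor <- runif(1, -179, 180)
    d <- place_atom(a, b, c3, bond, ang, tor)
    expect_equal(sqrt(sum((d - c3)^2)), bond, tolerance = 1e-9)
    expect_equal(measure_dihedral(a, b, c3, d), tor, tolerance = 1e-9)
    expect_equal(oracle_dihedral(a, b, c3, d), tor, tolerance = 1e-6)
  }
})

test_that("trans tri-glycine has the canonical 3.80 A CA-CA spacing", {
  # independent oracle: place CA' from CA, C, N by the explicit
  # rotation-matrix construction and take the distance
  k <- backbone_constants()
  ca <- c(0, 0, 0)
  cc <- c(k[["b_CA_C"]], 0, 0)
  nn <- as.numeric(oracle_fourth_atom(c(0, 1, 0), ca, cc, k[["b_C_N"]],
                                      k[["a_CA_C_N"]], 137))  # psi arbitrary
  ca2 <- as.numeric(oracle_fourth_atom(ca, cc, nn, k[["b_N_CA"]],
                                       k[["a_C_N_CA"]], 180))  # omega trans
  d_expected <- sqrt(sum((ca2 - ca)^2))
  expect_equal(d_expected, 3.80, tolerance = 0.01)
  p <- build_backbone("GGG", dihedral_table(3))
  ca_xyz <- coords(p, "CA")
  expect_equal(sqrt(sum((ca_xyz[2, ] - ca_xyz[1, ])^2)), d_expected,
               tolerance = 1e-9)
  expect_equal(sqrt(sum((ca_xyz[3, ] - ca_xyz[2, ])^2)), d_expected,
               tolerance = 1e-9)
})

test_that("phi/psi of the built chain round-trip the inputs", {
  dt <- dihedral_table(5, phi = -139, psi = 135)
  m <- measure_phi_psi(build_backbone("GAGAG", dt))
  expect_equal(m$phi[2:5], rep(-139, 4), tolerance = 1e-3)
  expect_equal(m$psi[1:4], rep(135, 4), tolerance = 1e-3)
  # property: random dihedral tables round-trip too
  set.seed(21)
  for (i in 1:10) {
    dt <- dihedral_table(6, phi = runif(6, -179, 179), psi = runif(6, -179, 179))
    m <- measure_phi_psi(build_backbone("AAAAAA", dt))
    expect_equal(m$phi[-1], dt$phi[-1], tolerance = 1e-3)
    expect_equal(m$psi[-6], dt$psi[-6], tolerance = 1e-3)
  }
})

test_that("bond lengths equal the geometry constants exactly", {
  k <- backbone_constants()
  p1 <- build_backbone("A", dihedral_table(1))
  at <- p1$atoms
  g <- function(nm) unlist(at[at$atom == nm, c("x", "y", "z")])
  expect_equal(sqrt(sum((g("CA") - g("N"))^2)), unname(k[["b_N_CA"]]))
  expect_equal(sqrt(sum((g("C") - g("CA"))^2)), unname(k[["b_CA_C"]]),
               tolerance = 1e-12)
  expect_equal(sqrt(sum((g("CB") - g("CA"))^2)), unname(k[["b_CA_CB"]]),
               tolerance = 1e-12)
  # inter-residue C-N and all bonds under arbitrary dihedrals
  p <- build_backbone("AGA", dihedral_table(3, phi = -77, psi = 44))
  at <- p$atoms
  gg <- function(i, nm) unlist(at[at$resno == i & at$atom == nm,
                                  c("x", "y", "z")])
  for (i in 1:2)
    expect_equal(sqrt(sum((gg(i + 1, "N") - gg(i, "C"))^2)),
                 unname(k[["b_C_N"]]), tolerance = 1e-6)
  for (i in 1:3)
    expect_equal(sqrt(sum((gg(i, "O") - gg(i, "C"))^2)),
                 unname(k[["b_C_O"]]), tolerance = 1e-12)
})

test_that("all non-glycine residues are built as L enantiomers", {
  p <- attach_sidechains(build_backbone("ACDEFHIKLMNPQRSTVWY",
                                        dihedral_table(19)))
  at <- p$atoms
  for (i in unique(at$resno)) {
    r <- at[at$resno == i, ]
    if (!"CB" %in% r$atom) next
    g <- function(nm) unlist(r[r$atom == nm, c("x", "y", "z")])
    expect_lt(measure_dihedral(g("N"), g("CA"), g("C"), g("CB")), 0)
  }
})

test_that("side chains carry the expected atoms and geometry", {
  p <- attach_sidechains(build_backbone("GVY", dihedral_table(3)))
  at <- p$atoms
  expect_identical(at$atom[at$resno == 1], c("N", "CA", "C", "O"))  # glycine
  expect_setequal(at$atom[at$resno == 2],
                  c("N", "CA", "C", "O", "CB", "CG1", "CG2"))
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")
  expect_true(all(ring %in% at$atom[at$resno == 3]))
  # tyrosine ring planarity against a least-squares plane fit
  rxyz <- as.matrix(at[at$resno == 3 & at$atom %in% ring, c("x", "y", "z")])
  expect_lt(oracle_plane_deviation(rxyz), 0.01)
  expect_error(attach_sidechains(
    fake_structure(diag(3), c("N", "C", "C"), resname = "XXX")), "XXX")
})

test_that("library peptides share one rigid backbone scaffold", {
  p1 <- build_library_peptide(c("V", "V", "V"))
  expect_identical(p1$sequence, "GGVGVGGVG")
  p2 <- build_library_peptide(c("Q", "Y", "H"))
  bb <- c("N", "CA", "C", "O")
  xyz1 <- coords(p1, bb); xyz2 <- coords(p2, bb)
  expect_equal(ligand_rmsd(xyz1, xyz2), 0)
  # sidechain atom budget: only the three triad residues go beyond CB
  beyond <- p2$atoms[!p2$atoms$atom %in% c(bb, "CB"), ]
  expect_setequal(unique(beyond$resno), c(3L, 5L, 8L))
  expect_error(build_library_peptide(c("A", "V", "V")), "SCAA")
})

test_that("construction is a deterministic function of sequence and dihedrals", {
  a <- build_library_peptide(c("S", "Y", "D"))
  b <- build_library_peptide(c("S", "Y", "D"))
  expect_identical(a$atoms, b$atoms)
})

test_that("dihedral tables validate length and read from CSV", {
  expect_error(build_backbone("AAA", dihedral_table(4)), "3 residues")
  expect_error(build_backbone("AAX", dihedral_table(3)), "X")
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(position = 1:4, phi = -60, psi = -45),
                   tmp, row.names = FALSE)
  dt <- dihedral_table(file = tmp)
  expect_identical(nrow(dt), 4L)
  expect_equal(dt$omega, rep(180, 4))
})
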