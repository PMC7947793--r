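# Ideal-geometry constants (Engh-Huber-style), sidechain internal-coordinate
# templates, the default rotamer policy and the simplified force field.
# All lengths in Angstrom, angles/torsions in degrees, energies kcal/mol.

#' Canonical backbone geometry constants
#'
#' Ideal bond lengths and angles used by the internal-coordinate builder.
#' Override individual entries via the `constants` argument of
#' [build_backbone()].
#'
#' @return Named numeric vector of lengths (Angstrom) and angles (degrees).
#' @export
backbone_constants <- function() {
  c(b_N_CA  = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
    b_CA_CB = 1.530,
    a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
    a_CA_C_O = 120.8, a_N_CA_CB = 110.5,
    # torsion C-N-CA-CB fixing the L configuration of the side chain
    t_CB = -122.6)
}

AA_321 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
            H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
            P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
            W = "TRP", Y = "TYR")

# Sidechain templates: one row per heavy atom beyond CB, placed by
# place_atom(a, b, c, bond, angle, torsion).  Torsions are strings evaluated
# against the chi vector of the rotamer policy ("chi1", "chi2+180", "0", ...).
sc_atom <- function(name, a, b, c, bond, angle, torsion) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       torsion = torsion)
}

SIDECHAIN_ZMAT <- list(
  GLY = list(),
  ALA = list(),
  SER = list(sc_atom("OG",  "N",  "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = list(sc_atom("SG",  "N",  "CA", "CB", 1.808, 113.8, "chi1")),
  THR = list(sc_atom("OG1", "N",  "CA", "CB", 1.433, 109.6, "chi1"),
             sc_atom("CG2", "OG1", "CA", "CB", 1.521, 110.5, "-122.3")),
  VAL = list(sc_atom("CG1", "N",  "CA", "CB", 1.521, 110.5, "chi1"),
             sc_atom("CG2", "CG1", "CA", "CB", 1.521, 110.5, "122.3")),
  ILE = list(sc_atom("CG1", "N",  "CA", "CB", 1.530, 110.4, "chi1"),
             sc_atom("CG2", "CG1", "CA", "CB", 1.521, 110.5, "-122.3"),
             sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  LEU = list(sc_atom("CG",  "N",  "CA", "CB", 1.530, 116.3, "chi1"),
             sc_atom("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
             sc_atom("CD2", "CD1", "CB", "CG", 1.521, 110.7, "122.5")),
  MET = list(sc_atom("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
             sc_atom("SD",  "CA", "CB", "CG", 1.803, 112.7, "chi2"),
             sc_atom("CE",  "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  PRO = list(sc_atom("CG",  "N",  "CA", "CB", 1.492, 104.5, "chi1"),
             sc_atom("CD",  "CA", "CB", "CG", 1.503, 106.1, "chi2")),
  ASP = list(sc_atom("CG",  "N",  "CA", "CB", 1.516, 112.6, "chi1"),
             sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
             sc_atom("OD2", "OD1", "CB", "CG", 1.249, 118.4, "180")),
  ASN = list(sc_atom("CG",  "N",  "CA", "CB", 1.516, 112.6, "chi1"),
             sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             sc_atom("ND2", "OD1", "CB", "CG", 1.328, 116.4, "180")),
  GLU = list(sc_atom("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
             sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
             sc_atom("OE2", "OE1", "CG", "CD", 1.249, 118.4, "180")),
  GLN = list(sc_atom("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
             sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             sc_atom("NE2", "OE1", "CG", "CD", 1.328, 116.4, "180")),
  LYS = list(sc_atom("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             sc_atom("CE",  "CB", "CG", "CD", 1.520, 111.3, "chi3"),
             sc_atom("NZ",  "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = list(sc_atom("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             sc_atom("NE",  "CB", "CG", "CD", 1.461, 112.0, "chi3"),
             sc_atom("CZ",  "CG", "CD", "NE", 1.329, 124.2, "chi4"),
             sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
             sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
  # Histidine: built as the doubly N-protonated (+1) tautomer; heavy atoms
  # only, protonation carried as metadata.  Planar ring (all in-ring torsions
  # 0/180), approximate closure.
  HIS = list(sc_atom("CG",  "N",  "CA", "CB", 1.497, 113.8, "chi1"),
             sc_atom("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi2"),
             sc_atom("CD2", "ND1", "CB", "CG", 1.354, 131.2, "180"),
             sc_atom("CE1", "CB", "CG", "ND1", 1.321, 109.3, "180"),
             sc_atom("NE2", "CB", "CG", "CD2", 1.374, 107.2, "180")),
  # Aromatic six-rings: uniform 1.39 A / 120 deg so the hexagon closes
  # exactly and is exactly planar.
  PHE = list(sc_atom("CG",  "N",  "CA", "CB", 1.502, 113.8, "chi1"),
             sc_atom("CD1", "CA", "CB", "CG", 1.390, 120.0, "chi2"),
             sc_atom("CD2", "CA", "CB", "CG", 1.390, 120.0, "chi2+180"),
             sc_atom("CE1", "CB", "CG", "CD1", 1.390, 120.0, "180"),
             sc_atom("CE2", "CB", "CG", "CD2", 1.390, 120.0, "180"),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, "0")),
  TYR = list(sc_atom("CG",  "N",  "CA", "CB", 1.502, 113.8, "chi1"),
             sc_atom("CD1", "CA", "CB", "CG", 1.390, 120.0, "chi2"),
             sc_atom("CD2", "CA", "CB", "CG", 1.390, 120.0, "chi2+180"),
             sc_atom("CE1", "CB", "CG", "CD1", 1.390, 120.0, "180"),
             sc_atom("CE2", "CB", "CG", "CD2", 1.390, 120.0, "180"),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, "0"),
             sc_atom("OH",  "CD1", "CE1", "CZ", 1.376, 120.0, "180")),
  TRP = list(sc_atom("CG",  "N",  "CA", "CB", 1.498, 113.6, "chi1"),
             sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
             sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.8, "chi2+180"),
             sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
             sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
             sc_atom("CE3", "CB", "CG", "CD2", 1.398, 126.0, "0"),
             sc_atom("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
             sc_atom("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
             sc_atom("CH2", "CD2", "CE3", "CZ3", 1.368, 121.1, "0"))
)

# Most-common rotamer per residue (coarse, one entry per chi); chi defaults
# to 180 where a residue needs more angles than listed.
ROTAMER_CHI <- list(
  SER = 64, CYS = -65, THR = 62, VAL = 175,
  ILE = c(-65, 170), LEU = c(-65, 175), MET = c(-67, 180, 75),
  PRO = c(30, -35),
  ASP = c(-70, -15), ASN = c(-65, -65),
  GLU = c(-67, 180, -10), GLN = c(-67, 180, -25),
  LYS = c(-67, 180, 180, 180), ARG = c(-67, 180, 65, 85),
  HIS = c(-65, -70), PHE = c(-65, 90), TYR = c(-65, 90), TRP = c(-65, 95)
)

# --- simplified force field -------------------------------------------------

# Per-element-class 12-6 Lennard-Jones parameters (sigma form:
# E = 4 eps [(sigma/r)^12 - (sigma/r)^6]).  Radii are ~6% below typical
# liquid-simulation values: rigid ideal-geometry bodies carry no relaxation,
# so slightly reduced radii keep near-contact poses from being dominated by
# hard-core overlap.
LJ_PARAMS <- data.frame(
  elem  = c("C", "N", "O", "S"),
  eps   = c(0.10, 0.16, 0.20, 0.25),
  sigma = c(3.20, 3.05, 2.85, 3.35),
  stringsAsFactors = FALSE
)

# Coarse per-atom partial charges: a backbone dipole set plus formal charges
# spread over the terminal polar atoms of charged side chains (His is the
# doubly protonated +1 form).
BACKBONE_CHARGES <- c(N = -0.40, CA = 0.25, C = 0.55, O = -0.40)
SIDECHAIN_CHARGES <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0),
  ARG = c(NH1 = 0.5, NH2 = 0.5),
  HIS = c(ND1 = 0.5, NE2 = 0.5),
  SER = c(CB = 0.25, OG = -0.25),
  THR = c(CB = 0.25, OG1 = -0.25),
  CYS = c(CB = 0.25, SG = -0.25),
  TYR = c(CZ = 0.25, OH = -0.25),
  ASN = c(OD1 = -0.5, ND2 = 0.5),
  GLN = c(OE1 = -0.5, NE2 = 0.5)
)

COULOMB_CONST <- 332.0636  # kcal mol^-1 A e^-2

element_of <- function(atom_names) {
  substr(gsub("[0-9]", "", atom_names), 1, 1)
}
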