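# All-atom peptide construction from sequence + per-residue phi/psi/omega by
# internal-coordinate chain extension.

#' Per-position dihedral table
#'
#' One phi/psi/omega triple per template position.  The default is an
#' extended beta-like scaffold (phi = -139, psi = 135, omega = 180 at every
#' position), a stand-in for antigen scaffold dihedrals measured from a real
#' peptide-MHC complex; supply measured values via `file` (CSV with columns
#' `position, phi, psi, omega`).
#'
#' @param length Number of residues (ignored when `file` is given).
#' @param phi,psi,omega Scalar or per-position vectors, degrees.
#' @param file Optional CSV path.
#' @param provenance Free-text label recorded with the table.
#' @return A data.frame of class `dihedral_table` with columns
#'   `position, phi, psi, omega`.
#' @export
dihedral_table <- function(length = 9L, phi = -139, psi = 135, omega = 180,
                           file = NULL, provenance = "default extended scaffold") {
  if (!is.null(file)) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    need <- c("position", "phi", "psi")
    if (!all(need %in% names(df)))
      stop("dihedral file needs columns position, phi, psi (omega optional)")
    if (is.null(df$omega)) df$omega <- 180
    df <- df[order(df$position), c("position", "phi", "psi", "omega")]
    provenance <- paste0("file:", file)
  } else {
    df <- data.frame(position = seq_len(length),
                     phi = wrap_angle(rep_len(phi, length)),
                     psi = wrap_angle(rep_len(psi, length)),
                     omega = wrap_angle(rep_len(omega, length)))
  }
  structure(df, class = c("dihedral_table", "data.frame"),
            provenance = provenance)
}

new_peptide <- function(atoms, sequence, chain = "A", metadata = list()) {
  structure(list(atoms = atoms, sequence = sequence, chain = chain,
                 metadata = metadata),
            class = "peptide_structure")
}

#' @export
print.peptide_structure <- function(x, ...) {
  cat(sprintf("Peptide structure: %s (chain %s, %d residues, %d heavy atoms)\n",
              x$sequence, x$chain, nchar(x$sequence), nrow(x$atoms)))
  if (!is.null(x$metadata$triad))
    cat(sprintf("  triad: %s\n", paste(x$metadata$triad, collapse = " ")))
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#' @param structure A `peptide_structure`.
#' @param atom_names Optional atom-name filter (e.g. `"CA"`).
#' @return n x 3 numeric matrix.
#' @export
coords <- function(structure, atom_names = NULL) {
  at <- structure$atoms
  if (!is.null(atom_names)) at <- at[at$atom %in% atom_names, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Build a rigid peptide backbone from dihedrals
#'
#' Internal-coordinate chain extension: each atom is placed from a bond
#' length, bond angle and torsion relative to three previously placed atoms,
#' using canonical ideal geometry.  The first residue is placed in a fixed
#' frame (N at the origin, CA on +x, C in the xy plane), so the build is a
#' deterministic function of `(sequence, dihedrals)`.  Carbonyl O atoms are
#' placed in the peptide plane.
#'
#' @param sequence One-letter sequence string.
#' @param dihedrals A [dihedral_table()] of matching length.
#' @param chain Chain identifier for the built atoms.
#' @param constants Geometry constants, see [backbone_constants()].
#' @return A `peptide_structure` with N, CA, C, O (and CB for non-glycine)
#'   per residue.
#' @export
build_backbone <- function(sequence, dihedrals = dihedral_table(nchar(sequence)),
                           chain = "A", constants = backbone_constants()) {
  seqv <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seqv)
  if (!all(seqv %in% names(AA_321)))
    stop(sprintf("invalid residue code(s): %s",
                 paste(setdiff(seqv, names(AA_321)), collapse = ", ")))
  if (nrow(dihedrals) != n)
    stop(sprintf("dihedral table has %d rows but sequence has %d residues",
                 nrow(dihedrals), n))
  k <- constants
  rows <- vector("list", n * 5L)
  ri <- 0L
  add <- function(name, resno, xyz) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(atom = name, resno = resno,
                              resname = AA_321[[seqv[resno]]],
                              x = xyz[1], y = xyz[2], z = xyz[3],
                              stringsAsFactors = FALSE)
  }
  # residue 1 frame: N at origin, CA on +x, C in the xy plane
  Npos <- c(0, 0, 0)
  CApos <- c(k[["b_N_CA"]], 0, 0)
  ang <- deg2rad(k[["a_N_CA_C"]])
  Cpos <- CApos + k[["b_CA_C"]] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      Nnew <- place_atom(Nprev, CAprev, Cprev, k[["b_C_N"]], k[["a_CA_C_N"]],
                         dihedrals$psi[i - 1L])
      CAnew <- place_atom(CAprev, Cprev, Nnew, k[["b_N_CA"]], k[["a_C_N_CA"]],
                          dihedrals$omega[i])
      Cnew <- place_atom(Cprev, Nnew, CAnew, k[["b_CA_C"]], k[["a_N_CA_C"]],
                         dihedrals$phi[i])
      Npos <- Nnew; CApos <- CAnew; Cpos <- Cnew
    }
    add("N", i, Npos); add("CA", i, CApos); add("C", i, Cpos)
    Opos <- place_atom(Npos, CApos, Cpos, k[["b_C_O"]], k[["a_CA_C_O"]],
                       wrap_angle(dihedrals$psi[i] + 180))
    add("O", i, Opos)
    if (seqv[i] != "G") {
      CBpos <- place_atom(Cpos, Npos, CApos, k[["b_CA_CB"]], k[["a_N_CA_CB"]],
                          k[["t_CB"]])
      add("CB", i, CBpos)
    }
    Nprev <- Npos; CAprev <- CApos; Cprev <- Cpos
  }
  atoms <- do.call(rbind, rows[seq_len(ri)])
  atoms$chain <- chain
  atoms$elem <- element_of(atoms$atom)
  new_peptide(atoms[, c("atom", "resno", "resname", "chain", "elem", "x", "y", "z")],
              paste(seqv, collapse = ""), chain,
              metadata = list(dihedrals = dihedrals))
}

#' Attach ideal-geometry side chains
#'
#' Places all heavy sidechain atoms from ideal internal coordinates, with
#' chi angles taken from the rotamer policy (single most-common rotamer per
#' residue; chi = 180 where the policy has no entry).  Histidine is built as
#' the doubly N-protonated (+1) form, recorded in the structure metadata;
#' hydrogens are never built.
#'
#' @param structure A backbone `peptide_structure` (CB already present for
#'   non-glycine residues).
#' @param rotamer_policy Named list of chi vectors per 3-letter residue name;
#'   defaults to the built-in table.
#' @return The structure with sidechain atoms appended (atoms stay grouped
#'   by residue).
#' @export
attach_sidechains <- function(structure, rotamer_policy = ROTAMER_CHI) {
  at <- structure$atoms
  out <- vector("list", max(at$resno))
  for (i in sort(unique(at$resno))) {
    res <- at[at$resno == i, , drop = FALSE]
    resname <- res$resname[1]
    zmat <- SIDECHAIN_ZMAT[[resname]]
    if (is.null(zmat))
      stop(sprintf("unknown residue '%s' at position %d", resname, i))
    placed <- lapply(seq_len(nrow(res)), function(j)
      c(res$x[j], res$y[j], res$z[j]))
    names(placed) <- res$atom
    chi <- rotamer_policy[[resname]]
    get_chi <- function(m) if (length(chi) >= m) chi[m] else 180
    newrows <- list()
    for (sa in zmat) {
      tor <- sa$torsion
      if (grepl("^chi", tor)) {
        m <- as.integer(substr(tor, 4, 4))
        off <- 0
        if (grepl("\\+", tor)) off <- as.numeric(sub(".*\\+", "", tor))
        tor <- get_chi(m) + off
      } else {
        tor <- as.numeric(tor)
      }
      xyz <- place_atom(placed[[sa$a]], placed[[sa$b]], placed[[sa$c]],
                        sa$bond, sa$angle, tor)
      placed[[sa$name]] <- xyz
      newrows[[length(newrows) + 1L]] <-
        data.frame(atom = sa$name, resno = i, resname = resname,
                   chain = res$chain[1], elem = element_of(sa$name),
                   x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
    out[[i]] <- rbind(res, do.call(rbind, newrows))
  }
  structure$atoms <- do.call(rbind, out)
  rownames(structure$atoms) <- NULL
  if (grepl("H", structure$sequence))
    structure$metadata$his_protonation <- "doubly-protonated (+1)"
  structure
}

#' Build one library peptide from its SCAA triad
#'
#' Renders the triad onto the template, builds the shared rigid backbone and
#' attaches side chains.  Every library member shares the identical backbone
#' scaffold; only the three triad side chains differ.
#'
#' @param triad Three SCAA letters (P3, P5, P8 occupants).
#' @param template An [antigen_template()].
#' @param dihedrals A [dihedral_table()] of template length.
#' @param chain Chain id for the ligand (default "A").
#' @return A `peptide_structure` carrying its triad in `metadata$triad`.
#' @export
build_library_peptide <- function(triad, template = antigen_template(),
                                  dihedrals = dihedral_table(template$length),
                                  chain = "A") {
  triad <- as_triad(triad)
  if (!all(triad %in% SCAA_LETTERS))
    stop(sprintf("triad letters must be SCAA letters; got %s",
                 paste(triad, collapse = " ")))
  seqs <- render_template(triad, template)
  p <- build_backbone(seqs, dihedrals, chain = chain)
  p <- attach_sidechains(p)
  p$metadata$triad <- triad
  p$metadata$template <- template
  p
}

#' Measure the realized phi/psi of a built structure
#'
#' @param structure A `peptide_structure`.
#' @return Data.frame `position, phi, psi` (NA at chain ends where the
#'   torsion is undefined).
#' @export
measure_phi_psi <- function(structure) {
  at <- structure$atoms
  get <- function(i, nm) {
    r <- at[at$resno == i & at$atom == nm, ]
    if (nrow(r) == 0L) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  n <- max(at$resno)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L)
      phi[i] <- measure_dihedral(get(i - 1L, "C"), get(i, "N"),
                                 get(i, "CA"), get(i, "C"))
    if (i < n)
      psi[i] <- measure_dihedral(get(i, "N"), get(i, "CA"),
                                 get(i, "C"), get(i + 1L, "N"))
  }
  data.frame(position = seq_len(n), phi = phi, psi = psi)
}
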