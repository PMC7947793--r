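# Structure file I/O: PDB v3.3 ATOM records out, bio3d-backed reading in.

#' Write a structure (or pose set) as PDB
#'
#' Writes ATOM records (PDB v3.3 fixed columns, element column filled).
#' A list of structures is written as a multi-MODEL file.
#'
#' @param structure A `peptide_structure`, or a list of them for MODEL blocks.
#' @param path Output file path.
#' @param header Optional character vector of REMARK lines (text only).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("REMARK   1 %s", header), con)
  multi <- !inherits(structure, "peptide_structure")
  models <- if (multi) structure else list(structure)
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    at <- models[[m]]$atoms
    lines <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), formatC(format_atom_name(at$atom), width = 4),
      at$resname, at$chain, at$resno, at$x, at$y, at$z, 1, 0, at$elem)
    writeLines(lines, con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_name <- function(nm) {
  # PDB convention: names of <4 chars start in column 14
  ifelse(nchar(nm) >= 4, nm, paste0(" ", nm))
}

#' Read a receptor/peptide structure from PDB
#'
#' Reads a PDB v3.3 file via bio3d, keeping heavy protein atoms only:
#' waters and HETATM records are dropped, hydrogens removed, and where
#' alternate locations exist one atom per name is kept (highest occupancy,
#' ties broken toward altloc 'A').  Insertion codes are preserved.
#'
#' @param pdb_path Path to the PDB file.
#' @param chain_filter Optional character vector of chain ids; `NULL` keeps
#'   all chains.
#' @return A `peptide_structure` whose atom table carries PDB residue
#'   numbering (`resno`) as-is.
#' @export
read_structure <- function(pdb_path, chain_filter = NULL) {
  pdb <- bio3d::read.pdb(pdb_path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  at <- at[element_of(at$elety) != "H" & !grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (!is.null(chain_filter) && length(chain_filter))
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after filtering")
  # altloc resolution: one atom per (chain, resno, insert, name)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    alt <- ifelse(is.na(at$alt) | at$alt == "", "A", at$alt)
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  atoms <- data.frame(atom = at$elety, resno = at$resno, resname = at$resid,
                      chain = at$chain, elem = element_of(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      stringsAsFactors = FALSE)
  seq1 <- tryCatch({
    ca <- atoms[atoms$atom == "CA", ]
    code <- names(AA_321)[match(ca$resname, AA_321)]
    paste(ifelse(is.na(code), "X", code), collapse = "")
  }, error = function(e) "")
  new_peptide(atoms, seq1, chain = paste(unique(atoms$chain), collapse = ""),
              metadata = list(source = pdb_path))
}

check_cdr3_backbone <- function(structure, chain, range) {
  at <- structure$atoms
  missing <- character(0)
  for (r in seq(range[1], range[2])) {
    have <- at$atom[at$chain == chain & at$resno == r]
    lack <- setdiff(c("N", "CA", "C", "O"), have)
    if (length(lack))
      missing <- c(missing, sprintf("%s%d (%s)", chain, r, paste(lack, collapse = ",")))
  }
  if (length(missing))
    stop(sprintf("missing backbone atoms in CDR3 range: %s",
                 paste(missing, collapse = "; ")))
  invisible(TRUE)
}
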