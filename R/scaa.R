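#' The six-letter simplified chemical alphabet (SCAA)
#'
#' The SCAA collapses the 20 natural amino acids into six chemical-class
#' representatives: Asp (`D`, negative), Gln (`Q`, polar amide), His (`H`,
#' positive; modelled doubly protonated), Ser (`S`, polar hydroxyl), Tyr
#' (`Y`, aromatic) and Val (`V`, hydrophobic).  `scaa_table()` returns the
#' default 20-to-6 translation table shipped with the package; an alternative
#' alphabet can be supplied as a two-column CSV (`natural,scaa`).
#'
#' @param file Optional path to a CSV with columns `natural` and `scaa`.
#'   When `NULL` the packaged default alphabet is used.
#' @return An object of class `scaa_table`: a named character vector mapping
#'   each one-letter natural code to its SCAA letter, with a `class_labels`
#'   attribute naming the six chemical classes.
#' @examples
#' tab <- scaa_table()
#' tab[["R"]]   # "H": arginine is represented by (protonated) histidine
#' @export
scaa_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "scaa_alphabet.csv", package = "scaadock",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("natural", "scaa") %in% names(df)))
    stop("alphabet file must have columns 'natural' and 'scaa'")
  map <- toupper(df$scaa)
  names(map) <- toupper(df$natural)
  validate_scaa_table(map)
  attr(map, "class_labels") <- c(
    D = "negative", Q = "polar-amide", H = "positive",
    S = "polar-hydroxyl", Y = "aromatic", V = "hydrophobic")
  class(map) <- "scaa_table"
  map
}

SCAA_LETTERS <- c("D", "Q", "H", "S", "Y", "V")
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

validate_scaa_table <- function(map) {
  if (!setequal(names(map), AA1))
    stop("alphabet domain must be exactly the 20 standard one-letter codes")
  if (!all(map %in% SCAA_LETTERS))
    stop("alphabet codomain must be a subset of {D,Q,H,S,Y,V}")
  fixed <- map[SCAA_LETTERS]
  if (!all(fixed == SCAA_LETTERS))
    stop("SCAA letters must map to themselves (idempotent translation)")
  invisible(map)
}

#' @export
print.scaa_table <- function(x, ...) {
  cat("SCAA translation table (20 natural codes -> 6 classes)\n")
  labs <- attr(x, "class_labels")
  for (s in SCAA_LETTERS) {
    nat <- sort(names(x)[unclass(x) == s])
    cat(sprintf("  %s (%-14s): %s\n", s, labs[[s]], paste(nat, collapse = " ")))
  }
  invisible(x)
}

#' Translate a natural residue to its SCAA class letter
#'
#' @param residue A single one-letter natural amino-acid code.
#' @param table A [scaa_table()].
#' @return The SCAA letter of the residue's chemical class.
#' @examples
#' translate_residue("R")  # "H"
#' @export
translate_residue <- function(residue, table = scaa_table()) {
  residue <- toupper(as.character(residue))
  if (length(residue) != 1L || is.na(residue) || !nzchar(residue))
    stop("'residue' must be a single one-letter code")
  if (!residue %in% names(table))
    stop(sprintf("unknown residue code '%s' (not a standard amino acid)", residue))
  unname(unclass(table)[residue])
}

#' Translate an immunogenic triad
#'
#' Translates the three residues occupying the TCR-facing antigen positions
#' (P3, P5, P8) elementwise.
#'
#' @param triad A character vector of three one-letter natural codes, or a
#'   3-character string.
#' @inheritParams translate_residue
#' @return A character vector of three SCAA letters.
#' @examples
#' translate_triad(c("N", "V", "R"))  # Q V H
#' @export
translate_triad <- function(triad, table = scaa_table()) {
  triad <- as_triad(triad)
  vapply(seq_along(triad), function(i) {
    tryCatch(translate_residue(triad[i], table),
             error = function(e) stop(sprintf("triad position %d: %s",
                                              i, conditionMessage(e)), call. = FALSE))
  }, character(1))
}

as_triad <- function(triad) {
  if (is.character(triad) && length(triad) == 1L && nchar(triad) == 3L)
    triad <- strsplit(triad, "")[[1]]
  if (length(triad) != 3L) stop("a triad must have exactly 3 residues")
  toupper(as.character(triad))
}

#' Antigen scaffold template
#'
#' Describes the rigid antigen scaffold: a glycine backbone of fixed length
#' with variable (triad) positions facing the TCR.  The default is the
#' 9-mer `GGXGXGGXG` with the immunogenic triad at P3, P5, P8, numbered from
#' the N terminus.  Set `numbering = "C"` to interpret the triad positions
#' as counted from the C terminus instead.
#'
#' @param length Residue count (default 9).
#' @param triad_positions Integer positions of the variable residues
#'   (default `c(3, 5, 8)`).
#' @param spacer One-letter code filling non-triad positions (default `"G"`).
#' @param numbering `"N"` (positions counted from the N terminus, default)
#'   or `"C"` (from the C terminus).
#' @return An object of class `antigen_template`.
#' @examples
#' antigen_template()
#' @export
antigen_template <- function(length = 9L, triad_positions = c(3L, 5L, 8L),
                             spacer = "G", numbering = c("N", "C")) {
  numbering <- match.arg(numbering)
  length <- as.integer(length)
  pos <- as.integer(triad_positions)
  if (numbering == "C") pos <- sort(length - pos + 1L)
  if (anyDuplicated(pos) || is.unsorted(pos, strictly = TRUE) ||
      any(pos < 1L) || any(pos > length))
    stop("triad positions must be distinct, increasing and within [1, length]")
  structure(list(length = length, triad_positions = pos, spacer = toupper(spacer)),
            class = "antigen_template")
}

#' @export
print.antigen_template <- function(x, ...) {
  cat(sprintf("Antigen template: %s (triad at P%s)\n",
              render_template(c("X", "X", "X"), x),
              paste(x$triad_positions, collapse = ", P")))
  invisible(x)
}

#' Render a triad onto a template
#'
#' @param triad Three letters for the triad positions.
#' @param template An [antigen_template()].
#' @return The full peptide sequence string.
#' @export
render_template <- function(triad, template = antigen_template()) {
  triad <- as_triad(triad)
  s <- rep(template$spacer, template$length)
  s[template$triad_positions] <- triad
  paste(s, collapse = "")
}

#' Project a natural peptide onto the SCAA template
#'
#' Non-triad positions become the spacer (glycine, mimicking the
#' MHC-anchoring backbone-driven positions); triad positions are translated
#' into the SCAA.
#'
#' @param sequence A natural peptide sequence of template length.
#' @inheritParams render_template
#' @inheritParams translate_residue
#' @return The projected SCAA peptide sequence string.
#' @examples
#' project_to_template("FKLILTYKL")  # "GGVGVGGHG"
#' @export
project_to_template <- function(sequence, template = antigen_template(),
                                table = scaa_table()) {
  seqv <- strsplit(toupper(sequence), "")[[1]]
  if (length(seqv) != template$length)
    stop(sprintf("sequence length %d does not match template length %d",
                 length(seqv), template$length))
  triad <- vapply(seqv[template$triad_positions], translate_residue,
                  character(1), table = table)
  render_template(triad, template)
}

#' Deduplicated SCAA projections of a sequence collection
#'
#' @param sequences Character vector of natural sequences (template length).
#' @inheritParams project_to_template
#' @return A sorted character vector of unique SCAA peptide sequences.
#' @examples
#' unique_translated_set(c("FKLILTYKL", "FKLITTYKL", "FKLIPTYKG"))
#' @export
unique_translated_set <- function(sequences, template = antigen_template(),
                                  table = scaa_table()) {
  if (length(sequences) == 0L) return(character(0))
  sort(unique(vapply(sequences, project_to_template, character(1),
                     template = template, table = table, USE.NAMES = FALSE)))
}

#' Expand an SCAA letter back to its natural amino acids
#'
#' The inverse image of an SCAA class letter: all natural residues that the
#' alphabet collapses onto it.  The six inverse images partition the 20
#' standard codes, supporting re-expansion of a reduced library into the
#' full natural chemical space.
#'
#' @param scaa_letter One SCAA letter in `{D,Q,H,S,Y,V}`.
#' @inheritParams translate_residue
#' @return Sorted character vector of natural one-letter codes.
#' @examples
#' expand_to_natural("H")  # H K R
#' @export
expand_to_natural <- function(scaa_letter, table = scaa_table()) {
  scaa_letter <- toupper(as.character(scaa_letter))
  if (length(scaa_letter) != 1L || !scaa_letter %in% SCAA_LETTERS)
    stop(sprintf("'%s' is not an SCAA letter (expected one of %s)",
                 scaa_letter, paste(SCAA_LETTERS, collapse = ", ")))
  sort(names(table)[unclass(table) == scaa_letter])
}
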