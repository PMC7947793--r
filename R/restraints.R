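# Ambiguous interaction restraints (AIRs) anchoring the peptide to the
# CDR3-alpha/beta surface of the receptor.

#' Annotate a receptor with its CDR3 loop ranges
#'
#' @param structure A receptor `peptide_structure`.
#' @param cdr3a,cdr3b Length-2 integer vectors: first and last residue number
#'   (structure numbering) of the CDR3-alpha and CDR3-beta loops.
#' @param chain_a,chain_b Chain ids carrying the two loops.
#' @return The structure with `metadata$cdr3` set; the central residue of a
#'   loop is the lower median of its range.
#' @export
annotate_receptor <- function(structure, cdr3a, cdr3b,
                              chain_a = "R", chain_b = "S") {
  check_cdr3_backbone(structure, chain_a, cdr3a)
  check_cdr3_backbone(structure, chain_b, cdr3b)
  structure$metadata$cdr3 <- list(
    alpha = list(chain = chain_a, range = as.integer(cdr3a),
                 center = cdr3_center(cdr3a)),
    beta  = list(chain = chain_b, range = as.integer(cdr3b),
                 center = cdr3_center(cdr3b)))
  structure
}

# Central residue of a loop range: lower median on ties.
cdr3_center <- function(range) as.integer(floor((range[1] + range[2]) / 2))

#' Construct one ambiguous restraint
#'
#' @param pairs Data.frame with columns `lig_resno, lig_atom, rec_chain,
#'   rec_resno, rec_atom` — the candidate atom pairs.
#' @param lower,upper Flat-bottom bounds in Angstrom (default 4 and 8).
#' @param k Force constant, kcal mol^-1 A^-2 (default 50).
#' @param label Optional name.
#' @return Object of class `air_restraint`.
#' @export
air_restraint <- function(pairs, lower = 4, upper = 8, k = 50, label = NULL) {
  if (!(lower > 0 && lower < upper)) stop("need 0 < lower < upper")
  if (nrow(pairs) < 1L) stop("a restraint needs at least one atom pair")
  structure(list(pairs = pairs, lower = lower, upper = upper, k = k,
                 label = label), class = "air_restraint")
}

#' @export
print.air_restraint <- function(x, ...) {
  cat(sprintf("AIR %s: %d pair(s), bounds [%g, %g] A, k = %g\n",
              if (is.null(x$label)) "" else x$label, nrow(x$pairs),
              x$lower, x$upper, x$k))
  invisible(x)
}

#' Default CDR3-anchoring ambiguous restraints
#'
#' Builds the two default AIRs tying the ligand to the loop centers:
#' restraint alpha groups (P2 CA, P3 CB, P4 CA) against the CDR3-alpha
#' central-residue CA; restraint beta groups (P4 CA, P5 CB, P6 CA) against
#' the CDR3-beta central-residue CA; bounds 4-8 Angstrom.  Where a CB slot
#' falls on glycine the pair degrades to CA with a warning.  `mode = "split"`
#' instead emits one single-pair restraint per listed atom.
#'
#' @param ligand_template An [antigen_template()] (ligand residues are
#'   numbered 1..length).
#' @param receptor An annotated receptor (see [annotate_receptor()]).
#' @param lower,upper,k Restraint parameters.
#' @param mode `"grouped"` (two ambiguous restraints, default) or `"split"`.
#' @return List of `air_restraint` objects.
#' @export
make_default_airs <- function(ligand_template = antigen_template(), receptor,
                              lower = 4, upper = 8, k = 50,
                              mode = c("grouped", "split")) {
  mode <- match.arg(mode)
  cdr3 <- receptor$metadata$cdr3
  if (is.null(cdr3)) stop("receptor is not annotated; call annotate_receptor()")
  if (ligand_template$length < 6L)
    stop("ligand must have at least 6 residues (anchors P2..P6)")
  lig_atom <- function(resno, want_cb) {
    seq_pos <- resno  # ligand resseq == template position
    is_triad <- seq_pos %in% ligand_template$triad_positions
    if (want_cb && !is_triad) {
      warning(sprintf("P%d is a glycine spacer: CB restraint pair degraded to CA",
                      seq_pos))
      return("CA")
    }
    if (want_cb) "CB" else "CA"
  }
  mk_pairs <- function(spec, loop) {
    do.call(rbind, lapply(spec, function(s) {
      data.frame(lig_resno = s[[1]], lig_atom = lig_atom(s[[1]], s[[2]]),
                 rec_chain = loop$chain, rec_resno = loop$center,
                 rec_atom = "CA", stringsAsFactors = FALSE)
    }))
  }
  spec_a <- list(list(2L, FALSE), list(3L, TRUE), list(4L, FALSE))
  spec_b <- list(list(4L, FALSE), list(5L, TRUE), list(6L, FALSE))
  pa <- mk_pairs(spec_a, cdr3$alpha)
  pb <- mk_pairs(spec_b, cdr3$beta)
  if (mode == "grouped") {
    list(air_restraint(pa, lower, upper, k, label = "CDR3a"),
         air_restraint(pb, lower, upper, k, label = "CDR3b"))
  } else {
    c(lapply(seq_len(nrow(pa)), function(i)
        air_restraint(pa[i, , drop = FALSE], lower, upper, k,
                      label = sprintf("CDR3a.%d", i))),
      lapply(seq_len(nrow(pb)), function(i)
        air_restraint(pb[i, , drop = FALSE], lower, upper, k,
                      label = sprintf("CDR3b.%d", i))))
  }
}

resolve_selector <- function(atoms, chain, resno, atom) {
  hit <- which(atoms$resno == resno & atoms$atom == atom &
               (is.na(chain) | atoms$chain == chain))
  if (length(hit) != 1L)
    stop(sprintf("selector %s/%s/%s resolves to %d atoms",
                 chain, resno, atom, length(hit)))
  hit
}

air_pair_indices <- function(restraint, ligand, receptor) {
  p <- restraint$pairs
  lig <- vapply(seq_len(nrow(p)), function(i)
    resolve_selector(ligand$atoms, NA, p$lig_resno[i], p$lig_atom[i]), integer(1))
  rec <- vapply(seq_len(nrow(p)), function(i)
    resolve_selector(receptor$atoms, p$rec_chain[i], p$rec_resno[i],
                     p$rec_atom[i]), integer(1))
  cbind(lig = lig, rec = rec)
}

#' Effective distance of an ambiguous restraint
#'
#' Aggregates the candidate pair distances as
#' `d_eff = (sum over pairs d^-6)^(-1/6)`, the smooth minimum-dominated
#' convention of ambiguity-driven docking.  `d_eff` never exceeds the
#' smallest pairwise distance (equality only for a single pair), and adding
#' a pair can only decrease it.
#'
#' @param restraint An `air_restraint`.
#' @param ligand_coords,receptor_coords n x 3 coordinate matrices matching
#'   the structures the restraint indices were resolved against.
#' @param idx Optional precomputed index matrix from `air_pair_indices`.
#' @param ligand,receptor Structures (needed when `idx` is missing).
#' @return Effective distance in Angstrom.
#' @export
effective_distance <- function(restraint, ligand_coords, receptor_coords,
                               idx = NULL, ligand = NULL, receptor = NULL) {
  if (is.null(idx)) idx <- air_pair_indices(restraint, ligand, receptor)
  d <- sqrt(rowSums((ligand_coords[idx[, "lig"], , drop = FALSE] -
                     receptor_coords[idx[, "rec"], , drop = FALSE])^2))
  sum(d^-6)^(-1 / 6)
}

#' Flat-bottom restraint energy
#'
#' Soft-square potential: zero inside `[lower, upper]`, harmonic in the
#' violation outside.
#'
#' @param restraint An `air_restraint`.
#' @param d_eff Effective distance, Angstrom (> 0).
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(restraint, d_eff) {
  if (any(d_eff <= 0)) stop("d_eff must be positive")
  viol <- pmax(d_eff - restraint$upper, restraint$lower - d_eff, 0)
  restraint$k * viol^2
}

#' Export restraints in the ambiguity-driven docking table dialect
#'
#' One `assign` statement per restraint pair group, in center/minus/plus
#' form: bounds `[4, 8]` become `6.0 2.0 2.0`.  Also see
#' [export_airs_json()].
#'
#' @param restraints List of `air_restraint`s.
#' @param path Optional file to write; when `NULL` the lines are returned.
#' @param lig_segid Segment id used for the ligand selections (default "A").
#' @return Character vector of assign statements, invisibly when written.
#' @export
export_airs_table <- function(restraints, path = NULL, lig_segid = "A") {
  lines <- unlist(lapply(restraints, function(r) {
    center <- (r$lower + r$upper) / 2
    minus <- center - r$lower
    plus <- r$upper - center
    sel <- sprintf("(segid %s and resid %d and name %s)",
                   lig_segid, r$pairs$lig_resno, r$pairs$lig_atom)
    rec <- sprintf("(segid %s and resid %d and name %s)",
                   r$pairs$rec_chain, r$pairs$rec_resno, r$pairs$rec_atom)
    if (nrow(r$pairs) == 1L) {
      sprintf("assign %s %s %.1f %.1f %.1f", sel, rec, center, minus, plus)
    } else {
      body <- paste(sprintf("       %s %s", sel, rec), collapse = "\n    or\n")
      sprintf("assign\n%s\n%.1f %.1f %.1f", body, center, minus, plus)
    }
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export restraints as JSON
#'
#' @param restraints List of `air_restraint`s.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
export_airs_json <- function(restraints, path = NULL) {
  obj <- lapply(restraints, function(r)
    list(label = r$label, lower = r$lower, upper = r$upper, k = r$k,
         pairs = r$pairs))
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
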