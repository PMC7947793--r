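# Pose characterisation: intermolecular contact counting.  RMSD measures
# (Kabsch and direct ligand RMSD) live in geometry.R.

#' Contact-counting specification
#'
#' @param cutoff Distance cutoff in Angstrom (default 6.0, chosen to give
#'   counts of order 10^2-10^3 for a 9-mer against a receptor surface).
#' @param atoms `"heavy"` (default) or `"all"`.
#' @return Object of class `contact_spec`.
#' @export
contact_spec <- function(cutoff = 6.0, atoms = c("heavy", "all")) {
  atoms <- match.arg(atoms)
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff, atoms = atoms), class = "contact_spec")
}

#' Count intermolecular atomic contacts
#'
#' Number of intermolecular atom pairs closer than the cutoff, symmetric in
#' argument order.  With `atoms = "heavy"` hydrogen positions (element "H")
#' are ignored when element vectors are supplied.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices of the two molecules.
#' @param spec A [contact_spec()].
#' @param elems_a,elems_b Optional element vectors matching the rows.
#' @return Integer contact count.
#' @export
compute_contacts <- function(coords_a, coords_b, spec = contact_spec(),
                             elems_a = NULL, elems_b = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    warning("empty coordinate set: 0 contacts")
    return(0L)
  }
  if (spec$atoms == "heavy") {
    if (!is.null(elems_a)) a <- a[elems_a != "H", , drop = FALSE]
    if (!is.null(elems_b)) b <- b[elems_b != "H", , drop = FALSE]
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sum(d2 < spec$cutoff^2)
}
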