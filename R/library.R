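#' Specify a combinatorial SCAA library
#'
#' A library is the Cartesian product of per-position alphabets at the
#' template's triad positions, minus per-position exclusions.
#'
#' @param alphabet Character vector (shared by all positions) or a list with
#'   one character vector per triad position.  Default: the full SCAA.
#' @param exclusions Named list of excluded letters per position, names like
#'   `"P5"` (or bare position numbers).  Default: none.
#' @param template An [antigen_template()].
#' @return An object of class `library_spec`.
#' @examples
#' library_spec(exclusions = list(P5 = "S", P8 = "D"))
#' @export
library_spec <- function(alphabet = SCAA_LETTERS, exclusions = list(),
                         template = antigen_template()) {
  k <- length(template$triad_positions)
  if (!is.list(alphabet)) alphabet <- rep(list(alphabet), k)
  if (length(alphabet) != k)
    stop("'alphabet' must give one letter set per triad position")
  alphabet <- lapply(alphabet, function(a) sort(unique(toupper(a))))
  excl <- rep(list(character(0)), k)
  pos_names <- paste0("P", template$triad_positions)
  if (length(exclusions)) {
    nm <- names(exclusions)
    if (is.null(nm)) stop("'exclusions' must be a named list (e.g. list(P5 = 'S'))")
    for (i in seq_along(exclusions)) {
      key <- sub("^P", "", nm[i])
      j <- match(paste0("P", key), pos_names)
      if (is.na(j)) stop(sprintf("exclusion position '%s' is not a triad position", nm[i]))
      excl[[j]] <- sort(unique(toupper(exclusions[[i]])))
    }
  }
  eff <- mapply(setdiff, alphabet, excl, SIMPLIFY = FALSE)
  structure(list(alphabet = alphabet, exclusions = excl, effective = eff,
                 template = template, positions = template$triad_positions),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat("SCAA library specification\n")
  for (i in seq_along(x$positions)) {
    cat(sprintf("  P%d: {%s}%s\n", x$positions[i],
                paste(x$effective[[i]], collapse = ","),
                if (length(x$exclusions[[i]]))
                  sprintf("  (excluded: %s)", paste(x$exclusions[[i]], collapse = ","))
                else ""))
  }
  cat(sprintf("  size: %d peptides\n", library_size(lengths(x$effective))))
  invisible(x)
}

#' Enumerate a combinatorial peptide library
#'
#' Generates the full Cartesian product of the per-position effective
#' alphabets, in lexicographic order of the rendered sequence.  The default
#' spec yields the 216-member SCAA library (6 classes at each of P3, P5, P8).
#'
#' @param spec A [library_spec()].
#' @return A data.frame with columns `peptide_id`, `p1`, `p2`, `p3` (triad
#'   letters, in triad-position order) and `sequence`.
#' @examples
#' nrow(enumerate_library())  # 216
#' @export
enumerate_library <- function(spec = library_spec()) {
  sizes <- lengths(spec$effective)
  if (any(sizes == 0L)) {
    warning("a triad position has an empty effective alphabet; library is empty")
    return(data.frame(peptide_id = character(0), p1 = character(0),
                      p2 = character(0), p3 = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(rev(spec$effective), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(spec$effective)), drop = FALSE]
  names(grid) <- paste0("p", seq_along(spec$effective))
  seqs <- apply(grid, 1L, function(tr) render_template(tr, spec$template))
  ord <- order(seqs, method = "radix")
  grid <- grid[ord, , drop = FALSE]
  out <- data.frame(peptide_id = sprintf("pep%03d", seq_len(nrow(grid))),
                    grid, sequence = seqs[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Library size from per-position alphabet sizes
#'
#' @param position_alphabet_sizes Non-negative integer vector.
#' @return The product of the sizes: `library_size(c(6, 6, 6))` is 216,
#'   `c(20, 20, 20)` gives the 8,000-member full natural triad space.
#' @export
library_size <- function(position_alphabet_sizes) {
  s <- as.numeric(position_alphabet_sizes)
  if (any(s < 0)) stop("alphabet sizes must be non-negative")
  prod(s)
}

#' Reduction factor between two library sizes
#'
#' @param full_size Size of the unreduced library.
#' @param reduced_size Size of the reduced library (> 0).
#' @return `full_size / reduced_size`; e.g. 8000/216 = 37.04, the
#'   dimensionality gain of the SCAA over the natural triad space.
#' @export
reduction_factor <- function(full_size, reduced_size) {
  if (any(reduced_size <= 0)) stop("reduced size must be positive")
  full_size / reduced_size
}
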