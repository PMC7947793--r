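# Library-level analysis: per-peptide pose statistics (E_i, C_i), the
# +-sigma best-binder window, positional residual-energy heatmaps and
# library-reduction proposals.

#' Aggregate a pose ensemble into a per-peptide record
#'
#' Means, standard deviations and standard errors of the interaction energy,
#' contacts and RMSD over all poses of the ensemble (no pose filtering: the
#' per-peptide coordinates E_i, C_i are averages over the full ensemble).
#' SD uses the sample convention (ddof = 1); the SD of a single pose is 0.
#'
#' @param pose_set A `pose_set` (or a data.frame with columns `E_total`,
#'   `contacts`, optionally `rmsd`).
#' @param triad The peptide's triad letters.
#' @return One-row data.frame: `triad`, `sequence`, `E_mean`, `E_sd`,
#'   `E_sem`, `C_mean`, `C_sd`, `rmsd_mean`, `rmsd_best`, `n_poses`.
#' @export
aggregate_poses <- function(pose_set, triad = NULL) {
  p <- if (inherits(pose_set, "pose_set")) pose_set$poses else pose_set
  if (nrow(p) == 0L) stop("empty pose set")
  if (is.null(triad) && inherits(pose_set, "pose_set"))
    triad <- pose_set$ligand$metadata$triad
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  n <- nrow(p)
  rmsd <- if ("rmsd" %in% names(p)) p$rmsd else rep(NA_real_, n)
  data.frame(
    triad = paste(triad, collapse = ""),
    sequence = if (inherits(pose_set, "pose_set")) pose_set$ligand$sequence
               else NA_character_,
    E_mean = mean(p$E_total), E_sd = sd0(p$E_total),
    E_sem = sd0(p$E_total) / sqrt(n),
    C_mean = mean(p$contacts), C_sd = sd0(p$contacts),
    rmsd_mean = mean(rmsd), rmsd_best = suppressWarnings(min(rmsd)),
    n_poses = n, stringsAsFactors = FALSE)
}

#' Select the +-sigma best-binder window
#'
#' Centers are the unweighted means of the per-peptide `E_mean` and `C_mean`
#' across the library; the half-widths are, by default, the standard
#' deviations of those per-peptide means across the library (`sigma =
#' "sd"`), i.e. the spread of the energy-contact map.  `sigma = "sem"`
#' instead uses the standard error of those library means.  A record is a
#' member iff both |E_mean - E_center| <= E_sigma and |C_mean - C_center| <=
#' C_sigma (closed boundary).
#'
#' @param records Data.frame of per-peptide records (>= 2 rows) as returned
#'   by [aggregate_poses()].
#' @param sigma `"sd"` (default) or `"sem"`.
#' @return Object of class `binder_window`: centers, sigmas, logical
#'   `members`, member `ids`, and the sigma mode used.
#' @export
select_best_binders <- function(records, sigma = c("sd", "sem")) {
  sigma <- match.arg(sigma)
  if (nrow(records) < 2L) stop("need at least 2 records to define a window")
  e <- records$E_mean; c_ <- records$C_mean
  es <- stats::sd(e); cs <- stats::sd(c_)
  if (sigma == "sem") {
    es <- es / sqrt(length(e)); cs <- cs / sqrt(length(c_))
  }
  members <- abs(e - mean(e)) <= es & abs(c_ - mean(c_)) <= cs
  structure(list(E_center = mean(e), E_sigma = es,
                 C_center = mean(c_), C_sigma = cs,
                 members = members,
                 ids = records$triad[members], sigma_mode = sigma),
            class = "binder_window")
}

#' @export
print.binder_window <- function(x, ...) {
  cat(sprintf("Best-binder window (+-sigma, mode '%s')\n", x$sigma_mode))
  cat(sprintf("  E: %.2f +- %.2f kcal/mol;  C: %.1f +- %.1f\n",
              x$E_center, x$E_sigma, x$C_center, x$C_sigma))
  cat(sprintf("  members: %d of %d peptides\n", sum(x$members),
              length(x$members)))
  invisible(x)
}

#' Flag the translated reference peptide in a record set
#'
#' Translates a natural reference triad into the SCAA and marks the matching
#' record, reporting whether it falls inside the best-binder window.
#'
#' @param records Per-peptide records (column `triad`, letters concatenated).
#' @param reference_triad Three natural one-letter codes.
#' @param table An [scaa_table()].
#' @param window Optional `binder_window` for membership reporting.
#' @return `records` with logical column `is_translated_reference` (and
#'   `in_window` when a window is given); attribute `reference_in_window`.
#' @export
flag_reference <- function(records, reference_triad, table = scaa_table(),
                           window = NULL) {
  tt <- paste(translate_triad(reference_triad, table), collapse = "")
  hit <- records$triad == tt
  if (!any(hit))
    stop(sprintf("translated triad %s not present among the records", tt))
  records$is_translated_reference <- hit
  if (!is.null(window)) {
    records$in_window <- window$members
    attr(records, "reference_in_window") <- any(hit & window$members)
  }
  records
}

#' Positional residual-energy heatmap
#'
#' Mean per-peptide energy `E_mean` for every SCAA class at every triad
#' position, computed over a subset of records (by default the best-binder
#' window members).  Cells with no contributing record are `NA` (missing,
#' not zero).
#'
#' @param records Per-peptide records.
#' @param subset Logical vector selecting the contributing records; default
#'   all `TRUE`.  Pass `window$members` to restrict to the binder window.
#' @param positions Triad position labels (default P3, P5, P8).
#' @return Object of class `scaa_heatmap`: a 6 x k matrix of mean energies
#'   (rows = SCAA classes, columns = positions) with an `n` attribute of
#'   occupancy counts.
#' @export
positional_heatmap <- function(records, subset = NULL,
                               positions = c("P3", "P5", "P8")) {
  if (is.null(subset)) subset <- rep(TRUE, nrow(records))
  rec <- records[subset, , drop = FALSE]
  k <- length(positions)
  m <- matrix(NA_real_, nrow = length(SCAA_LETTERS), ncol = k,
              dimnames = list(SCAA_LETTERS, positions))
  n <- matrix(0L, nrow = length(SCAA_LETTERS), ncol = k,
              dimnames = list(SCAA_LETTERS, positions))
  letters_at <- function(j) substr(rec$triad, j, j)
  for (j in seq_len(k)) {
    lj <- letters_at(j)
    for (s in SCAA_LETTERS) {
      sel <- lj == s
      n[s, j] <- sum(sel)
      if (any(sel)) m[s, j] <- mean(rec$E_mean[sel])
    }
  }
  structure(m, n = n, class = c("scaa_heatmap", "matrix"))
}

#' @export
print.scaa_heatmap <- function(x, ...) {
  cat("Positional residual-energy heatmap (kcal/mol)\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Propose per-position class exclusions from a heatmap
#'
#' Default policy: at each triad position, propose excluding the SCAA class
#' with the maximum mean residual energy (the least favourable positional
#' contributor).  A maximum counts only when it stands clear of the
#' runner-up by more than `margin` (kcal/mol); classes within the margin are
#' treated as tied and nothing is proposed for that position (conservative).
#' Positional minima are never excluded -- a strong minimum is not treated
#' as a positive selection rule.
#'
#' @param heatmap An `scaa_heatmap`.
#' @param policy Currently only `"max"`.
#' @param margin Minimum lead (kcal/mol) of the maximum over the runner-up
#'   for an exclusion to be proposed (default 1).
#' @return Named list of excluded classes per position (empty entries
#'   dropped), directly usable as the `exclusions` of [library_spec()].
#' @export
propose_exclusions <- function(heatmap, policy = "max", margin = 1) {
  stopifnot(policy == "max")
  m <- unclass(heatmap)
  out <- list()
  for (j in colnames(m)) {
    col <- m[!is.na(m[, j]), j]
    if (length(col) < 2L) next
    ord <- order(col, decreasing = TRUE)
    if (col[ord[1]] - col[ord[2]] > margin)
      out[[j]] <- names(col)[ord[1]]
  }
  out
}

#' Energy-contact map of a peptide library
#'
#' Scatter of per-peptide mean contacts vs mean interaction energy, with the
#' +-sigma best-binder window shaded and window members highlighted; the
#' translated reference (if flagged) is starred.
#'
#' @param records Per-peptide records, optionally flagged by
#'   [flag_reference()].
#' @param window Optional `binder_window`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `records`.
#' @export
plot_energy_contact_map <- function(records, window = NULL, ...) {
  col <- rep("black", nrow(records))
  if (!is.null(window)) col[window$members] <- "dodgerblue3"
  graphics::plot(records$C_mean, records$E_mean, pch = 16, col = col,
                 xlab = expression(C[i] ~ "(contacts)"),
                 ylab = expression(E[i] ~ "(kcal/mol)"), ...)
  if (!is.null(window))
    graphics::rect(window$C_center - window$C_sigma,
                   window$E_center - window$E_sigma,
                   window$C_center + window$C_sigma,
                   window$E_center + window$E_sigma,
                   border = "dodgerblue3", lty = 2)
  if (!is.null(records$is_translated_reference) &&
      any(records$is_translated_reference)) {
    i <- which(records$is_translated_reference)
    graphics::points(records$C_mean[i], records$E_mean[i], pch = 8,
                     col = "goldenrod2", cex = 2, lwd = 2)
  }
  invisible(records)
}

#' Plot a positional residual-energy heatmap
#'
#' @param x An `scaa_heatmap`.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.scaa_heatmap <- function(x, ...) {
  m <- unclass(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  axes = FALSE, xlab = "antigen position", ylab = "SCAA class")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 1)
  graphics::box()
  invisible(x)
}
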