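# Deterministic synthetic fixtures: a mock two-loop receptor groove, a
# planted ligand pose satisfying the default AIRs, and synthetic per-peptide
# record sets with planted positional-energy effects.  All fixtures are pure
# functions of their seed, generated in code at run time.

principal_axis <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(c0)$v[, 1]
  if (v[1] < 0) v <- -v
  v
}

# Rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- vnorm(v); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about_axis(cross3(a, p), 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

place_structure <- function(structure, tf) {
  xyz <- apply_transform(coords(structure), tf)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# The shared rigid scaffold in its docking frame: principal CA axis on x,
# CA centroid at the origin.  Backbone and CB positions are identical for
# every library triad, so the AIR anchor atoms are triad-independent.
scaffold_in_frame <- function(template = antigen_template()) {
  lig <- build_library_peptide(rep(SCAA_LETTERS[6], 3), template)
  ca <- coords(lig, "CA")
  R <- rotation_between(principal_axis(ca), c(1, 0, 0))
  cen <- colMeans(ca)
  place_structure(lig, rigid_transform(R, -as.numeric(R %*% cen)))
}

scaffold_anchor_xyz <- function(scaf, spec) {
  t(vapply(spec, function(s) {
    r <- scaf$atoms[scaf$atoms$resno == s[[1]] & scaf$atoms$atom == s[[2]], ]
    c(r$x[1], r$y[1], r$z[1])
  }, numeric(3)))
}

deff_to_point <- function(anchors, q) {
  d <- sqrt(rowSums(sweep(anchors, 2, q)^2))
  sum(d^-6)^(-1 / 6)
}

#' Mock two-loop receptor groove
#'
#' Builds two 7-residue poly-alanine loops with helical dihedrals and places
#' them as the walls of a V-shaped groove whose axis runs along x, raised to
#' either side of the scaffold frame (the beta loop is tilted and slightly
#' higher, so the groove has no mirror symmetry).  Each loop's central
#' residue (residue 4) is positioned by root-finding so that the default AIR
#' effective distance from the scaffold anchors to that residue's CA is
#' exactly 6.0 Angstrom: a library peptide lying in the groove floor
#' automatically satisfies both restraints at the flat-bottom center.  Loops
#' are annotated as CDR3-alpha (chain R) and CDR3-beta (chain S).
#'
#' @param seed Integer seed recorded with the fixture (the geometry itself
#'   is deterministic).
#' @return An annotated receptor `peptide_structure`.
#' @export
make_mock_receptor <- function(seed = 1L) {
  scaf <- scaffold_in_frame()
  anch_a <- scaffold_anchor_xyz(scaf, list(list(2, "CA"), list(3, "CB"),
                                           list(4, "CA")))
  anch_b <- scaffold_anchor_xyz(scaf, list(list(4, "CA"), list(5, "CB"),
                                           list(6, "CA")))
  loop <- function(chain) {
    p <- build_backbone("AAAAAAA", dihedral_table(7, phi = -60, psi = -45),
                        chain = chain)
    p <- attach_sidechains(p)
    ca <- coords(p, "CA")
    R <- rotation_between(principal_axis(ca), c(1, 0, 0))
    cen <- colMeans(ca)
    place_structure(p, rigid_transform(R, -as.numeric(R %*% cen)))
  }
  sff <- assign_ff(scaf)
  sxyz <- coords(scaf)
  no_air <- list(lig = integer(0), rec = integer(0), len = integer(0),
                 lower = numeric(0), upper = numeric(0), k = numeric(0))
  place_loop <- function(p, anchors, dirn, tilt_deg) {
    dirn <- unit(dirn)
    f <- function(r) deff_to_point(anchors, colMeans(anchors) + r * dirn) - 6
    r6 <- stats::uniroot(f, c(1, 40), tol = 1e-10)$root
    q <- colMeans(anchors) + r6 * dirn
    Rt <- rotation_about_axis(c(0, 0, 1), tilt_deg)
    pff <- assign_ff(p)
    # roll the loop about its own axis to present its least-clashing face
    # to the groove, then drop it so residue 4's CA hits the target point
    best <- NULL
    for (roll in seq(0, 350, by = 10)) {
      Rr <- Rt %*% rotation_about_axis(c(1, 0, 0), roll)
      cca <- unlist(p$atoms[p$atoms$resno == 4 & p$atoms$atom == "CA",
                            c("x", "y", "z")])
      tf <- rigid_transform(Rr, q - as.numeric(Rr %*% cca))
      e <- score_complex_cpp(apply_transform(coords(p), tf), sxyz,
                             pff$eps, pff$sigma, pff$q,
                             sff$eps, sff$sigma, sff$q,
                             no_air$lig, no_air$rec, no_air$len,
                             no_air$lower, no_air$upper, no_air$k,
                             12, TRUE, 4)
      if (is.null(best) || e$E_vdw < best$e) best <- list(e = e$E_vdw, tf = tf)
    }
    place_structure(p, best$tf)
  }
  elev_a <- deg2rad(60); elev_b <- deg2rad(52)
  la <- place_loop(loop("R"), anch_a, c(0,  cos(elev_a), sin(elev_a)), 0)
  lb <- place_loop(loop("S"), anch_b, c(0, -cos(elev_b), sin(elev_b)), 12)
  atoms <- rbind(la$atoms, lb$atoms)
  rownames(atoms) <- NULL
  rec <- new_peptide(atoms, paste0(la$sequence, lb$sequence), chain = "RS",
                     metadata = list(fixture = "mock-two-loop-groove",
                                     seed = seed))
  annotate_receptor(rec, cdr3a = c(1, 7), cdr3b = c(1, 7),
                    chain_a = "R", chain_b = "S")
}

#' Planted ligand pose in the mock groove
#'
#' Builds the library peptide for `triad`, slides it into the mock groove
#' and settles it by deterministic minimisation of the intermolecular energy
#' under a strong pinning term holding both AIR effective distances at 6.0
#' Angstrom (the flat-bottom center).  The stored pose therefore satisfies
#' every default restraint exactly (E_air = 0) and serves as the recovery
#' target for docking tests.
#'
#' @param triad Three SCAA letters (default `c("Q","V","H")`).
#' @param seed Integer seed (recorded; the construction is deterministic).
#' @return Object of class `fixture_complex`: `receptor`, `ligand` (built
#'   frame), `planted` (transform), `planted_coords`, `restraints`, `seed`.
#' @export
make_planted_complex <- function(triad = c("Q", "V", "H"), seed = 1L) {
  receptor <- make_mock_receptor(seed)
  template <- antigen_template()
  ligand <- build_library_peptide(triad, template)
  restraints <- make_default_airs(template, receptor)
  params <- scoring_params()
  lxyz0 <- coords(ligand)
  cen <- colMeans(lxyz0)
  # initial guess: the scaffold frame the groove was built around (long axis
  # on x, CA centroid at the origin)
  ca <- coords(ligand, "CA")
  R0 <- rotation_between(principal_axis(ca), c(1, 0, 0))
  tf0 <- rigid_transform(R0, -as.numeric(R0 %*% colMeans(ca)))
  idx <- lapply(restraints, air_pair_indices, ligand = ligand,
                receptor = receptor)
  rxyz <- coords(receptor)
  obj <- function(par, pin) {
    tf <- perturb_transform(tf0, par, cen)
    lxyz <- apply_transform(lxyz0, tf)
    d <- vapply(seq_along(restraints), function(i)
      effective_distance(restraints[[i]], lxyz, rxyz, idx = idx[[i]]),
      numeric(1))
    e <- score_pose(receptor, ligand, tf, list(), params)
    e$E_total + pin * sum((d - 6)^2)
  }
  # coarse roll scan about the groove axis seats the triad side chains
  rolls <- seq(0, 330, by = 30)
  vals <- vapply(rolls, function(r) obj(c(deg2rad(r), 0, 0, 0, 0, 0), 500),
                 numeric(1))
  par0 <- c(deg2rad(rolls[which.min(vals)]), 0, 0, 0, 0, 0)
  fit <- stats::optim(par0, obj, pin = 500, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
  # polish with a hard pin so both effective distances sit at the 6.0 A
  # flat-bottom center within 0.1 A
  fit <- stats::optim(fit$par, obj, pin = 5000, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
  planted <- perturb_transform(tf0, fit$par, cen)
  structure(list(receptor = receptor, ligand = ligand, planted = planted,
                 planted_coords = apply_transform(lxyz0, planted),
                 restraints = restraints, seed = seed,
                 template = template),
            class = "fixture_complex")
}

# Apply a 6-parameter perturbation (rotation vector in radians about the
# ligand centroid image, then translation) on top of a base transform.
perturb_transform <- function(tf0, par, cen) {
  th <- sqrt(sum(par[1:3]^2))
  R <- if (th < 1e-12) diag(3)
       else rotation_about_axis(par[1:3], rad2deg(th))
  c1 <- as.numeric(tf0$R %*% cen) + tf0$t  # centroid after tf0
  rigid_transform(R %*% tf0$R,
                  as.numeric(R %*% (tf0$t - c1)) + c1 + par[4:6])
}

#' @export
print.fixture_complex <- function(x, ...) {
  d <- planted_deff(x)
  cat(sprintf("Planted fixture complex: ligand %s in mock groove (seed %d)\n",
              x$ligand$sequence, x$seed))
  cat(sprintf("  AIR effective distances: %s A\n",
              paste(sprintf("%.2f", d), collapse = ", ")))
  invisible(x)
}

#' AIR effective distances of the planted pose
#' @param fixture A `fixture_complex`.
#' @return Numeric vector, one effective distance per restraint.
#' @export
planted_deff <- function(fixture) {
  rxyz <- coords(fixture$receptor)
  vapply(fixture$restraints, function(r)
    effective_distance(r, fixture$planted_coords, rxyz,
                       ligand = fixture$ligand, receptor = fixture$receptor),
    numeric(1))
}

#' Synthetic per-peptide records with planted positional effects
#'
#' Generates a record set shaped like the output of [aggregate_poses()] over
#' the full SCAA library, with per-class/per-position energy offsets planted
#' on top of Gaussian noise -- the ground truth for heatmap and
#' library-reduction recovery tests.
#'
#' @param n Number of records (default 216 = the full library; the first `n`
#'   library members in lexicographic order are used).
#' @param effect_spec List with elements `offsets` (named numeric like
#'   `c("S@P5" = 10)`), `noise_sd` (energy noise SD, kcal/mol), `base_E`,
#'   `base_C`, `C_sd` (contact noise SD).
#' @param seed Integer RNG seed.
#' @return Data.frame of records (`triad`, `sequence`, `E_mean`, `C_mean`,
#'   ...), plus attribute `effects`.
#' @export
make_synthetic_records <- function(n = 216L,
                                   effect_spec = list(offsets = c(),
                                                      noise_sd = 1,
                                                      base_E = -15,
                                                      base_C = 280,
                                                      C_sd = 20),
                                   seed = 1L) {
  set.seed(seed)
  lib <- enumerate_library()
  if (n > nrow(lib)) stop("n exceeds the library size")
  lib <- lib[seq_len(n), , drop = FALSE]
  positions <- paste0("P", antigen_template()$triad_positions)
  base_E <- if (is.null(effect_spec$base_E)) -15 else effect_spec$base_E
  base_C <- if (is.null(effect_spec$base_C)) 280 else effect_spec$base_C
  noise_sd <- if (is.null(effect_spec$noise_sd)) 1 else effect_spec$noise_sd
  C_sd <- if (is.null(effect_spec$C_sd)) 20 else effect_spec$C_sd
  E <- rep(base_E, n)
  offs <- effect_spec$offsets
  if (length(offs)) {
    for (key in names(offs)) {
      parts <- strsplit(key, "@", fixed = TRUE)[[1]]
      j <- match(parts[2], positions)
      if (is.na(j)) stop(sprintf("unknown position in effect '%s'", key))
      sel <- lib[[paste0("p", j)]] == parts[1]
      E[sel] <- E[sel] + offs[[key]]
    }
  }
  E <- E + stats::rnorm(n, 0, noise_sd)
  C <- base_C + stats::rnorm(n, 0, C_sd)
  out <- data.frame(
    triad = paste0(lib$p1, lib$p2, lib$p3),
    sequence = lib$sequence,
    E_mean = E, E_sd = abs(stats::rnorm(n, 2, 0.2)),
    E_sem = NA_real_,
    C_mean = C, C_sd = abs(stats::rnorm(n, 15, 2)),
    rmsd_mean = NA_real_, rmsd_best = NA_real_,
    n_poses = 100L, stringsAsFactors = FALSE)
  out$E_sem <- out$E_sd / sqrt(out$n_poses)
  attr(out, "effects") <- effect_spec
  out
}
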