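# Rigid-body docking of a rigid peptide onto a rigid receptor under AIRs:
# pose sampling, Metropolis Monte-Carlo refinement, scoring.

#' Scoring parameters for the simplified force field
#'
#' Intermolecular 12-6 Lennard-Jones (per-element-class parameters) plus
#' Coulomb with a distance-dependent dielectric eps(r) = `diel`*r by default
#' (a cheap implicit-solvent model), plus the flat-bottom AIR term.  Energies
#' in kcal/mol, distances in Angstrom.
#'
#' @param cutoff Nonbonded cutoff in Angstrom (default 12; no switching
#'   function).
#' @param dielectric `"rdie"` (distance-dependent, default) or `"cdie"`
#'   (constant).
#' @param diel Dielectric factor: eps(r) = diel*r for `"rdie"`, eps = diel
#'   for `"cdie"`.
#' @param w_vdw,w_elec,w_air Non-negative term weights;
#'   `E_total = w_vdw*E_vdw + w_elec*E_elec + w_air*E_air`.
#' @return Object of class `scoring_params`.
#' @export
scoring_params <- function(cutoff = 12, dielectric = c("rdie", "cdie"),
                           diel = 4, w_vdw = 1, w_elec = 1, w_air = 1) {
  dielectric <- match.arg(dielectric)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(c(w_vdw, w_elec, w_air) < 0)) stop("weights must be non-negative")
  structure(list(cutoff = cutoff, dielectric = dielectric, diel = diel,
                 w_vdw = w_vdw, w_elec = w_elec, w_air = w_air),
            class = "scoring_params")
}

#' Monte-Carlo refinement schedule
#'
#' The default (4000 steps, 12 degree / 0.8 Angstrom Gaussian step scales,
#' geometric cooling from 20 to 0.02 kcal/mol) is a short simulated-
#' annealing search: hot enough early to reorient a randomly placed ligand,
#' cold enough late to settle into a local minimum.
#'
#' @param steps Number of Metropolis steps.
#' @param rot_step Rotation step scale, degrees (Gaussian).
#' @param trans_step Translation step scale per axis, Angstrom (Gaussian).
#' @param t_start,t_end Start/end temperature of the geometric cooling
#'   schedule, in energy units (kcal/mol).
#' @return Object of class `mc_schedule`.
#' @export
mc_schedule <- function(steps = 4000L, rot_step = 12, trans_step = 0.8,
                        t_start = 20, t_end = 0.02) {
  structure(list(steps = as.integer(steps), rot_step = rot_step,
                 trans_step = trans_step, t_start = t_start, t_end = t_end),
            class = "mc_schedule")
}

# Per-atom force-field annotation: LJ by element class, coarse charges
# (backbone dipole set + formal charges on charged side chains).
assign_ff <- function(structure) {
  at <- structure$atoms
  m <- match(at$elem, LJ_PARAMS$elem)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("no force-field parameters for atom %s (%s%d, element '%s')",
                 at$atom[bad], at$resname[bad], at$resno[bad], at$elem[bad]))
  }
  q <- numeric(nrow(at))
  bb <- match(at$atom, names(BACKBONE_CHARGES))
  q[!is.na(bb)] <- BACKBONE_CHARGES[bb[!is.na(bb)]]
  for (res in names(SIDECHAIN_CHARGES)) {
    ch <- SIDECHAIN_CHARGES[[res]]
    sel <- at$resname == res & at$atom %in% names(ch)
    if (any(sel)) q[sel] <- ch[at$atom[sel]]
  }
  data.frame(eps = LJ_PARAMS$eps[m], sigma = LJ_PARAMS$sigma[m], q = q)
}

airs_to_cpp <- function(restraints, ligand, receptor) {
  idx <- lapply(restraints, air_pair_indices, ligand = ligand,
                receptor = receptor)
  list(lig = as.integer(unlist(lapply(idx, function(m) m[, "lig"])) - 1L),
       rec = as.integer(unlist(lapply(idx, function(m) m[, "rec"])) - 1L),
       len = vapply(idx, nrow, integer(1)),
       lower = vapply(restraints, `[[`, numeric(1), "lower"),
       upper = vapply(restraints, `[[`, numeric(1), "upper"),
       k = vapply(restraints, `[[`, numeric(1), "k"))
}

#' Score one rigid-body pose
#'
#' Intermolecular-only energy of the ligand placed by `transform` against
#' the fixed receptor: Lennard-Jones and Coulomb sums over heavy-atom pairs
#' within the cutoff, plus the summed flat-bottom AIR energies.
#' Deterministic for fixed inputs.
#'
#' @param receptor,ligand `peptide_structure`s.
#' @param transform A [rigid_transform()] applied to the ligand's built
#'   coordinates (identity by default).
#' @param restraints List of `air_restraint`s (may be empty).
#' @param params A [scoring_params()].
#' @return Named list `E_vdw`, `E_elec`, `E_air`, `E_total` (kcal/mol).
#' @export
score_pose <- function(receptor, ligand, transform = rigid_transform(),
                       restraints = list(), params = scoring_params()) {
  lff <- assign_ff(ligand)
  rff <- assign_ff(receptor)
  air <- airs_to_cpp(restraints, ligand, receptor)
  lxyz <- apply_transform(coords(ligand), transform)
  e <- score_complex_cpp(lxyz, coords(receptor),
                         lff$eps, lff$sigma, lff$q, rff$eps, rff$sigma, rff$q,
                         air$lig, air$rec, air$len, air$lower, air$upper, air$k,
                         params$cutoff, params$dielectric == "rdie", params$diel)
  e$E_total <- params$w_vdw * e$E_vdw + params$w_elec * e$E_elec +
    params$w_air * e$E_air
  e
}

# Ligand-side AIR anchor atoms (rows of the ligand atom table).
air_anchor_rows <- function(restraints, ligand) {
  unique(unlist(lapply(restraints, function(r)
    vapply(seq_len(nrow(r$pairs)), function(i)
      resolve_selector(ligand$atoms, NA, r$pairs$lig_resno[i],
                       r$pairs$lig_atom[i]), integer(1)))))
}

air_target_point <- function(restraints, receptor) {
  rows <- unique(unlist(lapply(restraints, function(r)
    vapply(seq_len(nrow(r$pairs)), function(i)
      resolve_selector(receptor$atoms, r$pairs$rec_chain[i],
                       r$pairs$rec_resno[i], r$pairs$rec_atom[i]),
      integer(1)))))
  colMeans(coords(receptor)[rows, , drop = FALSE])
}

#' Sample initial rigid-body poses
#'
#' Draws `n` starting transforms: a uniform random rotation (quaternion
#' method) about the ligand centroid, then a translation placing the
#' centroid of the ligand's restraint-anchor atoms uniformly in a ball of
#' radius `slack` around the mean position of the receptor-side restraint
#' atoms.  This keeps starting poses close to the CDR3 surface so that most
#' already satisfy the AIR bounds.  Reproducible given `seed`.
#'
#' @param receptor,ligand `peptide_structure`s (receptor annotated).
#' @param restraints List of `air_restraint`s.
#' @param n Number of poses (>= 0).
#' @param seed Integer RNG seed.
#' @param slack Ball radius in Angstrom (default 1.5).
#' @param max_clash Placements whose vdW energy exceeds this (kcal/mol) are
#'   resampled (up to 25 tries), so refinement starts from the molecular
#'   surface rather than from deep interpenetration.
#' @return List of `n` [rigid_transform()]s.
#' @export
sample_initial_poses <- function(receptor, ligand, restraints, n, seed,
                                 slack = 1.5, max_clash = 100) {
  stopifnot(n >= 0)
  if (n == 0L) return(list())
  set.seed(seed)
  lxyz <- coords(ligand)
  cen <- colMeans(lxyz)
  anchor_rows <- air_anchor_rows(restraints, ligand)
  target <- air_target_point(restraints, receptor)
  lff <- assign_ff(ligand)
  rff <- assign_ff(receptor)
  rxyz <- coords(receptor)
  no_air <- list(lig = integer(0), rec = integer(0), len = integer(0),
                 lower = numeric(0), upper = numeric(0), k = numeric(0))
  draw <- function() {
    R <- random_rotation()
    # anchor centroid after rotating about the ligand centroid
    anc <- colMeans(sweep(lxyz[anchor_rows, , drop = FALSE], 2, cen) %*% t(R)) + cen
    # uniform point in ball of radius slack
    u <- stats::rnorm(3)
    p <- target + slack * stats::runif(1)^(1 / 3) * u / sqrt(sum(u * u))
    # x -> R (x - cen) + cen + (p - anc)
    rigid_transform(R, cen - as.numeric(R %*% cen) + (p - anc))
  }
  lapply(seq_len(n), function(i) {
    for (try in seq_len(25L)) {
      tf <- draw()
      e <- score_complex_cpp(apply_transform(lxyz, tf), rxyz,
                             lff$eps, lff$sigma, lff$q,
                             rff$eps, rff$sigma, rff$q,
                             no_air$lig, no_air$rec, no_air$len,
                             no_air$lower, no_air$upper, no_air$k,
                             12, TRUE, 4)
      if (e$E_vdw <= max_clash) break
    }
    tf
  })
}

# Rigid transform mapping point set a onto b (least squares; used to recover
# the pose transform from refined coordinates).
kabsch_transform <- function(a, b) {
  ac <- colMeans(a); bc <- colMeans(b)
  s <- svd(crossprod(sweep(b, 2, bc), sweep(a, 2, ac)))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rigid_transform(R, bc - as.numeric(R %*% ac))
}

#' Refine one pose by rigid-body Monte Carlo
#'
#' Metropolis Monte Carlo over small random rotations/translations of the
#' ligand with geometric cooling, returning the lowest-E_total pose visited
#' (never worse than the start).  Seeded and reproducible.
#'
#' @inheritParams score_pose
#' @param schedule An [mc_schedule()]; 0 steps returns the scored input pose.
#' @param seed Integer RNG seed.
#' @return A list: `transform`, `E_vdw`, `E_elec`, `E_air`, `E_total`.
#' @export
refine_pose <- function(receptor, ligand, transform, restraints,
                        params = scoring_params(), schedule = mc_schedule(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lxyz0 <- coords(ligand)
  lxyz <- apply_transform(lxyz0, transform)
  if (schedule$steps == 0L) {
    e <- score_pose(receptor, ligand, transform, restraints, params)
    return(c(list(transform = transform), e))
  }
  lff <- assign_ff(ligand)
  rff <- assign_ff(receptor)
  air <- airs_to_cpp(restraints, ligand, receptor)
  rxyz <- coords(receptor)
  # deterministic pull-out: back a grossly overlapping start out along the
  # receptor-to-ligand axis until the hard-core clash is relieved, so the
  # Monte-Carlo stage starts from the molecular surface
  no_air <- list(lig = integer(0), rec = integer(0), len = integer(0),
                 lower = numeric(0), upper = numeric(0), k = numeric(0))
  vdw_of <- function(xyz) score_complex_cpp(
    xyz, rxyz, lff$eps, lff$sigma, lff$q, rff$eps, rff$sigma, rff$q,
    no_air$lig, no_air$rec, no_air$len, no_air$lower, no_air$upper, no_air$k,
    params$cutoff, params$dielectric == "rdie", params$diel)$E_vdw
  run_mc <- function(start_xyz) mc_refine_cpp(
    start_xyz, rxyz,
    lff$eps, lff$sigma, lff$q, rff$eps, rff$sigma, rff$q,
    air$lig, air$rec, air$len, air$lower, air$upper, air$k,
    params$cutoff, params$dielectric == "rdie", params$diel,
    params$w_vdw, params$w_elec, params$w_air,
    schedule$steps, schedule$rot_step, schedule$trans_step,
    schedule$t_start, schedule$t_end)
  pull_out <- function(xyz) {
    if (vdw_of(xyz) > 20) {
      dirn <- colMeans(xyz) - colMeans(rxyz)
      dirn <- if (sqrt(sum(dirn^2)) < 1e-8) c(0, 0, -1)
              else dirn / sqrt(sum(dirn^2))
      for (step in seq_len(80L)) {
        xyz <- sweep(xyz, 2, 0.5 * dirn, "+")
        if (vdw_of(xyz) <= 20) break
      }
    }
    xyz
  }
  res <- run_mc(pull_out(lxyz))
  # adaptive restarts: a run ending with positive total energy is wedged in
  # a clash or restraint violation; pull its best pose back to the surface
  # and re-anneal (at most three times)
  tries <- 0L
  while (res$E_total > 0 && tries < 3L) {
    res <- run_mc(pull_out(res$coords))
    tries <- tries + 1L
  }
  list(transform = kabsch_transform(lxyz0, res$coords),
       E_vdw = res$E_vdw, E_elec = res$E_elec, E_air = res$E_air,
       E_total = res$E_total)
}

#' Dock one peptide: sample, refine and score a pose ensemble
#'
#' Generates `n_poses` rigid-body poses of the ligand on the receptor
#' (default 100): initial placements near the restraint-defined surface
#' region, each refined by Monte Carlo, then scored and annotated with
#' contact counts (and RMSD to a reference pose when given).  All poses are
#' retained and sorted by `E_total` ascending; the per-peptide statistics
#' average over the full ensemble.
#'
#' @inheritParams score_pose
#' @param n_poses Number of poses (>= 1, default 100).
#' @param seed Integer RNG seed; the full run is a deterministic function of
#'   it.
#' @param schedule An [mc_schedule()].
#' @param reference Optional reference for per-pose direct ligand-CA RMSD: a
#'   posed `peptide_structure`, a full-atom coordinate matrix in the
#'   ligand's atom order, or a CA-only matrix (one row per residue).
#' @param contact_spec A [contact_spec()].
#' @param slack Initial-placement ball radius (see [sample_initial_poses()]).
#' @return Object of class `pose_set`: `poses` (data.frame of energies,
#'   contacts, rmsd, sorted by E_total), `transforms`, `ligand`, `seed`.
#' @export
dock_peptide <- function(receptor, ligand, restraints,
                         params = scoring_params(), n_poses = 100L, seed = 1L,
                         schedule = mc_schedule(), reference = NULL,
                         contact_spec = scaadock::contact_spec(), slack = 1.5) {
  stopifnot(n_poses >= 1)
  starts <- sample_initial_poses(receptor, ligand, restraints, n_poses, seed,
                                 slack = slack)
  lxyz0 <- coords(ligand)
  rxyz <- coords(receptor)
  ca_rows <- which(ligand$atoms$atom == "CA")
  ref_ca <- NULL
  if (!is.null(reference)) {
    if (inherits(reference, "peptide_structure")) {
      ref_ca <- coords(reference)[which(reference$atoms$atom == "CA"), ,
                                  drop = FALSE]
    } else {
      ref_xyz <- as.matrix(reference)
      ref_ca <- if (nrow(ref_xyz) == nrow(lxyz0))
        ref_xyz[ca_rows, , drop = FALSE] else ref_xyz
    }
    if (nrow(ref_ca) != length(ca_rows))
      stop("reference pose does not match the ligand residue count")
  }
  rows <- vector("list", n_poses)
  tfs <- vector("list", n_poses)
  for (i in seq_len(n_poses)) {
    p <- refine_pose(receptor, ligand, starts[[i]], restraints, params,
                     schedule, seed = NULL)  # continue the seeded RNG stream
    lxyz <- apply_transform(lxyz0, p$transform)
    nc <- compute_contacts(rxyz, lxyz, contact_spec,
                           elems_a = receptor$atoms$elem,
                           elems_b = ligand$atoms$elem)
    rmsd <- if (is.null(ref_ca)) NA_real_
            else ligand_rmsd(lxyz[ca_rows, , drop = FALSE], ref_ca)
    tfs[[i]] <- p$transform
    rows[[i]] <- data.frame(E_vdw = p$E_vdw, E_elec = p$E_elec,
                            E_air = p$E_air, E_total = p$E_total,
                            contacts = nc, rmsd = rmsd)
  }
  poses <- do.call(rbind, rows)
  ord <- order(poses$E_total)
  poses <- poses[ord, , drop = FALSE]
  poses <- cbind(pose_id = sprintf("pose%03d", seq_len(n_poses)), poses)
  rownames(poses) <- NULL
  structure(list(poses = poses, transforms = tfs[ord], ligand = ligand,
                 seed = seed, params = params, schedule = schedule),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("Pose set: %d poses of %s (seed %s)\n", nrow(x$poses),
              x$ligand$sequence, format(x$seed)))
  cat(sprintf("  E_total: best %.2f, mean %.2f kcal/mol; mean contacts %.1f\n",
              min(x$poses$E_total), mean(x$poses$E_total),
              mean(x$poses$contacts)))
  invisible(x)
}

#' @export
summary.pose_set <- function(object, ...) {
  p <- object$poses
  out <- data.frame(
    term = c("E_vdw", "E_elec", "E_air", "E_total", "contacts", "rmsd"),
    mean = vapply(p[, c("E_vdw", "E_elec", "E_air", "E_total", "contacts",
                        "rmsd")], mean, numeric(1)),
    sd = vapply(p[, c("E_vdw", "E_elec", "E_air", "E_total", "contacts",
                      "rmsd")], stats::sd, numeric(1)),
    min = vapply(p[, c("E_vdw", "E_elec", "E_air", "E_total", "contacts",
                       "rmsd")], min, numeric(1)))
  rownames(out) <- NULL
  out
}

#' Extract the ligand coordinates of one pose
#'
#' @param pose_set A `pose_set`.
#' @param i Pose rank (1 = lowest E_total).
#' @return n x 3 coordinate matrix of the posed ligand.
#' @export
pose_coords <- function(pose_set, i = 1L) {
  apply_transform(coords(pose_set$ligand), pose_set$transforms[[i]])
}
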