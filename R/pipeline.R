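# End-to-end pipeline: enumerate -> build -> restrain -> dock -> aggregate
# -> window -> heatmap -> exclusion proposal -> reports.

#' Pipeline run configuration
#'
#' @param receptor A receptor `peptide_structure` or a PDB path.
#' @param chain_a,chain_b Chains carrying the CDR3-alpha/beta loops.
#' @param cdr3a,cdr3b Length-2 residue ranges of the loops (structure
#'   numbering).
#' @param template An [antigen_template()].
#' @param dihedrals A [dihedral_table()] or CSV path.
#' @param alphabet_file Optional alternative SCAA table CSV.
#' @param exclusions Per-position exclusions for [library_spec()].
#' @param restraint_lower,restraint_upper,restraint_k AIR parameters.
#' @param restraint_mode `"grouped"` or `"split"` (see [make_default_airs()]).
#' @param params A [scoring_params()].
#' @param schedule An [mc_schedule()].
#' @param n_poses Poses per peptide (default 100).
#' @param seed Base integer seed; peptide `i` is docked with seed
#'   `seed + i - 1`.
#' @param contact_cutoff Contact cutoff in Angstrom.
#' @param sigma_mode `"sd"` or `"sem"` for the binder window.
#' @param heatmap_subset `"window"` (default: window members only) or
#'   `"all"`.
#' @param reference_triad Optional natural triad to flag.
#' @param reference_pose Optional reference ligand coordinates (matrix or
#'   `peptide_structure`) for per-pose RMSD.
#' @param outdir Optional output directory; when given, results/heatmap
#'   CSVs, a JSON report and a config echo are written.
#' @return Object of class `run_config`.
#' @export
run_config <- function(receptor, chain_a = "R", chain_b = "S",
                       cdr3a = c(1, 7), cdr3b = c(1, 7),
                       template = antigen_template(),
                       dihedrals = dihedral_table(template$length),
                       alphabet_file = NULL, exclusions = list(),
                       restraint_lower = 4, restraint_upper = 8,
                       restraint_k = 50,
                       restraint_mode = c("grouped", "split"),
                       params = scoring_params(), schedule = mc_schedule(),
                       n_poses = 100L, seed = 1L, contact_cutoff = 6.0,
                       sigma_mode = c("sd", "sem"),
                       heatmap_subset = c("window", "all"),
                       reference_triad = NULL, reference_pose = NULL,
                       outdir = NULL) {
  if (is.character(receptor)) receptor <- read_structure(receptor)
  if (is.character(dihedrals)) dihedrals <- dihedral_table(file = dihedrals)
  structure(list(receptor = receptor, chain_a = chain_a, chain_b = chain_b,
                 cdr3a = cdr3a, cdr3b = cdr3b, template = template,
                 dihedrals = dihedrals, alphabet_file = alphabet_file,
                 exclusions = exclusions,
                 restraint_lower = restraint_lower,
                 restraint_upper = restraint_upper,
                 restraint_k = restraint_k,
                 restraint_mode = match.arg(restraint_mode),
                 params = params, schedule = schedule,
                 n_poses = as.integer(n_poses), seed = as.integer(seed),
                 contact_cutoff = contact_cutoff,
                 sigma_mode = match.arg(sigma_mode),
                 heatmap_subset = match.arg(heatmap_subset),
                 reference_triad = reference_triad,
                 reference_pose = reference_pose, outdir = outdir),
            class = "run_config")
}

# Polynomial rolling hash of the serialized scalar configuration, for
# output provenance lines.
config_hash <- function(config) {
  keep <- config[!vapply(config, is.object, logical(1))]
  keep$receptor <- NULL; keep$reference_pose <- NULL; keep$outdir <- NULL
  s <- jsonlite::toJSON(keep, auto_unbox = TRUE, force = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[scaadock] ", fmt), ...))
}

#' Run the full screening pipeline
#'
#' Stages, in order: enumerate the SCAA library, build each peptide, set up
#' the default AIRs, dock every peptide (`n_poses` each, per-peptide seeds
#' `seed + i - 1`), count contacts and RMSDs, aggregate pose ensembles into
#' per-peptide records, select the +-sigma best-binder window, build the
#' positional residual-energy heatmap and propose per-position exclusions.
#' Fully reproducible given the base seed.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress to stderr.
#' @return List: `library`, `records`, `window`, `heatmap`, `exclusions`,
#'   `reduced_size`, `pose_sets`, `config`, and (when `outdir` is set)
#'   `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  table <- scaa_table(config$alphabet_file)
  receptor <- annotate_receptor(config$receptor, config$cdr3a, config$cdr3b,
                                config$chain_a, config$chain_b)
  spec <- library_spec(exclusions = config$exclusions,
                       template = config$template)
  lib <- enumerate_library(spec)
  pipeline_log(verbose, "library: %d peptides", nrow(lib))
  restraints <- make_default_airs(config$template, receptor,
                                  lower = config$restraint_lower,
                                  upper = config$restraint_upper,
                                  k = config$restraint_k,
                                  mode = config$restraint_mode)
  pipeline_log(verbose, "restraints: %d AIRs", length(restraints))
  cspec <- contact_spec(config$contact_cutoff)
  pose_sets <- vector("list", nrow(lib))
  records <- vector("list", nrow(lib))
  for (i in seq_len(nrow(lib))) {
    triad <- c(lib$p1[i], lib$p2[i], lib$p3[i])
    ligand <- build_library_peptide(triad, config$template, config$dihedrals)
    ps <- dock_peptide(receptor, ligand, restraints, config$params,
                       n_poses = config$n_poses, seed = config$seed + i - 1L,
                       schedule = config$schedule,
                       reference = config$reference_pose,
                       contact_spec = cspec)
    pose_sets[[i]] <- ps
    records[[i]] <- aggregate_poses(ps, triad)
    if (verbose && (i %% 25L == 0L))
      pipeline_log(verbose, "docked %d/%d peptides", i, nrow(lib))
  }
  records <- do.call(rbind, records)
  records <- cbind(peptide_id = lib$peptide_id, records)
  window <- select_best_binders(records, sigma = config$sigma_mode)
  records$in_window <- window$members
  records$is_translated_reference <- FALSE
  ref_in_window <- NA
  if (!is.null(config$reference_triad)) {
    records <- flag_reference(records, config$reference_triad, table, window)
    ref_in_window <- attr(records, "reference_in_window")
  }
  hm_subset <- if (config$heatmap_subset == "window") window$members else NULL
  heatmap <- positional_heatmap(records, subset = hm_subset,
                                positions = paste0("P",
                                  config$template$triad_positions))
  exclusions <- propose_exclusions(heatmap)
  reduced_size <- library_size(lengths(library_spec(
    exclusions = exclusions, template = config$template)$effective))
  pipeline_log(verbose, "window: %d members; proposed exclusions: %s",
               sum(window$members),
               if (length(exclusions))
                 paste(names(exclusions),
                       vapply(exclusions, paste, "", collapse = ","),
                       sep = ":", collapse = " ")
               else "none")
  out <- list(library = lib, records = records, window = window,
              heatmap = heatmap, exclusions = exclusions,
              reduced_size = reduced_size, pose_sets = pose_sets,
              reference_in_window = ref_in_window, config = config,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$outdir)) out$paths <- write_pipeline_outputs(out)
  out
}

write_pipeline_outputs <- function(result) {
  config <- result$config
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- sprintf("# scaadock run: config %s, seed %d", hash, config$seed)
  paths <- list()
  write_commented_csv <- function(df, file) {
    path <- file.path(config$outdir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  paths$results <- write_commented_csv(result$records, "results.csv")
  hm <- result$heatmap
  hm_df <- data.frame(class = rep(rownames(hm), ncol(hm)),
                      position = rep(colnames(hm), each = nrow(hm)),
                      mean_E = as.vector(unclass(hm)),
                      n = as.vector(attr(hm, "n")))
  paths$heatmap <- write_commented_csv(hm_df, "heatmap.csv")
  report <- list(config_hash = hash, seed = config$seed,
                 n_peptides = nrow(result$records),
                 window = result$window[c("E_center", "E_sigma", "C_center",
                                          "C_sigma", "sigma_mode")],
                 n_window_members = sum(result$window$members),
                 reference_in_window = result$reference_in_window,
                 exclusions = result$exclusions,
                 reduced_size = result$reduced_size)
  paths$report <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  paths$config <- file.path(config$outdir, "config.json")
  cfg <- config[!vapply(config, is.object, logical(1))]
  cfg$receptor <- NULL; cfg$reference_pose <- NULL
  jsonlite::write_json(c(list(config_hash = hash), cfg), paths$config,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  paths
}
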