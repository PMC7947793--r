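# Rigid-body docking: scoring, sampling, refinement, determinism.

test_that("pair scoring matches the brute-force double loop on small fixtures", {
  set.seed(31)
  for (i in 1:5) {
    nl <- sample(10:25, 1); nr <- sample(10:25, 1)
    lig <- fake_structure(rnorm(3 * nl, sd = 4),
                          sample(c("C", "N", "O", "S"), nl, replace = TRUE))
    rec <- fake_structure(rnorm(3 * nr, sd = 4) + 2,
                          sample(c("C", "N", "O", "S"), nr, replace = TRUE))
    e <- score_pose(rec, lig)
    lff <- scaadock:::assign_ff(lig); rff <- scaadock:::assign_ff(rec)
    oracle <- oracle_pair_energy(coords(lig), coords(rec), lff, rff)
    expect_equal(e$E_vdw, oracle$E_vdw, tolerance = 1e-9)
    expect_equal(e$E_elec, oracle$E_elec, tolerance = 1e-9)
  }
})

test_that("two neutral atoms at the LJ minimum score -epsilon", {
  sig <- 3.20  # carbon sigma of the parameter table
  rmin <- 2^(1 / 6) * sig
  lig <- fake_structure(c(0, 0, 0), "C")
  rec <- fake_structure(c(rmin, 0, 0), "C")
  e <- score_pose(rec, lig)
  expect_equal(e$E_vdw, -0.10, tolerance = 1e-9)
  expect_equal(e$E_elec, 0)
})

test_that("a ligand beyond the cutoff scores only its restraint energy", {
  fx <- get_fixture()
  far <- rigid_transform(diag(3), c(200, 0, 0))
  e <- score_pose(fx$receptor, fx$ligand, far, fx$restraints)
  expect_equal(e$E_vdw, 0)
  expect_equal(e$E_elec, 0)
  expect_gt(e$E_air, 0)
  expect_equal(e$E_total, e$E_air)
})

test_that("scoring is invariant under a common rigid transform", {
  fx <- get_fixture()
  e0 <- score_pose(fx$receptor, fx$ligand, fx$planted, fx$restraints)
  R <- scaadock:::rotation_about_axis(c(1, -2, 0.5), 37)
  t <- c(5, -3, 11)
  rec2 <- fx$receptor
  rec2$atoms[, c("x", "y", "z")] <- apply_transform(coords(fx$receptor),
                                                    rigid_transform(R, t))
  tf2 <- scaadock:::compose_transform(rigid_transform(R, t), fx$planted)
  e1 <- score_pose(rec2, fx$ligand, tf2, fx$restraints)
  for (term in c("E_vdw", "E_elec", "E_air", "E_total"))
    expect_equal(e1[[term]], e0[[term]], tolerance = 1e-9)
})

test_that("E_air vanishes exactly when every restraint is inside its bounds", {
  fx <- get_fixture()
  d <- planted_deff(fx)
  expect_true(all(d >= 4 & d <= 8))
  e <- score_pose(fx$receptor, fx$ligand, fx$planted, fx$restraints)
  expect_identical(e$E_air, 0)
})

test_that("initial pose sampling is seeded, sized and near the AIR shell", {
  fx <- get_fixture()
  expect_identical(sample_initial_poses(fx$receptor, fx$ligand, fx$restraints,
                                        0, seed = 1), list())
  a <- sample_initial_poses(fx$receptor, fx$ligand, fx$restraints, 5, seed = 4)
  b <- sample_initial_poses(fx$receptor, fx$ligand, fx$restraints, 5, seed = 4)
  expect_identical(a, b)
  # most starting poses already satisfy the flat-bottom AIR window
  tfs <- sample_initial_poses(fx$receptor, fx$ligand, fx$restraints, 1000,
                              seed = 11)
  ea <- vapply(tfs, function(tf)
    score_pose(fx$receptor, fx$ligand, tf, fx$restraints)$E_air, numeric(1))
  expect_gte(mean(ea == 0), 0.5)
})

test_that("refinement is monotone in the best-visited energy", {
  fx <- get_fixture()
  e0 <- score_pose(fx$receptor, fx$ligand, fx$planted, fx$restraints)
  # zero steps: the scored input pose comes back unchanged
  r0 <- refine_pose(fx$receptor, fx$ligand, fx$planted, fx$restraints,
                    schedule = mc_schedule(steps = 0))
  expect_identical(r0$transform, fx$planted)
  expect_equal(r0$E_total, e0$E_total)
  r1 <- refine_pose(fx$receptor, fx$ligand, fx$planted, fx$restraints,
                    schedule = mc_schedule(steps = 400), seed = 5)
  expect_lte(r1$E_total, e0$E_total)
})

test_that("docking is bit-reproducible under a fixed seed", {
  fx <- get_fixture()
  sched <- mc_schedule(steps = 150)
  a <- dock_peptide(fx$receptor, fx$ligand, fx$restraints, n_poses = 4,
                    seed = 9, schedule = sched, reference = fx$planted_coords)
  b <- dock_peptide(fx$receptor, fx$ligand, fx$restraints, n_poses = 4,
                    seed = 9, schedule = sched, reference = fx$planted_coords)
  expect_identical(a$poses, b$poses)
  expect_identical(a$transforms, b$transforms)
  expect_identical(nrow(a$poses), 4L)
  expect_false(is.unsorted(a$poses$E_total))
  one <- dock_peptide(fx$receptor, fx$ligand, fx$restraints, n_poses = 1,
                      seed = 2, schedule = mc_schedule(steps = 0))
  expect_identical(nrow(one$poses), 1L)
})

test_that("missing force-field annotation names the offending atom", {
  bad <- fake_structure(c(0, 0, 0), "Z", atom = "ZN1")
  expect_error(score_pose(bad, fake_structure(c(3, 0, 0), "C")), "ZN1")
})
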