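# Ambiguous interaction restraints: construction, aggregation, energetics,
# export.

test_that("default AIRs group the anchor atoms against the loop centers", {
  rec <- make_mock_receptor(1)
  airs <- make_default_airs(antigen_template(), rec)
  expect_length(airs, 2L)
  for (a in airs) {
    expect_identical(nrow(a$pairs), 3L)
    expect_equal(a$lower, 4)
    expect_equal(a$upper, 8)
  }
  expect_identical(airs[[1]]$pairs$lig_resno, c(2L, 3L, 4L))
  expect_identical(airs[[1]]$pairs$lig_atom, c("CA", "CB", "CA"))
  expect_identical(airs[[2]]$pairs$lig_resno, c(4L, 5L, 6L))
  expect_identical(unique(airs[[1]]$pairs$rec_resno), 4L)  # center of 1..7
  split <- make_default_airs(antigen_template(), rec, mode = "split")
  expect_length(split, 6L)
  expect_true(all(vapply(split, function(r) nrow(r$pairs), integer(1)) == 1L))
})

test_that("loop centers use the lower median and glycine slots degrade to CA", {
  expect_identical(scaadock:::cdr3_center(c(10, 17)), 13L)  # even length
  expect_identical(scaadock:::cdr3_center(c(10, 16)), 13L)
  rec <- make_mock_receptor(1)
  # triad at 4,6,8 leaves P3 and P5 as glycine spacers: their CB pairs
  # degrade to CA with a warning
  w <- capture_warnings(airs <- make_default_airs(
    antigen_template(triad_positions = c(4, 6, 8)), rec))
  expect_length(w, 2L)          # both CB slots (P3, P5) fall on glycine
  expect_match(w, "degraded", all = TRUE)
  expect_identical(airs[[1]]$pairs$lig_atom, c("CA", "CA", "CA"))
  expect_error(make_default_airs(antigen_template(length = 5,
                                                  triad_positions = c(2, 3, 4)),
                                 rec), "at least 6")
})

test_that("effective distance follows the r^-6 aggregate", {
  r1 <- air_restraint(data.frame(lig_resno = 1, lig_atom = "X",
                                 rec_chain = "R", rec_resno = 1,
                                 rec_atom = "Y"))
  # single pair at 5 A
  expect_equal(effective_distance(r1, matrix(c(0, 0, 0), 1),
                                  matrix(c(5, 0, 0), 1),
                                  idx = cbind(lig = 1L, rec = 1L)), 5)
  # two pairs both at 5 A -> 5 * 2^(-1/6)
  idx2 <- cbind(lig = c(1L, 2L), rec = c(1L, 1L))
  lig2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(effective_distance(r1, lig2, matrix(c(5, 0, 0), 1), idx = idx2),
               5 * 2^(-1 / 6), tolerance = 1e-12)
  # 4 A and 100 A -> min-distance domination
  lig3 <- rbind(c(1, 0, 0), c(-95, 0, 0))
  expect_equal(effective_distance(r1, lig3, matrix(c(5, 0, 0), 1), idx = idx2),
               4, tolerance = 1e-6)
})

test_that("aggregation is monotone and bounded by the closest pair", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    lig <- matrix(rnorm(3 * n, sd = 5), n)
    rec <- matrix(rnorm(3, sd = 5), 1)
    r <- air_restraint(data.frame(lig_resno = 1, lig_atom = "X",
                                  rec_chain = "R", rec_resno = 1,
                                  rec_atom = "Y"))
    dmin <- min(sqrt(rowSums(sweep(lig, 2, rec)^2)))
    idx_all <- cbind(lig = seq_len(n), rec = rep(1L, n))
    d_all <- effective_distance(r, lig, rec, idx = idx_all)
    expect_lt(d_all, dmin)
    # dropping a pair never decreases the effective distance
    idx_sub <- idx_all[-sample(n, 1), , drop = FALSE]
    expect_gte(effective_distance(r, lig, rec, idx = idx_sub), d_all)
  }
})

test_that("flat-bottom energy is zero inside and harmonic outside", {
  r <- air_restraint(data.frame(lig_resno = 1, lig_atom = "X",
                                rec_chain = "R", rec_resno = 1,
                                rec_atom = "Y"), lower = 4, upper = 8, k = 1)
  expect_equal(restraint_energy(r, 6), 0)
  expect_equal(restraint_energy(r, 4), 0)   # boundary included
  expect_equal(restraint_energy(r, 8), 0)
  expect_equal(restraint_energy(r, 9), 1)
  r50 <- air_restraint(r$pairs, 4, 8, k = 50)
  expect_equal(restraint_energy(r50, 3), 50)
  # continuity and monotone growth in the violation
  d <- seq(2, 12, by = 0.01)
  e <- restraint_energy(r, d)
  expect_true(all(diff(e[d < 4]) <= 0))
  expect_true(all(diff(e[d > 8]) >= 0))
  expect_lt(max(abs(diff(e))), 0.2)   # no jumps on a 0.01 A grid
  expect_error(restraint_energy(r, -1), "positive")
  expect_error(air_restraint(r$pairs, lower = 8, upper = 4), "lower")
})

test_that("restraints export to the assign-statement dialect and JSON", {
  rec <- make_mock_receptor(1)
  airs <- make_default_airs(antigen_template(), rec)
  lines <- export_airs_table(airs)
  txt <- paste(lines, collapse = "\n")
  expect_match(txt, "6.0 2.0 2.0", fixed = TRUE)  # bounds [4,8] as center/+-
  expect_match(txt, "segid A and resid 3 and name CB", fixed = TRUE)
  expect_match(txt, "segid R and resid 4 and name CA", fixed = TRUE)
  split <- make_default_airs(antigen_template(), rec, mode = "split")
  lines1 <- export_airs_table(split)
  expect_length(lines1, 6L)
  expect_true(all(grepl("^assign \\(segid", lines1)))
  js <- jsonlite::fromJSON(export_airs_json(airs), simplifyVector = TRUE)
  expect_identical(nrow(js), 2L)
  expect_equal(js$lower, c(4, 4))
  expect_equal(js$k, c(50, 50))
})
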