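# Pose-ensemble aggregation, best-binder window, heatmaps, reductions.

test_that("pose aggregation computes ensemble statistics exactly", {
  p <- data.frame(E_total = c(-10, -12, -14), contacts = c(100, 110, 120),
                  rmsd = c(1, 2, 3))
  r <- aggregate_poses(p, triad = c("Q", "V", "H"))
  expect_equal(r$E_mean, -12)
  expect_equal(r$E_sd, 2)                    # sample SD, ddof = 1
  expect_equal(r$E_sem, 2 / sqrt(3))
  expect_equal(r$C_mean, 110)
  expect_identical(r$triad, "QVH")
  single <- aggregate_poses(data.frame(E_total = -5, contacts = 10, rmsd = 1),
                            triad = c("V", "V", "V"))
  expect_equal(single$E_sd, 0)               # SD of one observation is 0
  expect_equal(single$E_sem, 0)
  expect_error(aggregate_poses(p[0, ], triad = c("V", "V", "V")), "empty")
})

test_that("aggregation matches an independent arithmetic oracle", {
  set.seed(41)
  p <- data.frame(E_total = rnorm(100, -12, 3),
                  contacts = rpois(100, 250), rmsd = runif(100, 0, 4))
  r <- aggregate_poses(p, triad = c("S", "Y", "D"))
  expect_equal(r$E_mean, sum(p$E_total) / 100, tolerance = 1e-12)
  expect_equal(r$E_sd, sqrt(sum((p$E_total - mean(p$E_total))^2) / 99),
               tolerance = 1e-12)
  expect_equal(r$E_sem, r$E_sd / 10, tolerance = 1e-12)
  expect_equal(r$C_sd, stats::sd(p$contacts), tolerance = 1e-12)
  expect_equal(r$rmsd_best, min(p$rmsd))
})

test_that("the +-sigma window uses closed boundaries and exact membership", {
  rec <- data.frame(triad = c("AAA", "BBB", "CCC", "DDD"),
                    E_mean = c(-10, -10, -10, -10),
                    C_mean = c(100, 100, 100, 100))
  w <- select_best_binders(rec)
  expect_true(all(w$members))   # identical records: everyone is central
  # a record exactly at center + sigma is a member (closed interval)
  rec2 <- data.frame(triad = sprintf("t%02d", 1:21),
                     E_mean = c(rep(-10, 20), -10 + 21 / sqrt(20) * 0.9),
                     C_mean = 100)
  w2 <- select_best_binders(rec2)
  members <- abs(rec2$E_mean - w2$E_center) <= w2$E_sigma &
    abs(rec2$C_mean - w2$C_center) <= w2$C_sigma
  expect_identical(w2$members, members)
  expect_error(select_best_binders(rec[1, ]), "2 records")
})

test_that("window membership fraction on independent normals is ~0.466", {
  set.seed(47)
  n <- 10000
  rec <- data.frame(triad = sprintf("t%05d", 1:n),
                    E_mean = rnorm(n), C_mean = rnorm(n))
  w <- select_best_binders(rec)
  expect_equal(mean(w$members), (pnorm(1) - pnorm(-1))^2,
               tolerance = 0.02 / 0.466)
  # sem mode shrinks the window to near-zero membership
  wsem <- select_best_binders(rec, sigma = "sem")
  expect_lt(mean(wsem$members), 0.05)
})

test_that("the translated reference is flagged by triad lookup", {
  rec <- make_synthetic_records(n = 216, seed = 13)
  fl <- flag_reference(rec, c("N", "V", "R"))
  expect_identical(rec$triad[fl$is_translated_reference], "QVH")
  fl2 <- flag_reference(rec, c("Y", "V", "E"))
  expect_identical(rec$triad[fl2$is_translated_reference], "YVD")
  fl3 <- flag_reference(rec, c("D", "Q", "H"))   # already SCAA: flags itself
  expect_identical(rec$triad[fl3$is_translated_reference], "DQH")
  w <- select_best_binders(rec)
  fl4 <- flag_reference(rec, c("N", "V", "R"), window = w)
  expect_identical(attr(fl4, "reference_in_window"),
                   w$members[rec$triad == "QVH"])
  expect_error(flag_reference(rec[1:5, ], c("N", "V", "R")), "not present")
})

test_that("positional heatmaps are 6 x 3 grouped means, order-invariant", {
  rec <- make_synthetic_records(n = 216, seed = 17)
  hm <- positional_heatmap(rec)
  expect_identical(dim(unclass(hm)), c(6L, 3L))
  expect_identical(rownames(hm), c("D", "Q", "H", "S", "Y", "V"))
  # occupancy per position sums to the number of contributing records
  expect_equal(unname(colSums(attr(hm, "n"))), rep(216, 3))
  # brute-force group means
  for (j in 1:3) for (s in rownames(hm)) {
    sel <- substr(rec$triad, j, j) == s
    expect_equal(unclass(hm)[s, j], mean(rec$E_mean[sel]), tolerance = 1e-12)
  }
  shuffled <- positional_heatmap(rec[sample(nrow(rec)), ])
  expect_equal(unclass(shuffled), unclass(hm), tolerance = 1e-12)
  # empty cells are missing, not zero
  sub <- rec[substr(rec$triad, 1, 1) != "D", ]
  hm2 <- positional_heatmap(sub)
  expect_true(is.na(unclass(hm2)["D", "P3"]))
})

test_that("exclusion proposals take positional maxima, never minima or ties", {
  m <- matrix(0, 6, 3, dimnames = list(c("D", "Q", "H", "S", "Y", "V"),
                                       c("P3", "P5", "P8")))
  m["S", "P5"] <- 10; m["D", "P8"] <- 10
  m["Y", "P3"] <- 10; m["V", "P3"] <- 10   # tie at P3: propose nothing
  hm <- structure(m, n = matrix(36L, 6, 3), class = c("scaa_heatmap", "matrix"))
  expect_identical(propose_exclusions(hm), list(P5 = "S", P8 = "D"))
  flat <- structure(matrix(-5, 6, 3, dimnames = dimnames(m)),
                    n = matrix(36L, 6, 3), class = c("scaa_heatmap", "matrix"))
  expect_identical(propose_exclusions(flat), list())
  # a strict positional minimum is never excluded
  m2 <- matrix(0, 6, 3, dimnames = dimnames(m))
  m2["Q", "P5"] <- -10; m2["S", "P5"] <- 10
  hm2 <- structure(m2, n = matrix(36L, 6, 3), class = c("scaa_heatmap", "matrix"))
  ex <- propose_exclusions(hm2)
  expect_false("Q" %in% unlist(ex))
})

test_that("plots render without error", {
  rec <- make_synthetic_records(n = 216, seed = 19)
  w <- select_best_binders(rec)
  rec <- flag_reference(rec, c("N", "V", "R"), window = w)
  hm <- positional_heatmap(rec, subset = w$members)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot_energy_contact_map(rec, w))
  expect_silent(plot(hm))
})
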