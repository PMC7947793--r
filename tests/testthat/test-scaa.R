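# The six-letter alphabet: translation, template projection, re-expansion.

test_that("attested residue and triad translations are reproduced", {
  # all 14 residue translations readable from the benchmark table and the
  # superantigen passage
  attested <- c(N = "Q", V = "V", R = "H", T = "S", Q = "Q", K = "H",
                G = "V", D = "D", A = "V", P = "V", F = "Y", Y = "Y",
                E = "D", L = "V")
  for (nat in names(attested))
    expect_identical(translate_residue(nat), unname(attested[nat]))
  # benchmark reference triads -> translated triads
  triads <- list(list(c("N", "V", "R"), c("Q", "V", "H")),
                 list(c("T", "Q", "K"), c("S", "Q", "H")),
                 list(c("G", "D", "R"), c("V", "D", "H")),
                 list(c("A", "G", "P"), c("V", "V", "V")),
                 list(c("Q", "F", "Q"), c("Q", "Y", "Q")),
                 list(c("Y", "R", "Q"), c("Y", "H", "Q")),
                 list(c("Y", "V", "E"), c("Y", "V", "D")))
  for (tr in triads)
    expect_identical(translate_triad(tr[[1]]), tr[[2]])
})

test_that("translation is idempotent on all 20 codes", {
  tab <- scaa_table()
  for (nat in names(tab)) {
    once <- translate_residue(nat, tab)
    expect_identical(translate_residue(once, tab), once)
  }
})

test_that("unknown residues are rejected with the offending code named", {
  expect_error(translate_residue("B"), "B")
  expect_error(translate_residue("Z"), "Z")
  expect_error(translate_triad(c("A", "X", "C")), "position 2")
})

test_that("template projection replaces anchors with G and translates the triad", {
  expect_identical(project_to_template("FKLILTYKL"), "GGVGVGGHG")
  expect_identical(project_to_template("FKLITTYKL"), "GGVGSGGHG")
  expect_identical(project_to_template("GGGGGGGGG"), "GGVGVGGVG")
  expect_error(project_to_template("FKLILT"), "length")
})

test_that("projection always matches the template pattern", {
  tab <- scaa_table()
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(names(tab), 9, replace = TRUE), collapse = "")
    p <- project_to_template(s)
    expect_match(p, "^GG[DQHSYV]G[DQHSYV]GG[DQHSYV]G$")
  }
})

test_that("the 18 superantigen variants collapse to exactly two model peptides", {
  vars <- superantigen_variants()
  expect_length(vars, 18L)
  expect_identical(unique_translated_set(vars),
                   c("GGVGSGGHG", "GGVGVGGHG"))
})

test_that("unique_translated_set handles empty and singleton inputs", {
  expect_identical(unique_translated_set(character(0)), character(0))
  expect_identical(unique_translated_set("FKLILTYKL"), "GGVGVGGHG")
})

test_that("class expansion partitions the 20 natural codes", {
  tab <- scaa_table()
  images <- lapply(c("D", "Q", "H", "S", "Y", "V"), expand_to_natural, tab)
  expect_identical(sort(unlist(images)), sort(names(tab)))  # cover, disjoint
  expect_identical(expand_to_natural("H"), c("H", "K", "R"))
  expect_true(all(c("D", "E") %in% expand_to_natural("D")))
  expect_error(expand_to_natural("B"), "not an SCAA letter")
})

test_that("template positions can be counted from either terminus", {
  tn <- antigen_template()
  tc <- antigen_template(numbering = "C")
  # P3,P5,P8 from the C terminus of a 9-mer are positions 2,5,7 from the N
  expect_identical(tc$triad_positions, c(2L, 5L, 7L))
  expect_identical(tn$triad_positions, c(3L, 5L, 8L))
  expect_error(antigen_template(triad_positions = c(3, 3, 8)), "distinct")
})

test_that("an alternative alphabet can be loaded from file and is validated", {
  tab <- scaa_table()
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(natural = names(tab), scaa = unclass(tab)),
                   tmp, row.names = FALSE)
  expect_identical(unclass(scaa_table(tmp))[names(tab)],
                   unclass(tab)[names(tab)])
  bad <- data.frame(natural = names(tab), scaa = unclass(tab))
  bad$scaa[bad$natural == "Q"] <- "V"   # Q must be a fixed point
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(scaa_table(tmp), "idempotent")
})
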