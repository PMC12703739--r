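make_two_chain_structure <- function() {
  afm_structure(tibble::tibble(
    chain = rep(c("A", "B"), each = 6),
    resno = rep(rep(1:3, each = 2), 2),
    resname = rep(c("ALA", "GLY", "LEU"), each = 2, times = 2),
    atom = rep(c("N", "CA"), 6),
    element = rep(c("N", "C"), 6),
    x = seq(0, 5.5, by = 0.5), y = rep(1.25, 12), z = rep(-3, 12)
  ), model_id = "toy")
}

test_that("structures round-trip through PDB with counts, ids and coordinates intact", {
  s <- make_two_chain_structure()
  expect_equal(nrow(structure_chains(s)), 2)
  expect_equal(nrow(structure_residues(s)), 6)

  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_equal(structure_residues(s2)[, c("chain", "resno", "resname")],
               structure_residues(s)[, c("chain", "resno", "resname")])
  expect_equal(as.matrix(s2[, c("x", "y", "z")]), as.matrix(s[, c("x", "y", "z")]),
               tolerance = 1e-3)
})

test_that("random helix structures survive write/read to PDB precision", {
  set.seed(11)
  for (i in 1:3) {
    h <- make_ideal_helix(10 + i, axis_origin = rnorm(3, sd = 5),
                          axis_direction = rnorm(3), phase = runif(1, 0, 360),
                          sequence = random_aa_seq(10 + i))
    path <- withr::local_tempfile(fileext = ".pdb")
    write_structure(h, path)
    h2 <- read_structure(path)
    expect_equal(nrow(h2), nrow(h))
    expect_lt(max(abs(as.matrix(h2[, c("x","y","z")]) - as.matrix(h[, c("x","y","z")]))),
              1e-3 + 1e-9)
  }
})

test_that("pathological PDB input is rejected with clear errors", {
  water <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), water)
  expect_error(read_structure(water), "zero protein residues")

  ins <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   1A      3.800   0.000   0.000  1.00  0.00           C",
    "END"
  ), ins)
  expect_error(read_structure(ins), "insertion codes")

  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")), "not found")
})

test_that("author numbering is preserved as metadata while indices are 1-based", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  17       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  19       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  LEU A  25       7.600   0.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  s <- read_structure(path)
  expect_equal(s$resno, 1:3)
  expect_equal(s$author_resno, c(17L, 19L, 25L))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C",
    "END"
  ), path)
  s <- read_structure(path)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 9.0)
})

test_that("all three confidence dialects canonicalise to identical data", {
  set.seed(7)
  n <- 4
  plddt <- round(runif(n, 60, 100), 3)
  pae <- round(matrix(runif(n * n, 0, 20), n, n), 3)

  plain <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = plddt, pae = pae), plain, digits = NA)
  af <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = plddt, predicted_aligned_error = pae),
                       af, digits = NA)
  idx <- expand.grid(r2 = 1:n, r1 = 1:n)  # column-major sweep
  afdb <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    residue1 = idx$r1, residue2 = idx$r2,
    distance = pae[cbind(idx$r1, idx$r2)], plddt = plddt
  )), afdb, digits = NA)

  c1 <- read_confidence(plain, "plain")
  c2 <- read_confidence(af, "af_pkl_json")
  c3 <- read_confidence(afdb, "afdb")
  expect_identical(c1$plddt, c2$plddt)
  expect_identical(c1$pae, c2$pae)
  expect_identical(c1$plddt, c3$plddt)
  expect_identical(c1$pae, c3$pae)
})

test_that("confidence dimension and range violations are rejected", {
  expect_error(afm_confidence(rep(90, 4), matrix(5, 5, 5)), "dimension mismatch")
  expect_error(afm_confidence(rep(90, 3), matrix(-1, 3, 3)), ">= 0")
  expect_error(afm_confidence(rep(150, 3), matrix(5, 3, 3)), "\\[0, 100\\]")
  # constant plain file: 4 residues at pLDDT 90, PAE 5
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = rep(90, 4), pae = matrix(5, 4, 4)), path)
  conf <- read_confidence(path, "plain")
  expect_equal(conf$pae, matrix(5, 4, 4))
  # attaching to a structure with a different residue count fails
  expect_error(attach_confidence(conf, make_two_chain_structure()), "dimension mismatch")
})

test_that("FASTA io round-trips and rejects illegal residues", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MAK"), path)
  expect_equal(read_fasta(path), tibble::tibble(id = "a", sequence = "MAK"))

  set.seed(5)
  recs <- tibble::tibble(
    id = sprintf("rec%03d", 1:100),
    sequence = vapply(sample(10:120, 100, TRUE), random_aa_seq, character(1))
  )
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  expect_equal(read_fasta(out), recs)
  expect_true(all(nchar(readLines(out)) <= 61))  # 60-column wrap

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">b", "MABK"), bad)
  expect_error(read_fasta(bad), "illegal")
})
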