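# Build a bundle whose confidence metrics are exact (zero jitter), so
# threshold logic can be probed at chosen values.
exact_bundle <- function(complex_plddt, mask_plddt, pae_inter,
                         target_coverage = 0.8, orientation = "c_terminal",
                         seed = 71) {
  n_b <- 54; n_m <- 18
  plddt_binder <- (complex_plddt * (n_b + n_m) - mask_plddt * n_m) / n_b
  fx <- make_bundle_fixture(
    mask_length = n_m, target_coverage = target_coverage,
    orientation = orientation,
    plddt_binder = plddt_binder, plddt_mask = mask_plddt,
    pae_inter = pae_inter, jitter_sd = 0, seed = seed
  )
  list(binder_mask = fx$binder_mask, confidence = fx$confidence,
       binder_receptor = fx$binder_receptor, design_id = "exact")
}

test_that("a design meeting every criterion passes; one failing metric flips it", {
  rec <- evaluate_design(exact_bundle(91, 85, 7.0))
  expect_equal(rec$complex_plddt, 91, tolerance = 1e-9)
  expect_equal(rec$mask_plddt, 85, tolerance = 1e-9)
  expect_equal(rec$interchain_pae, 7.0, tolerance = 1e-9)
  expect_gte(rec$coverage, 0.6)
  expect_true(rec$orientation)
  expect_true(rec$passed)

  rec2 <- evaluate_design(exact_bundle(91, 85, 8.5))
  expect_false(rec2$pass_interchain_pae)
  expect_false(rec2$passed)
  expect_true(rec2$pass_complex_plddt)
})

test_that("inequality strictness at the printed thresholds: pLDDT strict, PAE inclusive", {
  at_thresholds <- evaluate_design(exact_bundle(90, 80, 8.0))
  expect_false(at_thresholds$pass_complex_plddt)  # 90 is not > 90
  expect_false(at_thresholds$pass_mask_plddt)     # 80 is not > 80
  expect_true(at_thresholds$pass_interchain_pae)  # 8 <= 8 passes
})

test_that("orientation and coverage criteria gate as configured", {
  wrong_way <- evaluate_design(exact_bundle(95, 88, 5, orientation = "n_terminal"))
  expect_false(wrong_way$pass_orientation)
  expect_false(wrong_way$passed)
  lax <- evaluate_design(exact_bundle(95, 88, 5, orientation = "n_terminal"),
                         triage_thresholds(require_c_terminal = FALSE))
  expect_true(lax$passed)

  low_cov <- evaluate_design(exact_bundle(95, 88, 5, target_coverage = 0.3))
  expect_false(low_cov$pass_coverage)
  tight <- evaluate_design(exact_bundle(95, 88, 5, target_coverage = 0.8),
                           triage_thresholds(min_coverage = 0.95))
  expect_false(tight$pass_coverage)
})

test_that("design RMSD gates only when a backbone model is supplied", {
  b <- exact_bundle(95, 88, 5)
  no_backbone <- evaluate_design(b)
  expect_true(is.na(no_backbone$design_rmsd))
  expect_true(no_backbone$passed)

  b$design_backbone <- b$binder_mask
  with_backbone <- evaluate_design(b)
  expect_equal(with_backbone$design_rmsd, 0, tolerance = 1e-9)
  expect_true(with_backbone$pass_design_rmsd)

  # a grossly distorted backbone fails the 1.5 A gate
  warped <- tibble::as_tibble(b$binder_mask)
  warped$x <- warped$x * 1.5
  b$design_backbone <- assign_roles(afm_structure(warped),
                                    c(A = "binder", B = "mask"))
  expect_false(evaluate_design(b)$pass_design_rmsd)

  b$design_backbone <- NULL
  b$confidence <- NULL
  expect_error(evaluate_design(b), "missing model")
})

test_that("planted pass/fail labels are recovered exactly on a small suite", {
  suite <- make_fixture_suite(n = 8, seed = 61)
  for (i in seq_len(8)) {
    fx <- suite$fixtures[[i]]
    rec <- evaluate_design(list(binder_mask = fx$binder_mask,
                                confidence = fx$confidence,
                                binder_receptor = fx$binder_receptor,
                                design_id = suite$truth$design_id[i]))
    truth <- suite$truth[i, ]
    expect_equal(rec$pass_complex_plddt, truth$pass_complex_plddt)
    expect_equal(rec$pass_mask_plddt, truth$pass_mask_plddt)
    expect_equal(rec$pass_interchain_pae, truth$pass_interchain_pae)
    expect_equal(rec$pass_coverage, truth$pass_coverage)
    expect_equal(rec$pass_orientation, truth$pass_orientation)
    expect_equal(rec$passed, truth$passed)
  }
})

test_that("loosening any single threshold never shrinks the survivor set", {
  suite <- make_fixture_suite(n = 8, seed = 62)
  bundles <- lapply(names(suite$fixtures), function(id) {
    fx <- suite$fixtures[[id]]
    list(binder_mask = fx$binder_mask, confidence = fx$confidence,
         binder_receptor = fx$binder_receptor, design_id = id)
  })
  survivors <- function(th) {
    sum(vapply(bundles, function(b) evaluate_design(b, th)$passed, logical(1)))
  }
  base <- survivors(triage_thresholds())
  looser <- list(
    triage_thresholds(min_complex_plddt = 80),
    triage_thresholds(min_mask_plddt = 70),
    triage_thresholds(max_interchain_pae = 12),
    triage_thresholds(min_coverage = 0.2),
    triage_thresholds(require_c_terminal = FALSE)
  )
  for (th in looser) expect_gte(survivors(th), base)
})

fake_records <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    design_id = sprintf("d%02d", seq_len(n)),
    mask_sequence = vapply(rep(18, n), random_aa_seq, character(1)),
    complex_plddt = runif(n, 85, 97),
    mask_plddt = runif(n, 75, 95),
    interchain_pae = runif(n, 4, 11),
    coverage = runif(n, 0.2, 1),
    orientation = sample(c(TRUE, FALSE), n, TRUE),
    design_rmsd = NA_real_,
    passed = sample(c(TRUE, FALSE), n, TRUE)
  )
}

test_that("ranking orders survivors first by the declared keys with id tie-break", {
  r <- fake_records(2)
  r$passed <- TRUE
  r$coverage <- c(0.7, 0.8)
  expect_equal(rank_designs(r)$design_id, c("d02", "d01"))

  tie <- fake_records(2)
  tie$passed <- TRUE
  tie[2, c("coverage", "interchain_pae", "complex_plddt")] <-
    tie[1, c("coverage", "interchain_pae", "complex_plddt")]
  tie$design_id <- c("d2", "d1")
  expect_equal(rank_designs(tie)$design_id, c("d1", "d2"))

  # comparison-sort oracle on a random batch
  r <- fake_records(25, seed = 99)
  got <- rank_designs(r)$design_id
  key_order <- order(-r$passed, -r$coverage, r$interchain_pae,
                     -r$complex_plddt, r$design_id)
  expect_equal(got, r$design_id[key_order])
  expect_equal(rank_designs(r)$rank, 1:25)
})

test_that("sequence identity is a sane symmetric global-alignment score", {
  expect_equal(sequence_identity("MAK", "MAK"), 1)
  expect_equal(sequence_identity("AAAA", "CCCC"), 0)
  expect_equal(sequence_identity("AAAA", "AACC"), 0.5)
  a <- "LLWEKLLR"; b <- "LLWKLLR"
  expect_equal(sequence_identity(a, b), sequence_identity(b, a))
  expect_equal(sequence_identity(a, b), 7 / 8)  # one-gap alignment
})

test_that("diverse selection: trivial cases and greedy max-min behaviour", {
  r <- fake_records(4)
  expect_equal(select_diverse(r, k = 4), r)   # k = n returns everything
  expect_equal(select_diverse(r, k = 10), r)  # k > n capped
  dup <- fake_records(2)
  dup$mask_sequence <- rep(dup$mask_sequence[1], 2)
  expect_equal(nrow(select_diverse(dup, k = 1)), 1)
  expect_equal(select_diverse(dup, k = 1)$design_id, "d01")  # seed = top rank
  expect_error(select_diverse(r, k = 0), "k must be")
})

test_that("greedy selection attains the exhaustive max-min optimum on a clustered pool", {
  # three well-separated sequence clusters; top-ranked record in cluster 1
  recs <- tibble::tibble(
    design_id = sprintf("d%d", 1:6),
    mask_sequence = c(
      "LLWLLWLLWLLWLLWLLW", "LLWLLWLLWLLWLLWLLA",   # cluster 1
      "EKREKREKREKREKREKR", "EKREKREKREKREKREKA",   # cluster 2
      "GSGSGSGSGSGSGSGS",   "GSGSGSGSGSGSGSGA"      # cluster 3
    )
  )
  sel <- select_diverse(recs, k = 3)
  n <- 6
  dmat <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- (1 - sequence_identity(recs$mask_sequence[i], recs$mask_sequence[j])) +
      0.2 * abs(nchar(recs$mask_sequence[i]) - nchar(recs$mask_sequence[j])) /
        max(nchar(recs$mask_sequence[i]), nchar(recs$mask_sequence[j]))
    dmat[i, j] <- dmat[j, i] <- d
  }
  best <- exhaustive_maxmin(dmat, 3)  # enumerates all 20 subsets
  sel_idx <- sort(match(sel$design_id, recs$design_id))
  expect_true(any(vapply(best, function(b) identical(sort(b), sel_idx), logical(1))))
  # one representative per cluster
  expect_equal(sort(ceiling(sel_idx / 2)), 1:3)
})

test_that("rank-then-select is idempotent", {
  r <- fake_records(10, seed = 7)
  r$passed <- TRUE
  ranked <- rank_designs(r)
  sel <- select_diverse(ranked, k = 4)
  expect_equal(select_diverse(sel, k = 4), sel)
})
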