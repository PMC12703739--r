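two_helix_structure <- function(sep = 6, n = 12, chain_b = "B") {
  a <- make_ideal_helix(n, chain = "A")
  b <- make_ideal_helix(n, axis_origin = c(sep, 0, 0), chain = chain_b)
  afm_structure(dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b)))
}

test_that("distant chains yield an empty interface", {
  s <- two_helix_structure(sep = 150)
  rep <- interface_residues(s, "A", "B")
  expect_equal(nrow(rep$residues_a), 0)
  expect_equal(nrow(rep$residues_b), 0)
  expect_equal(rep$n_pairs, 0)
  expect_equal(rep$contact_cutoff, 5)  # default contact distance
})

test_that("parallel-helix contacts match the brute-force all-pairs oracle", {
  s <- two_helix_structure(sep = 6)
  rep <- interface_residues(s, "A", "B")
  oracle <- brute_force_contacts(s, "A", "B")
  expect_equal(rep$residues_a$resno, oracle$residues_a)
  expect_equal(rep$residues_b$resno, oracle$residues_b)
  expect_equal(rep$n_pairs, oracle$n_pairs)
  expect_gt(rep$n_pairs, 0)
})

test_that("interface detection is symmetric in its chain arguments", {
  for (sep in c(5.5, 6.5, 8)) {
    s <- two_helix_structure(sep = sep)
    ab <- interface_residues(s, "A", "B")
    ba <- interface_residues(s, "B", "A")
    expect_equal(ab$residues_a, ba$residues_b)
    expect_equal(ab$residues_b, ba$residues_a)
    expect_equal(ab$n_pairs, ba$n_pairs)
  }
})

test_that("interface errors: missing chain, bad cutoff", {
  s <- two_helix_structure()
  expect_error(interface_residues(s, "A", "Z"), "missing chain")
  expect_error(interface_residues(s, "A", "B", cutoff = -1), "cutoff")
})

test_that("mask coverage counts blocked interface residues and is cutoff-monotone", {
  fx <- make_bundle_fixture(seed = 21, target_coverage = 0.6)
  cov <- mask_coverage(fx$binder_receptor, fx$binder_mask)
  expect_true(all(cov$blocked_residues$resno %in% cov$interface_residues$resno))
  expect_equal(cov$coverage,
               nrow(cov$blocked_residues) / nrow(cov$interface_residues))
  # monotone non-decreasing in the blocking cutoff (interface held fixed)
  covs <- vapply(c(4, 5, 6, 8, 12),
                 function(ct) mask_coverage(fx$binder_receptor, fx$binder_mask,
                                            cutoff = ct,
                                            interface_cutoff = 5)$coverage,
                 numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("mask translated far away gives zero coverage; empty interface warns", {
  fx <- make_bundle_fixture(seed = 22, target_coverage = 0)
  cov <- mask_coverage(fx$binder_receptor, fx$binder_mask)
  expect_equal(cov$coverage, 0)
  expect_false(cov$empty_interface)

  # binder far from receptor -> empty interface -> warning, coverage 0
  binder_far <- tibble::as_tibble(fx$binder_mask)
  br_far <- tibble::as_tibble(fx$binder_receptor)
  br_far[br_far$chain == "R", c("x", "y", "z")] <-
    br_far[br_far$chain == "R", c("x", "y", "z")] + 500
  br_far <- assign_roles(afm_structure(br_far), c(A = "binder", R = "receptor"))
  expect_warning(cov0 <- mask_coverage(br_far, fx$binder_mask), "empty")
  expect_equal(cov0$coverage, 0)
  expect_true(cov0$empty_interface)
})

test_that("blocked residue sets equal the brute-force oracle on random fixtures", {
  for (seed in c(31, 32, 33)) {
    fx <- make_bundle_fixture(seed = seed,
                              target_coverage = c(0.4, 0.7, 0.9)[seed - 30])
    cov <- mask_coverage(fx$binder_receptor, fx$binder_mask)
    iface_o <- brute_force_contacts(fx$binder_receptor, "A", "R")$residues_a
    near_o <- brute_force_contacts(fx$binder_mask, "A", "B")$residues_a
    expect_equal(cov$interface_residues$resno, iface_o)
    expect_equal(cov$blocked_residues$resno, intersect(iface_o, near_o))
  }
})

test_that("coverage errors on binder length mismatch between models", {
  fx <- make_bundle_fixture(seed = 23)
  bm_short <- tibble::as_tibble(fx$binder_mask)
  bm_short <- bm_short[!(bm_short$chain == "A" & bm_short$resno > 50), ]
  bm_short <- assign_roles(afm_structure(bm_short), c(A = "binder", B = "mask"))
  expect_error(mask_coverage(fx$binder_receptor, bm_short), "length mismatch")
})

test_that("orientation compares terminal C-alpha pairings with a tie-break", {
  # mask N-term 5 A from binder C-term, other pairing 40 A -> C-terminal
  s <- afm_structure(tibble::tibble(
    chain = c(rep("A", 3), rep("B", 3)),
    resno = c(1:3, 1:3),
    resname = "ALA", atom = "CA", element = "C",
    x = c(0, 2, 4, 4, 20, 40), y = 0, z = c(0, 0, 3, 7, 7, 7)
  )) |> assign_roles(c(A = "binder", B = "mask"))
  ori <- orientation_check(s)
  expect_true(ori$c_terminal_orientation)
  expect_lt(ori$d_cterm, ori$d_nterm)

  # mirrored geometry -> false
  s2 <- afm_structure(tibble::tibble(
    chain = c(rep("A", 3), rep("B", 3)),
    resno = c(1:3, 1:3),
    resname = "ALA", atom = "CA", element = "C",
    x = c(0, 2, 4, 40, 20, 0), y = 0, z = c(0, 0, 3, 7, 7, 3)
  )) |> assign_roles(c(A = "binder", B = "mask"))
  expect_false(orientation_check(s2)$c_terminal_orientation)

  # exact tie resolves to not-C-terminal
  s3 <- afm_structure(tibble::tibble(
    chain = c(rep("A", 2), rep("B", 2)),
    resno = c(1:2, 1:2),
    resname = "ALA", atom = "CA", element = "C",
    x = c(0, 10, 14, 4), y = 0, z = 0
  )) |> assign_roles(c(A = "binder", B = "mask"))
  expect_false(orientation_check(s3)$c_terminal_orientation)
})

test_that("orientation booleans agree with direct distance comparison on random fixtures", {
  set.seed(41)
  for (i in 1:50) {
    coords <- matrix(rnorm(12 * 3, sd = 15), 12, 3)
    s <- afm_structure(tibble::tibble(
      chain = rep(c("A", "B"), each = 6),
      resno = rep(1:6, 2),
      resname = "GLY", atom = "CA", element = "C",
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    )) |> assign_roles(c(A = "binder", B = "mask"))
    ori <- orientation_check(s)
    d_c <- sqrt(sum((coords[6, ] - coords[7, ])^2))
    d_n <- sqrt(sum((coords[1, ] - coords[12, ])^2))
    expect_equal(ori$c_terminal_orientation, d_c < d_n)
  }
})

test_that("mean pLDDT and interchain PAE match explicit summation oracles", {
  conf <- make_confidence_fixture(c(A = 30, B = 20), c(A = 88, B = 75),
                                  jitter_sd = 4, seed = 9)
  expect_equal(mean_plddt(conf, "all"), sum(conf$plddt) / 50, tolerance = 1e-12)

  one <- tibble::tibble(chain = "B", resno = 7)
  expect_equal(mean_plddt(conf, one), conf$plddt[37])

  set.seed(10)
  sel <- tibble::tibble(chain = "A", resno = sample(30, 12))
  acc <- 0
  for (r in sel$resno) acc <- acc + conf$plddt[r]
  expect_equal(mean_plddt(conf, sel), acc / 12, tolerance = 1e-12)

  # interchain PAE: double-loop oracle over both off-diagonal blocks
  set_a <- tibble::tibble(chain = "A", resno = 1:30)
  set_b <- tibble::tibble(chain = "B", resno = 1:20)
  acc <- 0; cnt <- 0
  for (i in 1:30) for (j in 31:50) {
    acc <- acc + conf$pae[i, j] + conf$pae[j, i]; cnt <- cnt + 2
  }
  expect_equal(interchain_pae(conf, set_a, set_b), acc / cnt, tolerance = 1e-12)
})

test_that("interchain PAE of constant and two-block matrices is exact", {
  map <- tibble::tibble(chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2))
  const <- afm_confidence(rep(90, 8), matrix(8, 8, 8), map)
  sa <- tibble::tibble(chain = "A", resno = 1:4)
  sb <- tibble::tibble(chain = "B", resno = 1:4)
  expect_equal(interchain_pae(const, sa, sb), 8.0)

  pae <- matrix(3, 8, 8)
  pae[1:4, 5:8] <- 6; pae[5:8, 1:4] <- 10
  two <- afm_confidence(rep(90, 8), pae, map)
  expect_equal(interchain_pae(two, sa, sb), 8.0)
  expect_error(interchain_pae(two, sa, sa), "disjoint")
  expect_error(mean_plddt(two, tibble::tibble(chain = "Q", resno = 1)), "unknown residue")
})
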