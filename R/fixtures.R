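# --- synthetic masked-design fixtures -------------------------------------
#
# Geometry convention (all axes parallel to z):
#   binder chain "A": three 18-residue ideal helices
#     h1 axis (0, 0), residues 1-18 running up z (z in [0, 25.5])
#     h2 axis (11, 1), residues 19-36 running down z
#     h3 axis (5.5, 9), residues 37-54 running up z (C-term at top)
#   receptor chain "R" (binder-receptor model only): two 30-residue
#     helices at (-3, -6.5) and (3, -6.5), z in [-9, 34.5] — a flat slab
#     that puts the h1 face of the binder at a contact interface.
#   mask chain "B" (binder-mask model only): one helix on the receptor
#     side at (0, -6.5), positioned along z so that a chosen number of
#     interface residues fall within the contact cutoff.

FIX_HELIX_LEN <- 18L
FIX_MASK_AXIS <- c(0, -6.5)
FIX_RECEPTOR_AXES <- list(c(-3, -6.5), c(3, -6.5))

# Evaluate `code` under a fixed seed, then restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Amphipathic sequence for a helix at the given wheel phase: positions
# whose side chain points toward `inward_deg` draw from hydrophobic
# residues, the rest from polar ones — mirroring the apolar-core /
# polar-shell make-up of designed helix bundles, so helical-wheel and
# moment analyses on fixtures behave like they do on real masks.
# Stochastic within each class (seeded by the caller) to give the suite
# sequence diversity.
amphipathic_sequence <- function(n, phase = 0, inward_deg = 270, twist = 100) {
  hydro <- c("L", "I", "F", "W", "V", "M")
  polar <- c("E", "R", "K", "S", "Q", "N", "D", "T")
  ang <- (phase + (seq_len(n) - 1) * twist) %% 360
  delta <- abs(((ang - inward_deg + 180) %% 360) - 180)
  inward <- delta <= 60
  out <- character(n)
  out[inward] <- sample(hydro, sum(inward), replace = TRUE)
  out[!inward] <- sample(polar, sum(!inward), replace = TRUE)
  paste0(out, collapse = "")
}

# The binder geometry is fixed across the suite (one campaign, one
# binder); only its sequence decoration is seeded.
fixture_binder <- function() {
  p <- helix_params()
  seqs <- list(
    h1 = amphipathic_sequence(FIX_HELIX_LEN, phase = 0, inward_deg = 270),
    h2 = amphipathic_sequence(FIX_HELIX_LEN, phase = 40, inward_deg = 180),
    h3 = amphipathic_sequence(FIX_HELIX_LEN, phase = 80, inward_deg = 90)
  )
  h1 <- make_ideal_helix(FIX_HELIX_LEN, p, c(0, 0, 0), c(0, 0, 1),
                         phase = 0, chain = "A", sequence = seqs$h1)
  h2 <- make_ideal_helix(FIX_HELIX_LEN, p, c(11, 1, 0), c(0, 0, 1),
                         phase = 40, chain = "A", sequence = seqs$h2,
                         reverse_numbering = TRUE)
  h3 <- make_ideal_helix(FIX_HELIX_LEN, p, c(5.5, 9, 0), c(0, 0, 1),
                         phase = 80, chain = "A", sequence = seqs$h3)
  at <- bind_rows(as_tibble(h1),
                  mutate(as_tibble(h2), resno = .data$resno + FIX_HELIX_LEN),
                  mutate(as_tibble(h3), resno = .data$resno + 2L * FIX_HELIX_LEN))
  afm_structure(at, model_id = "fixture_binder")
}

fixture_receptor <- function() {
  p <- helix_params()
  n <- 30L
  parts <- imap(FIX_RECEPTOR_AXES, function(ax, i) {
    h <- make_ideal_helix(n, p, c(ax[1], ax[2], -9), c(0, 0, 1),
                          phase = 30 * i, chain = "R",
                          sequence = amphipathic_sequence(n, phase = 30 * i, inward_deg = 90))
    mutate(as_tibble(h), resno = .data$resno + (i - 1L) * n)
  })
  afm_structure(bind_rows(parts), model_id = "fixture_receptor")
}

# Bare helix CA coordinates (no structure object) for the placement search.
helix_ca_coords <- function(n, axis_xy, z_start, phase, p = helix_params()) {
  i <- seq_len(n) - 1
  theta <- (phase + i * p$twist) * pi / 180
  cbind(axis_xy[1] + p$radius * cos(theta),
        axis_xy[2] + p$radius * sin(theta),
        z_start + i * p$rise_per_residue)
}

# Find a mask z-placement blocking exactly k_target of the interface
# residues, with all interface-to-mask minimum distances kept clear of
# the cutoff by >= 0.05 A so PDB-precision rounding cannot flip a
# residue. Returns the z of the mask's first (lowest) residue.
search_mask_z <- function(mask_length, k_target, iface_ca, cutoff, phase) {
  span <- (mask_length - 1) * 1.5
  z_lo <- min(iface_ca[, 3]) - span - 6
  z_hi <- max(iface_ca[, 3]) + 6
  candidates <- seq(z_lo, z_hi, by = 0.25)
  best <- NULL
  for (z0 in candidates) {
    mca <- helix_ca_coords(mask_length, FIX_MASK_AXIS, z0, phase)
    dmin <- sqrt(apply(cross_dist2(iface_ca, mca), 1, min))
    k <- sum(dmin <= cutoff)
    margin <- min(abs(dmin - cutoff))
    cand <- list(z0 = z0, k = k, margin = margin)
    if (is.null(best) ||
        abs(cand$k - k_target) < abs(best$k - k_target) ||
        (abs(cand$k - k_target) == abs(best$k - k_target) && cand$margin > best$margin)) {
      best <- cand
    }
  }
  if (best$margin < 0.05) {
    warn("mask placement margin below 0.05 A; coverage may be rounding-sensitive")
  }
  best
}

#' Generate one synthetic masked-design bundle with planted ground truth
#'
#' Builds a three-helix-bundle binder, a two-helix receptor slab defining
#' a known interface, and a mask helix laid along the interface groove so
#' that a controllable fraction of the interface residues fall within the
#' contact cutoff. Confidence data is emitted with requested block means
#' and seeded jitter. All coordinates are rounded to 0.001 Angstrom (PDB
#' precision) *before* the truth is measured, so written fixtures
#' re-measure identically.
#'
#' Coverage is planted by a placement search over mask positions and then
#' verified against the package's own contact metric before emission; a
#' request that is not realisable at one-residue granularity falls back
#' to the nearest achievable value (with a warning).
#'
#' @param mask_length Mask helix length in residues (the 15-25 design
#'   band).
#' @param target_coverage Requested fraction of interface residues
#'   blocked by the mask, in \[0, 1\].
#' @param orientation `"c_terminal"` or `"n_terminal"` mask fusion
#'   geometry.
#' @param plddt_binder,plddt_mask Mean pLDDT planted for the binder and
#'   mask residues.
#' @param pae_intra,pae_inter Mean PAE (Angstrom) planted for the
#'   intra-chain and binder-mask blocks.
#' @param jitter_sd Gaussian jitter on confidence values.
#' @param cutoff Contact cutoff (Angstrom) the truth is planted against.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `afm_fixture`: `binder_receptor`, `binder_mask`
#'   ([afm_structure()]s with roles assigned), `confidence` (attached
#'   [afm_confidence()]), and `truth` (planted interface/blocked residue
#'   sets, achieved coverage, orientation, confidence means).
#' @export
make_bundle_fixture <- function(mask_length = 18,
                                target_coverage = 0.75,
                                orientation = c("c_terminal", "n_terminal"),
                                plddt_binder = 95, plddt_mask = 88,
                                pae_intra = 3, pae_inter = 5.5,
                                jitter_sd = 0.8, cutoff = 5, seed = 1) {
  orientation <- match.arg(orientation)
  if (mask_length < 2) abort("mask_length must be >= 2")
  if (target_coverage < 0 || target_coverage > 1) abort("target_coverage must be in [0, 1]")

  binder <- with_seed(seed * 7L + 11L, fixture_binder())
  receptor <- with_seed(seed * 7L + 12L, fixture_receptor())
  br <- afm_structure(bind_rows(as_tibble(binder), as_tibble(receptor)),
                      model_id = sprintf("fixture_%d_br", seed)) %>%
    assign_roles(c(A = "binder", R = "receptor"))

  iface <- interface_residues(br, "A", "R", cutoff)$residues_a
  n_iface <- nrow(iface)
  if (n_iface == 0) abort("internal error: fixture interface is empty")
  k_target <- round(target_coverage * n_iface)

  binder_ca <- atom_coords(binder, atom_mode = "ca")
  iface_ca <- binder_ca[paste("A", iface$resno, sep = ":"), , drop = FALSE]
  mask_phase <- 20
  mask_seq <- with_seed(seed * 7L + 13L,
                        amphipathic_sequence(mask_length, phase = mask_phase, inward_deg = 90))
  p <- helix_params()
  if (k_target == 0) {
    mask <- make_ideal_helix(mask_length, p, c(200, 200, 200), c(0, 0, 1),
                             phase = mask_phase, chain = "B", sequence = mask_seq)
  } else {
    placement <- search_mask_z(mask_length, k_target, iface_ca, cutoff, mask_phase)
    mask <- make_ideal_helix(mask_length, p,
                             c(FIX_MASK_AXIS[1], FIX_MASK_AXIS[2], placement$z0),
                             c(0, 0, 1), phase = mask_phase, chain = "B",
                             sequence = mask_seq)
  }

  build_bm <- function(mask_atoms) {
    afm_structure(bind_rows(as_tibble(binder), mask_atoms),
                  model_id = sprintf("fixture_%d_bm", seed)) %>%
      assign_roles(c(A = "binder", B = "mask"))
  }
  bm <- build_bm(as_tibble(mask))
  # realise the requested terminal pairing by flipping mask numbering
  want_c <- orientation == "c_terminal"
  if (orientation_check(bm)$c_terminal_orientation != want_c) {
    m <- as_tibble(mask)
    m$resno <- rev(m$resno)
    bm <- build_bm(arrange(m, .data$resno))
  }

  # freeze at PDB precision, then measure the truth on what will be written
  round_coords <- function(s) {
    s$x <- round(s$x, 3); s$y <- round(s$y, 3); s$z <- round(s$z, 3)
    s
  }
  br <- round_coords(br)
  bm <- round_coords(bm)

  cov <- mask_coverage(br, bm, cutoff = cutoff)
  if (k_target > 0 && abs(nrow(cov$blocked_residues) - k_target) > 1) {
    warn(sprintf("requested coverage %.2f not realisable; achieved %.2f (nearest)",
                 target_coverage, cov$coverage))
  }
  ori_final <- orientation_check(bm)

  conf <- make_confidence_fixture(
    chain_lengths = c(A = 3L * FIX_HELIX_LEN, B = as.integer(mask_length)),
    plddt_means = c(A = plddt_binder, B = plddt_mask),
    pae_intra_mean = pae_intra, pae_inter_mean = pae_inter,
    jitter_sd = jitter_sd, seed = seed * 7L + 14L
  )
  conf <- attach_confidence(conf, bm)

  res_map <- conf$residue_map
  binder_pos <- which(res_map$chain == "A")
  mask_pos <- which(res_map$chain == "B")
  truth <- list(
    interface_residues = cov$interface_residues,
    blocked_residues = cov$blocked_residues,
    coverage = cov$coverage,
    target_coverage = target_coverage,
    c_terminal_orientation = ori_final$c_terminal_orientation,
    complex_plddt = mean(conf$plddt),
    mask_plddt = mean(conf$plddt[mask_pos]),
    interchain_pae = mean(c(conf$pae[binder_pos, mask_pos],
                            conf$pae[mask_pos, binder_pos])),
    mask_sequence = chain_sequence(bm, "B"),
    seed = seed
  )
  structure(list(binder_receptor = br, binder_mask = bm,
                 confidence = conf, truth = truth),
            class = "afm_fixture")
}

#' @export
print.afm_fixture <- function(x, ...) {
  cat("<afm_fixture> seed ", x$truth$seed, ": coverage ",
      sprintf("%.2f", x$truth$coverage), ", ",
      if (x$truth$c_terminal_orientation) "C-terminal" else "N-terminal",
      " mask, complex pLDDT ", sprintf("%.1f", x$truth$complex_plddt), "\n", sep = "")
  invisible(x)
}

#' Generate synthetic confidence data with planted block means
#'
#' @param chain_lengths Named integer vector of residues per chain, in
#'   order (e.g. `c(A = 54, B = 18)`).
#' @param plddt_means Named per-chain mean pLDDT (same names).
#' @param pae_intra_mean,pae_inter_mean Planted means (Angstrom) for the
#'   within-chain and between-chain PAE blocks.
#' @param jitter_sd Gaussian jitter standard deviation; 0 gives exactly
#'   constant blocks.
#' @param seed Integer seed; output is bit-identical for the same seed.
#' @return An [afm_confidence()] with residue map.
#' @export
make_confidence_fixture <- function(chain_lengths, plddt_means,
                                    pae_intra_mean = 3, pae_inter_mean = 5.5,
                                    jitter_sd = 1, seed = 1) {
  if (is.null(names(chain_lengths)) || !setequal(names(chain_lengths), names(plddt_means))) {
    abort("chain_lengths and plddt_means must share chain names")
  }
  if (any(plddt_means < 0 | plddt_means > 100)) abort("pLDDT means must be in [0, 100]")
  if (pae_intra_mean < 0 || pae_inter_mean < 0) abort("PAE means must be >= 0")
  n <- sum(chain_lengths)
  chain_of <- rep(names(chain_lengths), chain_lengths)
  with_seed(seed, {
    plddt <- rnorm(n, unname(plddt_means[chain_of]), jitter_sd)
    plddt <- pmin(pmax(plddt, 0), 100)
    same <- outer(chain_of, chain_of, "==")
    pae <- matrix(rnorm(n * n, ifelse(same, pae_intra_mean, pae_inter_mean), jitter_sd),
                  n, n)
    pae[pae < 0] <- 0
    afm_confidence(
      plddt, pae,
      residue_map = tibble(
        chain = chain_of,
        resno = unlist(lapply(chain_lengths, seq_len), use.names = FALSE)
      )
    )
  })
}

# pLDDT profile presets planting each pass/fail combination of the
# complex/mask pLDDT criteria, with margins comfortably clear of the
# 90/80 thresholds for any mask length in the 15-25 band.
plddt_profile_for <- function(pass_complex, pass_mask) {
  if (pass_complex && pass_mask) c(binder = 95, mask = 88)
  else if (!pass_complex && pass_mask) c(binder = 87, mask = 83)
  else if (pass_complex && !pass_mask) c(binder = 97, mask = 77)
  else c(binder = 86, mask = 74)
}

#' Generate a fixture suite with planted triage labels
#'
#' Draws a per-design pass/fail plan for the five triage criteria
#' (complex pLDDT, mask pLDDT, interchain PAE, coverage, orientation),
#' builds one bundle per design realising that plan, and records the
#' resulting truth. Truth flags are re-derived from the *achieved*
#' values against the supplied thresholds, so the suite is
#' self-validating even at the granularity limits of the geometry.
#'
#' @param n Number of designs.
#' @param seed Integer master seed.
#' @param thresholds [triage_thresholds()] the labels are planted
#'   against.
#' @return List with `fixtures` (named list of [make_bundle_fixture()]
#'   bundles) and `truth` (tibble: design_id, achieved metric values,
#'   expected per-criterion flags and `passed`).
#' @export
make_fixture_suite <- function(n = 40, seed = 1, thresholds = triage_thresholds()) {
  plan <- with_seed(seed, tibble(
    design_id = sprintf("fx%03d", seq_len(n)),
    pass_complex = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.6, 0.4)),
    pass_mask = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.7, 0.3)),
    pass_pae = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.6, 0.4)),
    pass_cov = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.6, 0.4)),
    pass_orient = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.5, 0.5)),
    mask_length = sample(15:25, n, TRUE),
    design_seed = seed * 1000L + seq_len(n)
  ))
  fixtures <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- plan[i, ]
    prof <- plddt_profile_for(row$pass_complex, row$pass_mask)
    fx <- make_bundle_fixture(
      mask_length = row$mask_length,
      target_coverage = if (row$pass_cov) 0.85 else 0.35,
      orientation = if (row$pass_orient) "c_terminal" else "n_terminal",
      plddt_binder = prof[["binder"]], plddt_mask = prof[["mask"]],
      pae_inter = if (row$pass_pae) 5.5 else 10,
      cutoff = thresholds$contact_cutoff,
      seed = row$design_seed
    )
    tr <- fx$truth
    flags <- tibble(
      pass_complex_plddt = tr$complex_plddt > thresholds$min_complex_plddt,
      pass_mask_plddt = tr$mask_plddt > thresholds$min_mask_plddt,
      pass_interchain_pae = tr$interchain_pae <= thresholds$max_interchain_pae,
      pass_coverage = tr$coverage >= thresholds$min_coverage,
      pass_orientation = if (thresholds$require_c_terminal) tr$c_terminal_orientation else TRUE
    )
    fixtures[[i]] <- fx
    truth_rows[[i]] <- bind_cols(
      tibble(design_id = row$design_id,
             complex_plddt = tr$complex_plddt, mask_plddt = tr$mask_plddt,
             interchain_pae = tr$interchain_pae, coverage = tr$coverage,
             orientation = tr$c_terminal_orientation,
             mask_sequence = tr$mask_sequence),
      flags,
      tibble(passed = all(unlist(flags)))
    )
  }
  names(fixtures) <- plan$design_id
  list(fixtures = fixtures, truth = bind_rows(truth_rows))
}

#' Write a fixture suite to disk in the pipeline's input layout
#'
#' Layout: `<dir>/binder_receptor.pdb` (shared reference) plus one
#' sub-directory per design holding `binder_mask.pdb` and
#' `confidence.json` (plain dialect); the suite truth table is written as
#' `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @inheritParams make_fixture_suite
#' @return The truth tibble, invisibly.
#' @export
write_fixture_suite <- function(dir, n = 40, seed = 1,
                                thresholds = triage_thresholds()) {
  suite <- make_fixture_suite(n = n, seed = seed, thresholds = thresholds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(suite$fixtures[[1]]$binder_receptor,
                  file.path(dir, "binder_receptor.pdb"))
  for (id in names(suite$fixtures)) {
    fx <- suite$fixtures[[id]]
    ddir <- file.path(dir, id)
    dir.create(ddir, showWarnings = FALSE)
    write_structure(fx$binder_mask, file.path(ddir, "binder_mask.pdb"))
    write_confidence(fx$confidence, file.path(ddir, "confidence.json"))
  }
  jsonlite::write_json(suite$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(suite$truth)
}
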