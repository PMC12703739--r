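#' Thresholds for the design filter cascade
#'
#' Defaults follow the criteria used to shortlist masked-binder designs
#' from prediction confidence and geometry: complex pLDDT > 90 and mask
#' pLDDT > 80 (strict), mean interchain PAE <= 8 Angstrom, interface
#' coverage >= 0.60 (campaigns tighten this up to 0.80 to size the
#' shortlist), C-terminal mask orientation required, and design-vs-
#' prediction C-alpha RMSD < 1.5 Angstrom where a design backbone is
#' available.
#'
#' @param min_complex_plddt Strict lower bound on mean pLDDT over binder
#'   plus mask residues.
#' @param min_mask_plddt Strict lower bound on mean pLDDT over mask
#'   residues.
#' @param max_interchain_pae Inclusive upper bound on the mean binder-mask
#'   PAE (Angstrom).
#' @param min_coverage Inclusive lower bound on mask coverage of the
#'   receptor interface (fraction).
#' @param require_c_terminal Require the mask N-terminus near the binder
#'   C-terminus?
#' @param max_design_rmsd Strict upper bound on design-vs-prediction
#'   C-alpha RMSD (Angstrom); only gated when a design backbone model is
#'   supplied. `NA` disables the criterion.
#' @param contact_cutoff Contact distance (Angstrom) used for the
#'   coverage metric.
#' @return One-row tibble of thresholds.
#' @export
triage_thresholds <- function(min_complex_plddt = 90,
                              min_mask_plddt = 80,
                              max_interchain_pae = 8,
                              min_coverage = 0.60,
                              require_c_terminal = TRUE,
                              max_design_rmsd = 1.5,
                              contact_cutoff = 5) {
  th <- tibble(
    min_complex_plddt = min_complex_plddt,
    min_mask_plddt = min_mask_plddt,
    max_interchain_pae = max_interchain_pae,
    min_coverage = min_coverage,
    require_c_terminal = require_c_terminal,
    max_design_rmsd = max_design_rmsd,
    contact_cutoff = contact_cutoff
  )
  num <- c("min_complex_plddt", "min_mask_plddt", "max_interchain_pae",
           "min_coverage", "contact_cutoff")
  if (any(!is.finite(unlist(th[num])))) abort("thresholds must be finite")
  if (th$min_coverage < 0 || th$min_coverage > 1) abort("min_coverage must be in [0, 1]")
  if (th$contact_cutoff <= 0) abort("contact_cutoff must be > 0")
  th
}

#' Evaluate one masked design against the filter cascade
#'
#' Computes all triage metrics for a candidate design and applies the
#' thresholds: pLDDT criteria are strict (`>`), PAE inclusive (`<=`),
#' coverage inclusive (`>=`), RMSD strict (`<`). `passed` is the
#' conjunction of all gated criteria.
#'
#' @param models A list with elements:
#'   * `binder_mask`: [afm_structure()] with roles `binder` and `mask`;
#'   * `confidence`: [afm_confidence()] for the binder-mask prediction
#'     (attached automatically if it has no residue map);
#'   * `binder_receptor`: [afm_structure()] with roles `binder` and
#'     `receptor` (the reference complex defining the interface);
#'   * optional `design_backbone`: [afm_structure()] of the generative
#'     backbone, for the RMSD validation gate;
#'   * optional `design_id` (string) and `mask_sequence` (one-letter
#'     string; derived from the mask chain residue names if absent).
#' @param thresholds A [triage_thresholds()] row.
#' @return One-row tibble (class `afm_design_record`): id, mask sequence,
#'   the six metrics, one `pass_*` flag per gated criterion, and `passed`.
#' @export
evaluate_design <- function(models, thresholds = triage_thresholds()) {
  for (need in c("binder_mask", "confidence", "binder_receptor")) {
    if (is.null(models[[need]])) abort(paste0("missing model '", need, "' required by an enabled criterion"))
  }
  bm <- models$binder_mask
  conf <- models$confidence
  if (is.null(conf$residue_map)) conf <- attach_confidence(conf, bm)
  sel_binder <- role_selection(bm, "binder")
  sel_mask <- role_selection(bm, "mask")
  sel_complex <- bind_rows(sel_binder, sel_mask)

  complex_plddt <- mean_plddt(conf, sel_complex)
  mask_plddt <- mean_plddt(conf, sel_mask)
  pae <- interchain_pae(conf, sel_binder, sel_mask)
  cov <- mask_coverage(models$binder_receptor, bm, cutoff = thresholds$contact_cutoff)
  orient <- orientation_check(bm)$c_terminal_orientation

  design_rmsd <- NA_real_
  if (!is.null(models$design_backbone) && is.finite(thresholds$max_design_rmsd)) {
    design_rmsd <- ca_rmsd(models$design_backbone, bm)
  }

  mask_sequence <- models$mask_sequence %||% chain_sequence(bm, chain_of_role(bm, "mask"))

  flags <- tibble(
    pass_complex_plddt = complex_plddt > thresholds$min_complex_plddt,
    pass_mask_plddt = mask_plddt > thresholds$min_mask_plddt,
    pass_interchain_pae = pae <= thresholds$max_interchain_pae,
    pass_coverage = cov$coverage >= thresholds$min_coverage,
    pass_orientation = if (thresholds$require_c_terminal) orient else TRUE,
    pass_design_rmsd = if (is.na(design_rmsd)) NA else design_rmsd < thresholds$max_design_rmsd
  )
  rec <- tibble(
    design_id = models$design_id %||% attr(bm, "model_id") %||% "design",
    mask_sequence = mask_sequence,
    complex_plddt = complex_plddt,
    mask_plddt = mask_plddt,
    interchain_pae = pae,
    coverage = cov$coverage,
    orientation = orient,
    design_rmsd = design_rmsd
  ) %>%
    bind_cols(flags) %>%
    mutate(passed = all(unlist(flags), na.rm = TRUE))
  class(rec) <- c("afm_design_record", class(rec))
  rec
}

#' Rank evaluated designs
#'
#' Survivors first; within each group ordered by coverage (descending),
#' then interchain PAE (ascending), then complex pLDDT (descending), with
#' `design_id` as the final tie-break so the order is a deterministic
#' total order.
#'
#' @param records Tibble of design records (rows from [evaluate_design()]).
#' @return The same tibble, reordered, with a `rank` column prepended.
#' @export
rank_designs <- function(records) {
  if (nrow(records) == 0) return(mutate(records, rank = integer()))
  records %>%
    arrange(desc(.data$passed), desc(.data$coverage), .data$interchain_pae,
            desc(.data$complex_plddt), .data$design_id) %>%
    mutate(rank = row_number()) %>%
    select("rank", dplyr::everything())
}

#' Global sequence identity between two mask sequences
#'
#' Needleman-Wunsch global alignment with unit match score, zero mismatch
#' and linear gap penalty -1 (via Biostrings); identity is the number of
#' identical aligned positions divided by the longer sequence length, so
#' it is symmetric and lands in \[0, 1\].
#'
#' @param seq_a,seq_b One-letter amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("empty sequence")
  if (identical(seq_a, seq_b)) return(1)
  alphabet <- unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]]))
  sub <- matrix(0, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seq_a), Biostrings::BString(seq_b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / max(nchar(seq_a), nchar(seq_b))
}

# Pairwise diversity distance between two design records:
# (1 - identity) + 0.2 * |length difference| / max length.
mask_distance <- function(seq_a, seq_b) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  (1 - sequence_identity(seq_a, seq_b)) + 0.2 * abs(la - lb) / max(la, lb)
}

#' Select a sequence-diverse shortlist
#'
#' Greedy max-min selection over mask sequences: the top-ranked survivor
#' seeds the set, then each step adds the record whose minimum diversity
#' distance to the already-chosen set is largest (ties broken by rank).
#' Distance is `(1 - global identity) + 0.2 * |length diff| / max length`.
#' Campaigns typically keep `k = 5` designs per binder.
#'
#' @param records Ranked design records ([rank_designs()] output or any
#'   tibble with `design_id` and `mask_sequence` in priority order).
#' @param k Number of designs to keep (>= 1); capped at `nrow(records)`.
#' @return The selected rows, in selection order.
#' @export
select_diverse <- function(records, k = 5) {
  if (k < 1) abort("k must be >= 1")
  n <- nrow(records)
  if (n == 0) return(records)
  if (k >= n) return(records)
  seqs <- records$mask_sequence
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- mask_distance(seqs[i], seqs[j])
    }
  }
  chosen <- 1L
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(n), chosen)
    min_d <- vapply(rest, function(i) min(dmat[i, chosen]), numeric(1))
    best <- rest[which.max(min_d)]  # which.max takes the first -> rank tie-break
    chosen <- c(chosen, best)
  }
  records[chosen, , drop = FALSE]
}
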