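# Squared cross-distances between two coordinate matrices (n x 3, m x 3).
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

split_res_keys <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  tibble(chain = map_chr(parts, 1), resno = as.integer(map_chr(parts, 2)))
}

#' Interface residues between two chains
#'
#' A residue is at the interface if any of its atoms (heavy atoms by
#' default, or C-alpha only) lies within `cutoff` Angstrom of any atom of
#' the partner chain. The 5 Angstrom default is the usual contact
#' criterion for scoring how much of a binder's receptor-facing surface a
#' design engages.
#'
#' @param s An [afm_structure()] containing both chains.
#' @param chain_a,chain_b Chain ids.
#' @param cutoff Contact distance cutoff in Angstrom (> 0).
#' @param atom_mode `"heavy"` (default) or `"ca"`.
#' @return A list of class `afm_interface`: `contact_cutoff`,
#'   `residues_a` / `residues_b` (tibbles `chain`, `resno`), `n_pairs`
#'   (count of residue pairs in contact) and `pairs` (tibble of the
#'   contacting residue pairs with their minimum inter-atomic distance).
#' @export
interface_residues <- function(s, chain_a, chain_b, cutoff = 5, atom_mode = c("heavy", "ca")) {
  atom_mode <- match.arg(atom_mode)
  if (!is.numeric(cutoff) || cutoff <= 0) abort("cutoff must be > 0")
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% s$chain) abort(paste0("missing chain '", ch, "'"))
  }
  if (atom_mode == "ca") check_ca_complete(s, c(chain_a, chain_b))
  ca_m <- atom_coords(s, chain_a, atom_mode)
  cb_m <- atom_coords(s, chain_b, atom_mode)
  d2 <- cross_dist2(ca_m, cb_m)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    pairs <- tibble(chain_a = character(), resno_a = integer(),
                    chain_b = character(), resno_b = integer(),
                    min_dist = numeric())
  } else {
    pairs <- tibble(
      key_a = rownames(ca_m)[hit[, 1]],
      key_b = rownames(cb_m)[hit[, 2]],
      dist = sqrt(d2[hit])
    ) %>%
      group_by(.data$key_a, .data$key_b) %>%
      summarise(min_dist = min(.data$dist), .groups = "drop")
    ka <- split_res_keys(pairs$key_a)
    kb <- split_res_keys(pairs$key_b)
    pairs <- tibble(chain_a = ka$chain, resno_a = ka$resno,
                    chain_b = kb$chain, resno_b = kb$resno,
                    min_dist = pairs$min_dist) %>%
      arrange(.data$resno_a, .data$resno_b)
  }
  res_a <- distinct(pairs[, c("chain_a", "resno_a")])
  res_b <- distinct(pairs[, c("chain_b", "resno_b")])
  structure(list(
    contact_cutoff = cutoff,
    atom_mode = atom_mode,
    residues_a = tibble(chain = res_a$chain_a, resno = sort(res_a$resno_a)),
    residues_b = tibble(chain = res_b$chain_b, resno = sort(res_b$resno_b)),
    n_pairs = nrow(pairs),
    pairs = pairs
  ), class = "afm_interface")
}

check_ca_complete <- function(s, chains) {
  res <- structure_residues(s)
  res <- res[res$chain %in% chains, ]
  a <- as_tibble(s)
  ca <- a[a$atom == "CA" & a$chain %in% chains, c("chain", "resno")]
  missing <- !paste(res$chain, res$resno) %in% paste(ca$chain, ca$resno)
  if (any(missing)) {
    bad <- paste0(res$chain, ":", res$resno)[missing]
    abort(paste0("residue(s) lacking a C-alpha atom: ", paste(head(bad, 5), collapse = ", ")))
  }
}

#' @export
print.afm_interface <- function(x, ...) {
  cat("<afm_interface> cutoff ", x$contact_cutoff, " A (", x$atom_mode, "): ",
      nrow(x$residues_a), " + ", nrow(x$residues_b), " residues, ",
      x$n_pairs, " contacting pairs\n", sep = "")
  invisible(x)
}

#' Mask coverage of the binder-receptor interface
#'
#' The steric-blocking metric for a masked design: of the binder residues
#' that contact the receptor (in the binder-receptor reference model),
#' what fraction lie within `cutoff` of the mask in the binder-mask
#' prediction? Residues are paired across the two models by index, so the
#' binder chain must have the same length in both.
#'
#' @param binder_receptor_model [afm_structure()] with roles `binder` and
#'   `receptor` assigned.
#' @param binder_mask_model [afm_structure()] with roles `binder` and
#'   `mask` assigned.
#' @param cutoff Contact cutoff in Angstrom (default 5) used to decide
#'   which interface residues the mask blocks.
#' @param interface_cutoff Cutoff defining the binder-receptor interface
#'   itself; defaults to `cutoff` (the single 5 Angstrom criterion).
#'   Holding it fixed while varying `cutoff` makes coverage monotone in
#'   the blocking distance.
#' @param atom_mode `"heavy"` or `"ca"`.
#' @return List of class `afm_coverage`: `interface_residues` (tibble of
#'   binder residues contacting the receptor), `blocked_residues` (subset
#'   within cutoff of the mask), `coverage` (fraction, 0 when the
#'   interface is empty) and `empty_interface` flag.
#' @export
mask_coverage <- function(binder_receptor_model, binder_mask_model,
                          cutoff = 5, interface_cutoff = cutoff,
                          atom_mode = c("heavy", "ca")) {
  atom_mode <- match.arg(atom_mode)
  br <- binder_receptor_model
  bm <- binder_mask_model
  ch_binder_br <- chain_of_role(br, "binder")
  ch_receptor <- chain_of_role(br, "receptor")
  ch_binder_bm <- chain_of_role(bm, "binder")
  ch_mask <- chain_of_role(bm, "mask")
  n_br <- sum(structure_residues(br)$chain == ch_binder_br)
  n_bm <- sum(structure_residues(bm)$chain == ch_binder_bm)
  if (n_br != n_bm) {
    abort(sprintf("binder length mismatch between models: %d vs %d residues", n_br, n_bm))
  }
  iface <- interface_residues(br, ch_binder_br, ch_receptor, interface_cutoff, atom_mode)
  interface_set <- iface$residues_a
  if (nrow(interface_set) == 0) {
    warn("empty binder-receptor interface; coverage reported as 0")
    return(structure(list(
      interface_residues = interface_set,
      blocked_residues = interface_set,
      coverage = 0,
      contact_cutoff = cutoff,
      empty_interface = TRUE
    ), class = "afm_coverage"))
  }
  near_mask <- interface_residues(bm, ch_binder_bm, ch_mask, cutoff, atom_mode)$residues_a
  blocked <- interface_set[interface_set$resno %in% near_mask$resno, , drop = FALSE]
  structure(list(
    interface_residues = interface_set,
    blocked_residues = blocked,
    coverage = nrow(blocked) / nrow(interface_set),
    contact_cutoff = cutoff,
    empty_interface = FALSE
  ), class = "afm_coverage")
}

chain_of_role <- function(s, role) {
  ch <- unique(s$chain[s$role == role])
  if (length(ch) == 0) abort(paste0("no chain with role '", role, "'; call assign_roles()"))
  if (length(ch) > 1) abort(paste0("multiple chains with role '", role, "'"))
  ch
}

#' @export
print.afm_coverage <- function(x, ...) {
  cat("<afm_coverage> ", nrow(x$blocked_residues), "/", nrow(x$interface_residues),
      " interface residues blocked (", sprintf("%.1f%%", 100 * x$coverage), ")",
      if (x$empty_interface) " [empty interface]", "\n", sep = "")
  invisible(x)
}

#' Mask orientation relative to the binder termini
#'
#' For cloning, a mask fused after the binder works only if the mask's
#' N-terminus sits near the binder's C-terminus. This check compares the
#' two possible terminal pairings on C-alpha atoms and reports whether the
#' C-terminal fusion geometry is the closer one. Exact ties (within 1e-6
#' Angstrom) count as not C-terminal.
#'
#' @param binder_mask_model [afm_structure()] with roles `binder` and
#'   `mask` assigned; terminal residues must have C-alpha atoms.
#' @return One-row tibble: `d_cterm` (binder C-term CA to mask N-term CA),
#'   `d_nterm` (binder N-term CA to mask C-term CA), and logical
#'   `c_terminal_orientation`.
#' @export
orientation_check <- function(binder_mask_model) {
  s <- binder_mask_model
  ch_b <- chain_of_role(s, "binder")
  ch_m <- chain_of_role(s, "mask")
  term_ca <- function(ch, which_end) {
    a <- as_tibble(s)
    a <- a[a$chain == ch & a$atom == "CA", ]
    if (nrow(a) == 0) abort(paste0("missing terminal C-alpha in chain ", ch))
    target <- if (which_end == "N") min(a$resno) else max(a$resno)
    res_all <- structure_residues(s)
    res_all <- res_all[res_all$chain == ch, ]
    expected <- if (which_end == "N") min(res_all$resno) else max(res_all$resno)
    if (target != expected) abort(paste0("missing terminal C-alpha in chain ", ch))
    as.numeric(a[a$resno == target, c("x", "y", "z")])
  }
  b_n <- term_ca(ch_b, "N"); b_c <- term_ca(ch_b, "C")
  m_n <- term_ca(ch_m, "N"); m_c <- term_ca(ch_m, "C")
  d_cterm <- sqrt(sum((b_c - m_n)^2))
  d_nterm <- sqrt(sum((b_n - m_c)^2))
  tibble(
    d_cterm = d_cterm,
    d_nterm = d_nterm,
    c_terminal_orientation = (d_cterm < d_nterm) && abs(d_cterm - d_nterm) > 1e-6
  )
}

#' Mean pLDDT over a residue selection
#'
#' @param conf An [afm_confidence()] with a residue map (see
#'   [attach_confidence()]).
#' @param selection `"all"` or a tibble with columns `chain`, `resno`.
#' @return Arithmetic mean pLDDT (scalar).
#' @export
mean_plddt <- function(conf, selection = "all") {
  pos <- confidence_positions(conf, selection)
  mean(conf$plddt[pos])
}

#' Mean interchain PAE between two residue sets
#'
#' Averages the predicted aligned error over both off-diagonal blocks
#' (a aligned on b, and b aligned on a), weighting every entry equally.
#' Low values over the binder-mask blocks indicate a confidently
#' predicted inter-chain interface.
#'
#' @param conf An [afm_confidence()] with a residue map.
#' @param set_a,set_b Disjoint residue selections (tibbles with `chain`,
#'   `resno`).
#' @return Mean PAE in Angstrom (scalar).
#' @export
interchain_pae <- function(conf, set_a, set_b) {
  pos_a <- confidence_positions(conf, set_a)
  pos_b <- confidence_positions(conf, set_b)
  if (length(intersect(pos_a, pos_b)) > 0) abort("set_a and set_b must be disjoint")
  block_ab <- conf$pae[pos_a, pos_b, drop = FALSE]
  block_ba <- conf$pae[pos_b, pos_a, drop = FALSE]
  mean(c(block_ab, block_ba))
}

#' Residue selection helper: all residues of a chain role
#'
#' @param s An [afm_structure()].
#' @param role Chain role (`"binder"`, `"mask"`, `"receptor"`).
#' @return Tibble with `chain`, `resno` for use as a metric selection.
#' @export
role_selection <- function(s, role) {
  ch <- chain_of_role(s, role)
  res <- structure_residues(s)
  res[res$chain == ch, c("chain", "resno")]
}
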