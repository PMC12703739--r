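# Residue (monomer) masses in Da for the 20 standard amino acids.
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_AVG <- 18.01528
WATER_MONO <- 18.010565

#' Default modification mass table
#'
#' Named mass deltas (Da) applied on top of residue masses, each on both
#' the average and monoisotopic scale. Bundled defaults cover the
#' chemogenetic photocage chemistry:
#'
#' * `mal_propanoyl`: 3-(maleimido)propanoyl adduct on a cysteine thiol
#'   (whole-molecule Michael addition of 3-maleimidopropanoic acid);
#' * `mal_propanoyl_hydrolyzed`: the same adduct after maleimide ring
#'   hydrolysis (+H2O), the stabilised form usually observed;
#' * `np_linker`: an o-nitrophenyl (NP) photocleavable unit
#'   (4-(4-(1-aminoethyl)-2-methoxy-5-nitrophenoxy)butanoic acid) built
#'   into a chain, counted as molecule minus one water like any residue;
#' * `np_n_fragment` / `np_c_fragment`: bookkeeping masses retained by the
#'   N- and C-side products after photolysis. The defaults put +1.008 (a
#'   hydrogen) on the N-side and the remainder on the C-side so that
#'   photolysis conserves mass; replace them with characterised
#'   photoproduct masses when available.
#'
#' @return Tibble with columns `mod`, `average`, `monoisotopic`.
#' @export
modification_table <- function() {
  tibble(
    mod = c("mal_propanoyl", "mal_propanoyl_hydrolyzed",
            "np_linker", "np_n_fragment", "np_c_fragment"),
    average = c(169.137, 187.152, 280.280, 1.008, 279.272),
    monoisotopic = c(169.0375, 187.0481, 280.1059, 1.00783, 279.0981)
  )
}

#' Peptide mass from sequence and modifications
#'
#' Sum of residue masses plus one water per chain plus modification
#' deltas. Average masses are the default scale because LC-MS
#' deconvolution of ~10 kDa proteins reports average mass.
#'
#' @param seq One-letter amino-acid string (standard 20 residues).
#' @param mods Optional character vector of modification names, or a data
#'   frame with a `mod` column; each named mod adds its delta once.
#' @param scale `"average"` (default) or `"monoisotopic"`.
#' @param mod_table Modification table (see [modification_table()]).
#' @return Mass in Da (scalar).
#' @export
peptide_mass <- function(seq, mods = NULL, scale = c("average", "monoisotopic"),
                         mod_table = modification_table()) {
  scale <- match.arg(scale)
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) abort("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  tab <- if (scale == "average") RESIDUE_MASS_AVG else RESIDUE_MASS_MONO
  if (any(!chars %in% names(tab))) {
    abort(paste0("unknown residue(s): ",
                 paste(unique(chars[!chars %in% names(tab)]), collapse = ", ")))
  }
  water <- if (scale == "average") WATER_AVG else WATER_MONO
  total <- sum(tab[chars]) + water
  if (!is.null(mods)) {
    mod_names <- if (is.data.frame(mods)) mods$mod else mods
    idx <- match(mod_names, mod_table$mod)
    if (any(is.na(idx))) {
      abort(paste0("unknown modification(s): ",
                   paste(mod_names[is.na(idx)], collapse = ", ")))
    }
    total <- total + sum(mod_table[[scale]][idx])
  }
  total
}

#' Assemble a masked-binder construct
#'
#' Builds the full expression construct in the standard N-to-C order:
#' His-tag, binder, GS linker, cleavable motif, mask. Every segment can be
#' overridden or disabled. For `linker_type = "mmp"` the motif defaults to
#' the canonical MMP2/9 substrate `GPLGLAG` with the scissile bond between
#' its G4 and L5 (PLG|LAG); for `"photo"` the motif is a GS stretch
#' carrying an internal NP photocleavable unit, with the cleavage site at
#' the NP position.
#'
#' @param binder_seq,mask_seq One-letter sequences (both required).
#' @param his_tag His-tag sequence or `NULL` to disable (default
#'   `"MHHHHHH"`).
#' @param gs_linker GS linker sequence or `NULL` (default `"GSGS"`).
#' @param motif Cleavable motif sequence (default `"GPLGLAG"` for mmp;
#'   `"GSGS"` for photo).
#' @param linker_type `"mmp"` (protease) or `"photo"` (NP photolinker).
#' @param scissile_offset Position within the motif after which cleavage
#'   occurs (default 4 for `GPLG|LAG`; for photo, the NP insertion point
#'   within the motif, default 2).
#' @return List of class `afm_construct`: `segments` (tibble `label`,
#'   `sequence`, `mods` list-column), `cleavage_sites` (tibble `label`,
#'   `offset`, `agent`), `full_sequence`.
#' @export
assemble_construct <- function(binder_seq, mask_seq,
                               his_tag = "MHHHHHH",
                               gs_linker = "GSGS",
                               motif = NULL,
                               linker_type = c("mmp", "photo"),
                               scissile_offset = NULL) {
  linker_type <- match.arg(linker_type)
  if (is.null(binder_seq) || !nzchar(binder_seq) ||
      is.null(mask_seq) || !nzchar(mask_seq)) {
    abort("both binder and mask sequences are required")
  }
  if (is.null(motif)) motif <- if (linker_type == "mmp") "GPLGLAG" else "GSGS"
  if (is.null(scissile_offset)) scissile_offset <- if (linker_type == "mmp") 4L else 2L
  if (scissile_offset < 1 || scissile_offset >= nchar(motif) + (linker_type == "photo")) {
    abort("scissile_offset must lie inside the motif")
  }
  seg <- tibble(
    label = c("his_tag", "binder", "gs_linker", "cleavable_motif", "mask"),
    sequence = c(his_tag %||% "", binder_seq, gs_linker %||% "", motif, mask_seq)
  )
  seg <- seg[nzchar(seg$sequence), , drop = FALSE]
  check_aa(seg$sequence)
  seg$mods <- vector("list", nrow(seg))
  if (linker_type == "photo") {
    i <- which(seg$label == "cleavable_motif")
    seg$mods[[i]] <- tibble(position = as.integer(scissile_offset), mod = "np_linker")
  }
  sites <- tibble(
    label = "cleavable_motif",
    offset = as.integer(scissile_offset),
    agent = linker_type
  )
  structure(list(
    segments = seg,
    cleavage_sites = sites,
    full_sequence = paste0(seg$sequence, collapse = "")
  ), class = "afm_construct")
}

#' @export
print.afm_construct <- function(x, ...) {
  cat("<afm_construct> ", nchar(x$full_sequence), " aa: ",
      paste0(x$segments$label, "[", nchar(x$segments$sequence), "]", collapse = " - "),
      "\n  cleavage: ", paste0(x$cleavage_sites$agent, " in ", x$cleavage_sites$label,
                               " after offset ", x$cleavage_sites$offset, collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' Total mass of a construct
#'
#' @param construct An [afm_construct()].
#' @inheritParams peptide_mass
#' @return Mass in Da.
#' @export
construct_mass <- function(construct, scale = c("average", "monoisotopic"),
                           mod_table = modification_table()) {
  scale <- match.arg(scale)
  mods <- purrr::list_rbind(purrr::compact(construct$segments$mods))
  peptide_mass(construct$full_sequence,
               mods = if (nrow(mods %||% tibble()) > 0) mods else NULL,
               scale = scale, mod_table = mod_table)
}

#' Simulate cleavage of a construct
#'
#' Splits the chain at the registered cleavage site for the chosen agent
#' (MMP proteolysis at the scissile bond, or photolysis at the NP unit)
#' and reports both products with sequences and masses. If the construct
#' carries several sites for the agent, the leftmost is used and a
#' warning notes the multiplicity. Proteolysis is hydrolytic, so product
#' masses sum to the parent mass plus one water.
#'
#' @param construct An [afm_construct()].
#' @param agent `"mmp"` or `"photo"`.
#' @inheritParams peptide_mass
#' @return List of class `afm_cleavage`: `n_product` and `c_product`
#'   (each `sequence` + `mass`), `agent`, `water_added` (Da), `scale`,
#'   `parent_mass`.
#' @export
simulate_cleavage <- function(construct, agent = c("mmp", "photo"),
                              scale = c("average", "monoisotopic"),
                              mod_table = modification_table()) {
  agent <- match.arg(agent)
  scale <- match.arg(scale)
  sites <- construct$cleavage_sites
  sites <- sites[sites$agent == agent, , drop = FALSE]
  if (nrow(sites) == 0) abort(paste0("no cleavage site for agent '", agent, "'"))
  if (nrow(sites) > 1) {
    warn(paste0(nrow(sites), " sites for agent '", agent, "'; using the leftmost"))
    sites <- sites[1, , drop = FALSE]
  }
  seg <- construct$segments
  seg_i <- match(sites$label, seg$label)
  if (is.na(seg_i)) abort(paste0("cleavage segment '", sites$label, "' not in construct"))
  abs_pos <- sum(nchar(seg$sequence[seq_len(seg_i - 1)])) + sites$offset
  seq_n <- substr(construct$full_sequence, 1, abs_pos)
  seq_c <- substr(construct$full_sequence, abs_pos + 1, nchar(construct$full_sequence))
  if (!nzchar(seq_n) || !nzchar(seq_c)) abort("cleavage site at a chain terminus")
  if (agent == "mmp") {
    mods_n <- NULL
    mods_c <- NULL
  } else {
    # the NP unit splits into its two bookkeeping fragments
    mods_n <- "np_n_fragment"
    mods_c <- "np_c_fragment"
  }
  mass_n <- peptide_mass(seq_n, mods_n, scale, mod_table)
  mass_c <- peptide_mass(seq_c, mods_c, scale, mod_table)
  water <- if (scale == "average") WATER_AVG else WATER_MONO
  structure(list(
    n_product = list(sequence = seq_n, mass = mass_n),
    c_product = list(sequence = seq_c, mass = mass_c),
    agent = agent,
    scale = scale,
    water_added = water,
    parent_mass = construct_mass(construct, scale, mod_table)
  ), class = "afm_cleavage")
}

#' @export
print.afm_cleavage <- function(x, ...) {
  cat("<afm_cleavage> ", x$agent, " (", x$scale, " scale)\n",
      "  N product: ", nchar(x$n_product$sequence), " aa, ",
      sprintf("%.2f", x$n_product$mass), " Da\n",
      "  C product: ", nchar(x$c_product$sequence), " aa, ",
      sprintf("%.2f", x$c_product$mass), " Da\n",
      "  parent: ", sprintf("%.2f", x$parent_mass), " Da\n", sep = "")
  invisible(x)
}
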