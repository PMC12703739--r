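# Three-letter <-> one-letter amino-acid code tables (20 standard residues).
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), unname(AA_THREE_TO_ONE))

CHAIN_ROLES <- c("binder", "mask", "receptor", "unassigned")

#' Build an atom-level structure tibble
#'
#' The package represents a (predicted) protein structure as a flat
#' atom-level tibble, one row per atom, with residues numbered 1-based and
#' sequentially within each chain. Chains carry a `role` column
#' (`"binder"`, `"mask"`, `"receptor"` or `"unassigned"`) that downstream
#' metrics use to find the right chains regardless of chain-id conventions.
#'
#' @param atoms A data frame with columns `chain` (single-character id),
#'   `resno` (1-based residue index within chain), `resname` (three-letter
#'   code), `atom` (atom name, e.g. `"CA"`), `element` (element symbol),
#'   `x`, `y`, `z` (coordinates in Angstrom). Optional: `role`,
#'   `author_resno` (original author numbering, kept as metadata).
#' @param model_id Label for the model (file stem by default when reading).
#'
#' @return A tibble of class `afm_structure`.
#' @export
afm_structure <- function(atoms, model_id = "model") {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"role" %in% names(atoms)) atoms$role <- "unassigned"
  if (!"author_resno" %in% names(atoms)) atoms$author_resno <- atoms$resno
  atoms$resno <- as.integer(atoms$resno)
  out <- atoms[, c("chain", "resno", "resname", "role", "atom", "element",
                   "x", "y", "z", "author_resno")]
  class(out) <- c("afm_structure", class(tibble()))
  attr(out, "model_id") <- model_id
  validate_structure(out)
}

#' @rdname afm_structure
#' @param s Object to test / validate.
#' @export
is_afm_structure <- function(s) inherits(s, "afm_structure")

validate_structure <- function(s) {
  if (nrow(s) == 0) abort("structure has no atoms")
  if (any(!is.finite(s$x) | !is.finite(s$y) | !is.finite(s$z))) {
    abort("non-finite atom coordinates")
  }
  if (any(!nzchar(s$atom))) abort("empty atom name")
  if (any(s$resno < 1L)) abort("residue indices must be >= 1")
  bad_role <- setdiff(unique(s$role), CHAIN_ROLES)
  if (length(bad_role) > 0) {
    abort(paste0("unknown chain role(s): ", paste(bad_role, collapse = ", ")))
  }
  # residue indices strictly increasing within each chain (atom order aside)
  per_chain <- split(s$resno, s$chain)
  for (ch in names(per_chain)) {
    idx <- unique(per_chain[[ch]])
    if (any(diff(idx) <= 0)) {
      abort(paste0("residue indices not strictly increasing in chain ", ch))
    }
  }
  # one role per chain
  role_tab <- distinct(as_tibble(s)[, c("chain", "role")])
  if (anyDuplicated(role_tab$chain)) abort("conflicting roles within a chain")
  s
}

#' @export
print.afm_structure <- function(x, ...) {
  ch <- structure_chains(x)
  cat("<afm_structure> model '", attr(x, "model_id") %||% "?", "': ",
      nrow(ch), " chain(s), ", sum(ch$n_residues), " residues, ",
      nrow(x), " atoms\n", sep = "")
  print(ch, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain- and residue-level views of a structure
#'
#' @param s An `afm_structure`.
#' @return `structure_chains()`: one row per chain (id, role, residue and
#'   atom counts). `structure_residues()`: one row per residue (`chain`,
#'   `resno`, `resname`, `role`, `n_atoms`).
#' @export
structure_chains <- function(s) {
  s %>%
    as_tibble() %>%
    group_by(.data$chain, .data$role) %>%
    summarise(n_residues = dplyr::n_distinct(.data$resno),
              n_atoms = n(), .groups = "drop") %>%
    arrange(.data$chain)
}

#' @rdname structure_chains
#' @export
structure_residues <- function(s) {
  s %>%
    as_tibble() %>%
    group_by(.data$chain, .data$resno, .data$resname, .data$role) %>%
    summarise(n_atoms = n(), .groups = "drop") %>%
    arrange(.data$chain, .data$resno)
}

#' Assign biological roles to chains
#'
#' @param s An `afm_structure`.
#' @param roles Named character vector mapping chain id to role, e.g.
#'   `c(A = "binder", B = "mask")`. Unmentioned chains keep their role.
#' @return The structure with updated `role` column.
#' @export
assign_roles <- function(s, roles) {
  bad <- setdiff(unname(roles), CHAIN_ROLES)
  if (length(bad) > 0) abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  missing_ch <- setdiff(names(roles), unique(s$chain))
  if (length(missing_ch) > 0) {
    abort(paste0("chain(s) not in structure: ", paste(missing_ch, collapse = ", ")))
  }
  hit <- s$chain %in% names(roles)
  s$role[hit] <- unname(roles[s$chain[hit]])
  validate_structure(s)
}

#' Extract the amino-acid sequence of a chain
#'
#' @param s An `afm_structure`.
#' @param chain Chain id; if `NULL` and the structure has one chain, that
#'   chain is used.
#' @return One-letter sequence string (unknown residues become `X`).
#' @export
chain_sequence <- function(s, chain = NULL) {
  if (is.null(chain)) {
    ids <- unique(s$chain)
    if (length(ids) != 1) abort("chain must be given for a multi-chain structure")
    chain <- ids
  }
  res <- structure_residues(s)
  res <- res[res$chain == chain, ]
  if (nrow(res) == 0) abort(paste0("no chain '", chain, "' in structure"))
  one <- AA_THREE_TO_ONE[res$resname]
  one[is.na(one)] <- "X"
  paste0(one, collapse = "")
}

#' Read a structure from PDB or mmCIF
#'
#' Parses the file with bio3d and canonicalises it into the package's
#' atom-tibble model: protein residues only, alternate locations resolved
#' to the highest-occupancy conformer, hydrogens retained, and residues
#' renumbered 1-based sequentially per chain (author numbering preserved in
#' `author_resno`). Files with insertion codes are rejected rather than
#' silently renumbered, because all cross-model metrics here pair residues
#' by index.
#'
#' @param path File path.
#' @param format `"pdb"` (default) or `"mmcif"`.
#' @return An [afm_structure()] tibble.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
    },
    error = function(e) abort(paste0("unreadable ", format, " file: ", conditionMessage(e)))
  )
  at <- pdb$atom
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(ins))) {
    abort("residue insertion codes present; renumber the input first (unsupported)")
  }
  protein <- at$resid %in% names(AA_THREE_TO_ONE)
  at <- at[protein, , drop = FALSE]
  if (nrow(at) == 0) abort("zero protein residues")
  # resolve altloc: keep highest occupancy per (chain, resno, atom name)
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & nzchar(alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  chain_id <- at$chain
  chain_id[is.na(chain_id) | !nzchar(chain_id)] <- "A"
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- ifelse(is.na(elem) | !nzchar(elem), guess_element(at$elety), elem)
  # 1-based sequential renumbering per chain, in file order
  resno_new <- integer(nrow(at))
  for (ch in unique(chain_id)) {
    i <- which(chain_id == ch)
    resno_new[i] <- match(at$resno[i], unique(at$resno[i]))
  }
  afm_structure(
    tibble(
      chain = chain_id,
      resno = resno_new,
      resname = at$resid,
      atom = at$elety,
      element = elem,
      x = at$x, y = at$y, z = at$z,
      author_resno = at$resno
    ),
    model_id = sub("\\.(pdb|cif|mmcif)$", "", basename(path))
  )
}

# Element from a protein atom name: strip leading digits, take first letter.
# Correct for standard protein atoms (CA -> C, HG1 -> H, OXT -> O, SD -> S).
guess_element <- function(atom_names) {
  stripped <- sub("^[0-9]+", "", atom_names)
  toupper(substr(stripped, 1, 1))
}

#' Write a structure as a PDB file
#'
#' @param s An [afm_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  validate_structure(s)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$resno,
    resid = s$resname,
    eleno = seq_len(nrow(s)),
    elety = s$atom,
    chain = s$chain,
    o = rep(1, nrow(s)),
    b = rep(0, nrow(s))
  )
  invisible(path)
}

#' Coordinates of selected atoms as a matrix
#'
#' @param s An `afm_structure`.
#' @param chain Optional chain id filter.
#' @param atom_mode `"heavy"` (non-hydrogen, default), `"ca"` (C-alpha
#'   only) or `"all"`.
#' @return N x 3 numeric matrix; rownames `chain:resno`.
#' @export
atom_coords <- function(s, chain = NULL, atom_mode = c("heavy", "ca", "all")) {
  atom_mode <- match.arg(atom_mode)
  a <- as_tibble(s)
  if (!is.null(chain)) {
    a <- a[a$chain %in% chain, , drop = FALSE]
    if (nrow(a) == 0) abort(paste0("no chain '", paste(chain, collapse = ","), "' in structure"))
  }
  a <- switch(atom_mode,
    heavy = a[a$element != "H", , drop = FALSE],
    ca = a[a$atom == "CA", , drop = FALSE],
    all = a
  )
  if (nrow(a) == 0) abort(paste0("no atoms left under atom_mode = '", atom_mode, "'"))
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, sep = ":")
  m
}
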