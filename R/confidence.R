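#' Confidence data: per-residue pLDDT and pairwise PAE
#'
#' `afm_confidence()` bundles a per-residue pLDDT vector (0-100) with a
#' square predicted-aligned-error (PAE) matrix in Angstrom, plus an
#' optional `residue_map` tibble (`chain`, `resno`) aligning matrix
#' positions to structure residues *by order* — the convention of
#' AlphaFold-style outputs, where confidence rows follow the residues of
#' the prediction in sequence order.
#'
#' @param plddt Numeric vector of per-residue scores in \[0, 100\].
#' @param pae Square numeric matrix, entries >= 0, side `length(plddt)`.
#' @param residue_map Optional tibble with columns `chain`, `resno`, one
#'   row per matrix position, in order.
#' @return An object of class `afm_confidence`.
#' @export
afm_confidence <- function(plddt, pae, residue_map = NULL) {
  plddt <- as.numeric(plddt)
  pae <- as.matrix(pae)
  if (length(plddt) == 0) abort("empty pLDDT vector")
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100)) {
    abort("pLDDT values must be finite and in [0, 100]")
  }
  if (nrow(pae) != ncol(pae)) abort("PAE matrix must be square")
  if (nrow(pae) != length(plddt)) {
    abort(sprintf("dimension mismatch: pLDDT length %d vs PAE side %d",
                  length(plddt), nrow(pae)))
  }
  if (any(!is.finite(pae)) || any(pae < 0)) abort("PAE entries must be finite and >= 0")
  if (!is.null(residue_map)) {
    residue_map <- as_tibble(residue_map)
    if (!all(c("chain", "resno") %in% names(residue_map))) {
      abort("residue_map needs columns chain, resno")
    }
    if (nrow(residue_map) != length(plddt)) {
      abort(sprintf("dimension mismatch: residue_map has %d rows for %d residues",
                    nrow(residue_map), length(plddt)))
    }
    if (anyDuplicated(paste(residue_map$chain, residue_map$resno))) {
      abort("residue_map positions not unique")
    }
  }
  structure(list(plddt = plddt, pae = unname(pae), residue_map = residue_map),
            class = "afm_confidence")
}

#' @export
print.afm_confidence <- function(x, ...) {
  cat("<afm_confidence> ", length(x$plddt), " residues; mean pLDDT ",
      round(mean(x$plddt), 1), "; mean PAE ", round(mean(x$pae), 2), " A",
      if (is.null(x$residue_map)) "; no residue map" else "; mapped",
      "\n", sep = "")
  invisible(x)
}

#' Read confidence data from JSON
#'
#' Three common serialisations ("dialects") of model-confidence output are
#' supported and canonicalised into the same [afm_confidence()] object:
#'
#' * `plain`: `{"plddt": [...], "pae": [[...]]}`
#' * `af_pkl_json`: `{"plddt": [...], "predicted_aligned_error": [[...]]}`
#'   (the keys used by AlphaFold pickle dumps re-serialised as JSON)
#' * `afdb`: an array holding one object with parallel `residue1`,
#'   `residue2`, `distance` vectors (the AFDB PAE triplet layout) plus a
#'   `plddt` vector.
#'
#' @param path JSON file path.
#' @param dialect One of `"plain"`, `"af_pkl_json"`, `"afdb"`.
#' @return An [afm_confidence()] (without residue map; see
#'   [attach_confidence()]).
#' @export
read_confidence <- function(path, dialect = c("plain", "af_pkl_json", "afdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (dialect == "plain") {
    if (!all(c("plddt", "pae") %in% names(j))) abort("plain dialect needs keys plddt, pae")
    afm_confidence(j$plddt, j$pae)
  } else if (dialect == "af_pkl_json") {
    if (!all(c("plddt", "predicted_aligned_error") %in% names(j))) {
      abort("af_pkl_json dialect needs keys plddt, predicted_aligned_error")
    }
    afm_confidence(j$plddt, j$predicted_aligned_error)
  } else {
    # afdb: array of one record with residue1/residue2/distance triplets
    if (is.data.frame(j)) j <- as.list(j)
    if (!is.null(names(j)) && all(c("residue1", "residue2", "distance") %in% names(j))) {
      rec <- j
    } else if (length(j) >= 1) {
      rec <- j[[1]]
    } else {
      abort("afdb dialect: empty JSON array")
    }
    need <- c("residue1", "residue2", "distance", "plddt")
    if (!all(need %in% names(rec))) {
      abort(paste0("afdb dialect needs keys ", paste(need, collapse = ", ")))
    }
    r1 <- unlist(rec$residue1); r2 <- unlist(rec$residue2)
    d <- unlist(rec$distance); plddt <- unlist(rec$plddt)
    n <- length(plddt)
    if (length(r1) != n * n || length(r2) != n * n || length(d) != n * n) {
      abort(sprintf("dimension mismatch: %d PAE triplets for %d residues", length(d), n))
    }
    pae <- matrix(NA_real_, n, n)
    pae[cbind(r1, r2)] <- d
    if (any(is.na(pae))) abort("afdb dialect: incomplete residue pair coverage")
    afm_confidence(plddt, pae)
  }
}

#' Write confidence data as plain-dialect JSON
#'
#' @param conf An [afm_confidence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confidence <- function(conf, path) {
  stopifnot(inherits(conf, "afm_confidence"))
  jsonlite::write_json(
    list(plddt = conf$plddt, pae = conf$pae),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Align confidence data to a structure
#'
#' Attaches a residue map built from the structure's residues in (chain,
#' index) order. Errors if the residue counts disagree.
#'
#' @param conf An [afm_confidence()].
#' @param s An [afm_structure()].
#' @return The confidence object with `residue_map` set.
#' @export
attach_confidence <- function(conf, s) {
  stopifnot(inherits(conf, "afm_confidence"))
  res <- structure_residues(s)
  if (nrow(res) != length(conf$plddt)) {
    abort(sprintf("dimension mismatch: structure has %d residues, confidence has %d",
                  nrow(res), length(conf$plddt)))
  }
  afm_confidence(conf$plddt, conf$pae, residue_map = res[, c("chain", "resno")])
}

# Resolve a selection (tibble chain/resno, "all", or role name given a map)
# to integer positions in the confidence arrays.
confidence_positions <- function(conf, selection) {
  if (is.null(conf$residue_map)) abort("confidence has no residue map; call attach_confidence()")
  map_key <- paste(conf$residue_map$chain, conf$residue_map$resno)
  if (is.character(selection) && length(selection) == 1 && selection == "all") {
    return(seq_along(map_key))
  }
  if (!is.data.frame(selection)) abort("selection must be 'all' or a tibble with chain, resno")
  if (!all(c("chain", "resno") %in% names(selection))) {
    abort("selection needs columns chain, resno")
  }
  if (nrow(selection) == 0) abort("empty selection")
  pos <- match(paste(selection$chain, selection$resno), map_key)
  if (any(is.na(pos))) {
    bad <- paste0(selection$chain, ":", selection$resno)[is.na(pos)]
    abort(paste0("unknown residue(s) in selection: ", paste(head(bad, 5), collapse = ", ")))
  }
  pos
}
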