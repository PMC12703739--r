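VALID_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
              "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read and write FASTA amino-acid sequences
#'
#' Thin tidy wrappers over Biostrings. Sequences must use the 20 standard
#' one-letter codes (plus `X`); anything else is an error, so typos and
#' nucleotide files are caught at the door. `write_fasta()` wraps at 60
#' columns and round-trips through `read_fasta()` exactly.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  out <- tibble(id = names(set), sequence = unname(as.character(set)))
  check_aa(out$sequence)
  out
}

#' @rdname read_fasta
#' @param records Tibble (or data frame) with columns `id`, `sequence`.
#' @export
write_fasta <- function(records, path) {
  records <- as_tibble(records)
  if (!all(c("id", "sequence") %in% names(records))) {
    abort("records needs columns id, sequence")
  }
  check_aa(records$sequence)
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

check_aa <- function(seqs) {
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- setdiff(unique(chars), VALID_AA)
    if (length(bad) > 0) {
      abort(paste0("illegal amino-acid character(s) in sequence ", i, ": ",
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(seqs)
}
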