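#' Build a sequence table
#'
#' Sequence collections (contigs, reads, scaffolds, pseudo-reads) are plain
#' tibbles with columns `id`, `seq`, `length` and an optional `desc`. This
#' constructor normalizes sequences to uppercase over the alphabet
#' `{A,C,G,T,N}` and checks id uniqueness.
#'
#' @param id Character vector of unique, non-empty sequence names.
#' @param seq Character vector of nucleotide sequences.
#' @param desc Optional character vector of free-text descriptions.
#' @param normalize Uppercase and replace characters outside `ACGTN` by `N`
#'   (with a message giving the replaced count)? Default `TRUE`.
#' @return A tibble with columns `id`, `seq`, `length` (and `desc` if given).
#' @export
#' @examples
#' seq_records(c("a", "b"), c("acgt", "GGNN"))
seq_records <- function(id, seq, desc = NULL, normalize = TRUE) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) abort("`id` and `seq` must have equal length")
  if (anyNA(id) || any(!nzchar(id))) abort("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (any(!nzchar(seq))) {
    abort(paste0("empty sequence for id(s): ",
                 paste(id[!nzchar(seq)], collapse = ", ")))
  }
  if (normalize) {
    seq <- toupper(seq)
    n_bad <- sum(nchar(gsub("[ACGTN]", "", seq)))
    if (n_bad > 0) {
      seq <- gsub("[^ACGTN]", "N", seq)
      inform(sprintf("replaced %d non-ACGTN character(s) by N", n_bad))
    }
  }
  out <- tibble(id = id, seq = unname(seq), length = nchar(seq))
  if (!is.null(desc)) out$desc <- desc
  out
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# named length lookup from a sequence table
seq_len_map <- function(records) setNames(records$length, records$id)
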