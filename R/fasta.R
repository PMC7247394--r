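#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercase-normalized; characters outside `{A,C,G,T,N}` are
#' replaced by `N` (never dropped, so lengths are conserved) and the replaced
#' count is reported. Record order is preserved. Ids are the first
#' whitespace-delimited token of the header; the remainder becomes `desc`.
#' Gzip-compressed files are accepted transparently.
#'
#' @param path Path to a FASTA file (`.gz` allowed).
#' @return Tibble with columns `id`, `seq`, `length`, `desc`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) return(seq_records(character(), character(), character()))
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(ids, as.character(ss), desc = desc)
}

#' Write a sequence table to FASTA
#'
#' Round-trip safe: `read_fasta(write_fasta(x))` reproduces ids, sequences and
#' order exactly.
#'
#' @param records Sequence table (see [seq_records()]).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param line_width Bases per sequence line (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 80) {
  stopifnot(line_width >= 1)
  ss <- Biostrings::BStringSet(setNames(as.character(records$seq), records$id))
  if ("desc" %in% names(records) && any(nzchar(records$desc))) {
    names(ss) <- ifelse(nzchar(records$desc),
                        paste(records$id, records$desc), records$id)
  }
  Biostrings::writeXStringSet(ss, path, width = line_width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
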