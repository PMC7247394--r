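#' Read a PAF alignment file
#'
#' Parses the 12 mandatory tab-separated PAF columns into a tibble; optional
#' SAM-style tags from column 13 onward are preserved verbatim in a single
#' `tags` string. Coordinates are 0-based half-open as in the format itself.
#' Every record is validated against the PAF interval invariants; violations
#' fail loudly with the offending line number (no silent clamping).
#'
#' @param path Path to a PAF file (`.gz` allowed).
#' @return A PAF tibble with columns `query_name`, `query_length`,
#'   `query_start`, `query_end`, `strand`, `target_name`, `target_length`,
#'   `target_start`, `target_end`, `matches`, `block_length`, `mapq`, `tags`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(validate_paf(empty_paf()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("PAF line %d has %d column(s); 12 required",
                  which(nf < 12)[1], nf[which(nf < 12)[1]]))
  }
  col <- function(i) map_chr(fields, i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x)) {
      abort(sprintf("PAF line %d: non-numeric %s", which(is.na(x))[1], what))
    }
    x
  }
  paf <- tibble(
    query_name = col(1), query_length = num(2, "query length"),
    query_start = num(3, "query start"), query_end = num(4, "query end"),
    strand = col(5),
    target_name = col(6), target_length = num(7, "target length"),
    target_start = num(8, "target start"), target_end = num(9, "target end"),
    matches = num(10, "match count"), block_length = num(11, "block length"),
    mapq = num(12, "mapping quality"),
    tags = map_chr(fields, function(f) {
      if (length(f) > 12) paste(f[-(1:12)], collapse = "\t") else NA_character_
    })
  )
  bad <- which(!paf$strand %in% c("+", "-"))
  if (length(bad)) abort(sprintf("PAF line %d: strand must be + or -", bad[1]))
  validate_paf(paf)
}

empty_paf <- function() {
  tibble(
    query_name = character(), query_length = numeric(),
    query_start = numeric(), query_end = numeric(), strand = character(),
    target_name = character(), target_length = numeric(),
    target_start = numeric(), target_end = numeric(),
    matches = numeric(), block_length = numeric(), mapq = numeric(),
    tags = character()
  )
}

#' Validate a PAF tibble against its interval invariants
#'
#' Checks `0 <= start < end <= length` on both query and target,
#' `matches <= block_length`, strand in `{+,-}`, and mapq in `{0..60, 255}`.
#'
#' @param paf A PAF tibble.
#' @return `paf`, invisibly validated (returned unchanged).
#' @export
validate_paf <- function(paf) {
  need <- setdiff(names(empty_paf()), "tags")
  miss <- setdiff(need, names(paf))
  if (length(miss)) abort(paste0("PAF tibble missing column(s): ",
                                 paste(miss, collapse = ", ")))
  ok <- paf$query_start >= 0 & paf$query_start < paf$query_end &
    paf$query_end <= paf$query_length &
    paf$target_start >= 0 & paf$target_start < paf$target_end &
    paf$target_end <= paf$target_length &
    paf$matches <= paf$block_length &
    paf$strand %in% c("+", "-") &
    (paf$mapq %in% 0:60 | paf$mapq == 255)
  if (any(!ok)) {
    abort(sprintf("PAF record %d violates interval/field invariants",
                  which(!ok)[1]))
  }
  paf
}

#' Write a PAF tibble to a file
#'
#' @param paf A PAF tibble (see [read_paf()]).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(
    paf$query_name, fmt(paf$query_length), fmt(paf$query_start),
    fmt(paf$query_end), paf$strand, paf$target_name, fmt(paf$target_length),
    fmt(paf$target_start), fmt(paf$target_end), fmt(paf$matches),
    fmt(paf$block_length), fmt(paf$mapq), sep = "\t")
  has_tags <- if ("tags" %in% names(paf)) !is.na(paf$tags) else logical(nrow(paf))
  lines[has_tags] <- paste(lines[has_tags], paf$tags[has_tags], sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Keep only high mapping-quality alignments
#'
#' Mapping quality 60 marks the most uniquely placed alignments; filtering at
#' 60 before rearrangement counting discards repeat-mediated placements.
#' Record order is preserved.
#'
#' @param paf A PAF tibble.
#' @param min_mapq Minimum mapping quality to keep (default 60).
#' @return Filtered PAF tibble.
#' @export
filter_mq <- function(paf, min_mapq = 60) {
  paf[paf$mapq >= min_mapq, , drop = FALSE]
}
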