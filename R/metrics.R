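#' Nxx length statistic
#'
#' The smallest length `L` such that sequences of length `>= L` together cover
#' at least `x` percent of the total assembled length. `nxx(lengths, 50)` is
#' the familiar N50.
#'
#' @param lengths Numeric vector of sequence lengths (all `>= 1`).
#' @param x Percentage threshold in `(0, 100]` (default 50).
#' @return The Nxx length in bases.
#' @export
#' @examples
#' nxx(c(10, 8, 6, 4, 2)) # 8
nxx <- function(lengths, x = 50) {
  if (length(lengths) == 0) abort("nxx of an empty length set is undefined")
  stopifnot(all(lengths >= 1), x > 0, x <= 100)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= x / 100 * sum(s))[1]]
}

lxx <- function(lengths, x = 50) {
  s <- sort(lengths, decreasing = TRUE)
  which(cumsum(s) >= x / 100 * sum(s))[1]
}

#' Ungapped sequence length
#'
#' @param seq Character vector of normalized sequences.
#' @return Number of non-`N` characters in each sequence.
#' @export
ungapped_length <- function(seq) {
  nchar(seq) - nchar(gsub("[^N]", "", seq))
}

#' Fraction of assembly in the top n largest sequences
#'
#' With `n` equal to the haploid chromosome number this measures
#' chromosome-scale completeness: the share of assembled bases contained in the
#' `n` largest scaffolds. Computed on ungapped lengths when those are supplied.
#'
#' @param lengths Numeric vector of (ungapped) sequence lengths.
#' @param n Number of largest sequences to sum (`>= 0`).
#' @return Ratio in `[0, 1]`; `1` when `n >=` the number of sequences, `0`
#'   when `n = 0`.
#' @export
top_n_fraction <- function(lengths, n) {
  stopifnot(n >= 0)
  if (n == 0) return(0)
  if (length(lengths) == 0) abort("empty length set with n > 0")
  sum(sort(lengths, decreasing = TRUE)[seq_len(min(n, length(lengths)))]) /
    sum(lengths)
}

#' Assembly summary metrics
#'
#' Computes sequence counts, total and ungapped length, N50/L50, gap counts
#' and the top-n completeness fraction for a sequence table. Contig-level
#' metrics are derived by splitting scaffolds at runs of `N` of at least
#' `min_gap_run` bases.
#'
#' @param records Sequence table (scaffolds or contigs).
#' @param n Top-n value for the completeness fraction (e.g., the haploid
#'   chromosome number); default 0 reports `NA`.
#' @param min_gap_run Minimum `N`-run length treated as a gap when deriving
#'   contigs from scaffolds (default 10).
#' @return One-row tibble: `n_sequences`, `total_length`, `ungapped_length`,
#'   `n50`, `l50`, `n_contigs`, `contig_n50`, `gap_count`, `gap_bases`,
#'   `top_n`, `top_n_fraction`.
#' @export
assembly_report <- function(records, n = 0, min_gap_run = 10) {
  if (nrow(records) == 0) abort("empty sequence collection")
  ungapped <- ungapped_length(records$seq)
  ctg <- split_at_gaps(records, min_gap_run)
  gap_runs <- gap_intervals(records, min_gap_run)
  tibble(
    n_sequences = nrow(records),
    total_length = sum(records$length),
    ungapped_length = sum(ungapped),
    n50 = nxx(records$length),
    l50 = lxx(records$length),
    n_contigs = nrow(ctg),
    contig_n50 = nxx(ctg$length),
    gap_count = nrow(gap_runs),
    gap_bases = sum(gap_runs$end - gap_runs$start),
    top_n = n,
    top_n_fraction = if (n > 0) top_n_fraction(ungapped, n) else NA_real_
  )
}

# maximal N-runs of length >= min_gap_run, 0-based half-open per sequence
gap_intervals <- function(records, min_gap_run = 10) {
  res <- map2(records$id, records$seq, function(id, s) {
    m <- gregexpr(sprintf("N{%d,}", min_gap_run), s)[[1]]
    if (m[1] == -1) return(NULL)
    tibble(name = id, start = as.numeric(m) - 1,
           end = as.numeric(m) - 1 + attr(m, "match.length"))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(name = character(), start = numeric(), end = numeric())
  }
  out
}

#' Split scaffolds into contigs at gap runs
#'
#' @param records Sequence table of scaffolds.
#' @param min_gap_run Minimum `N`-run length that counts as a gap (default 10).
#' @return Sequence table of contigs named `<scaffold>.<k>`; scaffolds without
#'   qualifying gap runs pass through under their own id.
#' @export
split_at_gaps <- function(records, min_gap_run = 10) {
  pieces <- map2(records$id, records$seq, function(id, s) {
    parts <- strsplit(gsub(sprintf("N{%d,}", min_gap_run), "\f", s), "\f",
                      fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 1) return(tibble(id = id, seq = parts))
    tibble(id = paste0(id, ".", seq_along(parts)), seq = parts)
  })
  out <- bind_rows(pieces)
  seq_records(out$id, out$seq, normalize = FALSE)
}
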