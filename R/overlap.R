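# Suffix-prefix overlap detection between two oriented sequences.
#
# Candidate overlap lengths are generated by k-mer seeding (exact k-mer
# matches between the tail of `a` and the head of `b` imply a diagonal, hence
# an overlap length); each candidate is verified end-anchored, longest first,
# by edit distance over the implied overlap region. Identity is
# matches / overlap-alignment length, approximated as 1 - dist/overlap. For
# overlaps beyond `verify_cap` bases the edit distance is evaluated on spaced
# chunks along the diagonal instead of the full region.
find_suffix_prefix_overlap <- function(a, b, min_overlap = 1000,
                                       min_identity = 0.95,
                                       max_search = 100000, kmer = 15,
                                       verify_cap = 20000) {
  la <- nchar(a); lb <- nchar(b)
  if (la < min_overlap || lb < min_overlap) return(NULL)
  tail_len <- min(la, max_search)
  head_len <- min(lb, max_search)
  a_tail <- substr(a, la - tail_len + 1, la)
  b_head <- substr(b, 1, head_len)
  n_pos <- head_len - kmer + 1
  if (n_pos < 1) return(NULL)
  step <- max(1L, floor(n_pos / 64))
  seeds <- unique(c(1L, seq(1L, n_pos, by = step)))
  cands <- unlist(lapply(seeds, function(j) {
    km <- substr(b_head, j, j + kmer - 1)
    hits <- gregexpr(km, a_tail, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(numeric(0))
    tail_len - hits + j
  }))
  cands <- sort(unique(cands[cands >= min_overlap & cands <= min(la, lb)]),
                decreasing = TRUE)
  for (ov in cands) {
    hit <- verify_overlap(substr(a, la - ov + 1, la), substr(b, 1, ov),
                          min_identity, verify_cap)
    if (!is.null(hit)) {
      return(list(overlap = ov, identity = hit$identity,
                  matches = hit$matches))
    }
  }
  NULL
}

verify_overlap <- function(x, y, min_identity, verify_cap = 20000) {
  ov <- nchar(x)
  if (x == y) return(list(identity = 1, matches = ov))
  if (ov <= verify_cap) {
    d <- as.numeric(adist(x, y))
    identity <- 1 - d / ov
    if (identity >= min_identity) {
      return(list(identity = identity, matches = ov - d))
    }
    return(NULL)
  }
  # spaced-chunk estimate along the diagonal for very long overlaps
  chunk <- 5000
  starts <- unique(pmin(ov - chunk + 1,
                        round(seq(1, ov - chunk + 1, length.out = 4))))
  ds <- map_dbl(starts, function(s) {
    adist(substr(x, s, s + chunk - 1), substr(y, s, s + chunk - 1))
  })
  identity <- 1 - mean(ds / chunk)
  if (identity >= min_identity) {
    list(identity = identity, matches = round(identity * ov))
  } else {
    NULL
  }
}

#' Stitch two gap-flanking sequences by their terminal overlap
#'
#' Searches the last `max_search` bases of `left` against the first
#' `max_search` bases of `right` for a suffix-prefix alignment, and accepts
#' the longest candidate of length at least `min_overlap` with identity at
#' least `min_identity`. The junction sequence is taken from the left flank by
#' convention (deterministic; consensus is left to downstream polishing).
#'
#' @param left,right Single-row sequence tables (or lists with `id` and `seq`)
#'   of the oriented flanks: `left`'s 3' end meets `right`'s 5' end.
#' @param min_overlap Minimum accepted overlap length in bases (default 1000).
#' @param min_identity Minimum accepted overlap identity (default 0.95).
#' @param max_search Bases searched from each flanking end (default 100000).
#' @return One-row tibble `left_id`, `right_id`, `overlap_length`, `identity`,
#'   `merged_length`, `merged_seq`, or `NULL` when no acceptable overlap
#'   exists. `merged_length = left + right - overlap_length` always holds.
#' @export
stitch_gap <- function(left, right, min_overlap = 1000, min_identity = 0.95,
                       max_search = 100000) {
  hit <- find_suffix_prefix_overlap(left$seq, right$seq,
                                    min_overlap = min_overlap,
                                    min_identity = min_identity,
                                    max_search = max_search)
  if (is.null(hit)) return(NULL)
  merged <- paste0(left$seq, substr(right$seq, hit$overlap + 1,
                                    nchar(right$seq)))
  tibble(left_id = left$id, right_id = right$id,
         overlap_length = hit$overlap, identity = hit$identity,
         merged_length = nchar(merged), merged_seq = merged)
}
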