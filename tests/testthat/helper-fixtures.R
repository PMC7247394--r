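# shared fixture builders; everything is generated in code under fixed seeds

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one PAF record with sensible defaults, overridable per field
paf_row <- function(query_name = "q", query_length = 1000, query_start = 0,
                    query_end = 500, strand = "+", target_name = "t",
                    target_length = 2000, target_start = 0, target_end = 500,
                    matches = NULL, block_length = NULL, mapq = 60,
                    tags = NA_character_) {
  span <- query_end - query_start
  tibble::tibble(
    query_name = query_name, query_length = query_length,
    query_start = query_start, query_end = query_end, strand = strand,
    target_name = target_name, target_length = target_length,
    target_start = target_start, target_end = target_end,
    matches = matches %||% span, block_length = block_length %||% span,
    mapq = mapq, tags = tags)
}
`%||%` <- rlang::`%||%`

# simple two-component plan: c1 (+), gap, c2 (-)
demo_plan <- function(len1 = 1000, gap = 100, len2 = 500) {
  scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:3, type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), orientation = c("+", NA, "-"),
    length = c(len1, gap, len2)))
}

# exhaustive-search assembler oracle: overlaps found by direct enumeration of
# every suffix-prefix length (all ordered pairs, both strands), merging the
# longest acceptable overlap each round, identical merge policy to the
# package's greedy assembler but sharing none of its code (no k-mer seeding,
# no banded verification)
oracle_exact_overlap <- function(a, b, min_overlap) {
  hi <- min(nchar(a), nchar(b))
  if (hi < min_overlap) return(0L)
  for (ov in seq(hi, min_overlap, by = -1)) {
    if (substring(a, nchar(a) - ov + 1) == substring(b, 1, ov)) return(ov)
  }
  0L
}

oracle_assemble <- function(records, min_overlap) {
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                 collapse = ""))
  seqs <- stats::setNames(records$seq, records$id)
  repeat {   # absorb exact containments
    done <- TRUE
    for (id in names(sort(nchar(seqs)))) {
      if (length(seqs) < 2) break
      rest <- seqs[setdiff(names(seqs), id)]
      contained <- any(vapply(rest, function(o) {
        nchar(o) >= nchar(seqs[[id]]) &&
          (grepl(seqs[[id]], o, fixed = TRUE) ||
             grepl(rc(seqs[[id]]), o, fixed = TRUE))
      }, logical(1)))
      if (contained) {
        seqs <- seqs[setdiff(names(seqs), id)]
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  repeat {
    if (length(seqs) < 2) break
    best <- NULL
    for (i in sort(names(seqs))) {
      for (j in sort(names(seqs))) {
        if (i == j) next
        for (ori in c("FF", "FR", "RF")) {
          a <- if (ori == "RF") rc(seqs[[i]]) else seqs[[i]]
          b <- if (ori == "FR") rc(seqs[[j]]) else seqs[[j]]
          ov <- oracle_exact_overlap(a, b, min_overlap)
          if (ov >= min_overlap && (is.null(best) || ov > best$ov)) {
            best <- list(i = i, j = j, a = a, b = b, ov = ov)
          }
        }
      }
    }
    if (is.null(best)) break
    merged <- paste0(best$a, substring(best$b, best$ov + 1))
    keep_id <- min(best$i, best$j)
    seqs <- seqs[setdiff(names(seqs), c(best$i, best$j))]
    seqs[[keep_id]] <- merged
  }
  seqs
}

# canonical form of a sequence set, invariant to order and orientation
canonical_set <- function(seqs) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  sort(pmin(unname(unlist(seqs)), rc(unname(unlist(seqs)))))
}
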