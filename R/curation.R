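#' Per-base coverage profiles from alignments
#'
#' Builds a run-length coverage profile for each contig from read-to-assembly
#' alignments: depth at a position is the number of retained alignments whose
#' target interval contains it. Alignments below `min_mapq` are ignored.
#'
#' @param alignments PAF tibble with contigs as target.
#' @param contig_lengths Named vector mapping contig id to length. Every
#'   alignment target must be present; contigs without alignments get an
#'   all-zero profile.
#' @param min_mapq Minimum mapping quality for an alignment to contribute
#'   (default 0).
#' @return Tibble of depth runs: `contig_id`, `start`, `end` (0-based
#'   half-open), `depth`; runs tile `[0, length)` of every contig.
#' @export
coverage_from_alignments <- function(alignments, contig_lengths, min_mapq = 0) {
  unknown <- setdiff(unique(alignments$target_name), names(contig_lengths))
  if (length(unknown)) {
    abort(paste0("alignment to unknown contig: ", paste(unknown, collapse = ", ")))
  }
  over <- alignments$target_end > contig_lengths[alignments$target_name]
  if (any(over)) {
    abort(paste0("alignment beyond declared length of contig ",
                 alignments$target_name[which(over)[1]]))
  }
  aln <- alignments[alignments$mapq >= min_mapq, ]
  profiles <- imap(contig_lengths, function(len, cid) {
    hit <- aln[aln$target_name == cid, ]
    cov <- IRanges::coverage(
      IRanges::IRanges(start = hit$target_start + 1, end = hit$target_end),
      width = len)
    ends <- cumsum(S4Vectors::runLength(cov))
    tibble(contig_id = cid, start = ends - S4Vectors::runLength(cov),
           end = ends, depth = S4Vectors::runValue(cov))
  })
  bind_rows(profiles)
}

#' Extract paired 500-bp ends from long reads
#'
#' For each read of length at least `2 * end_length`, emits two
#' forward-oriented records `<read>/1` (first `end_length` bases) and
#' `<read>/2` (last `end_length` bases), with origin offsets in the
#' description. Mapped like ordinary reads, these end pairs add long-range
#' coverage evidence for zero-coverage splitting. Shorter reads are skipped
#' (and counted in the `n_skipped` attribute).
#'
#' @param reads Sequence table of long reads.
#' @param end_length Bases taken from each end (default 500).
#' @return Sequence table of end pairs with attribute `n_skipped`.
#' @export
make_read_end_pairs <- function(reads, end_length = 500) {
  stopifnot(end_length >= 1)
  keep <- reads$length >= 2 * end_length
  kept <- reads[keep, ]
  out <- seq_records(
    id = as.vector(rbind(paste0(kept$id, "/1"), paste0(kept$id, "/2"))),
    seq = as.vector(rbind(substr(kept$seq, 1, end_length),
                          substr(kept$seq, kept$length - end_length + 1,
                                 kept$length))),
    desc = as.vector(rbind(
      sprintf("origin=%s:0-%d:+", kept$id, end_length),
      sprintf("origin=%s:%d-%d:+", kept$id, kept$length - end_length,
              kept$length))),
    normalize = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Split points at internal zero-coverage regions
#'
#' Scans combined coverage profiles (typically raw reads plus read-end pairs)
#' for maximal runs of zero depth. Internal runs of length `>= min_zero_run`
#' yield one split at the run midpoint; runs touching a contig end (within
#' `end_trim` bases) are reported as trim intervals instead, since mapping end
#' effects would otherwise shatter every contig terminus.
#'
#' @param profiles Coverage-run tibble from [coverage_from_alignments()]
#'   (profiles from several evidence sets can be summed with
#'   [combine_coverage()] first).
#' @param min_zero_run Minimum zero-run length that triggers a split
#'   (default 1: any true zero-coverage base splits).
#' @param end_trim Zero runs starting or ending within this many bases of a
#'   contig end count as end runs (default 0: only runs touching the ends).
#' @return Split tibble (`contig_id`, `position`, `reason = "zero_coverage"`)
#'   with attribute `trims`: a tibble of end intervals (`contig_id`, `start`,
#'   `end`).
#' @export
find_zero_coverage_splits <- function(profiles, min_zero_run = 1, end_trim = 0) {
  lens <- profiles |>
    group_by(.data$contig_id) |>
    summarise(len = max(.data$end))
  zero <- profiles |>
    filter(.data$depth == 0) |>
    left_join(lens, by = "contig_id") |>
    mutate(at_end = .data$start <= end_trim | .data$end >= .data$len - end_trim)
  trims <- zero |> filter(.data$at_end) |> select("contig_id", "start", "end")
  splits <- zero |>
    filter(!.data$at_end, .data$end - .data$start >= min_zero_run) |>
    mutate(position = floor((.data$start + .data$end) / 2),
           reason = "zero_coverage") |>
    select("contig_id", "position", "reason")
  attr(splits, "trims") <- trims
  splits
}

#' Sum coverage profiles position-wise
#'
#' @param ... Coverage-run tibbles over the same contigs.
#' @return A single coverage-run tibble whose depth is the position-wise sum.
#' @export
combine_coverage <- function(...) {
  all <- bind_rows(...)
  combined <- all |>
    group_by(.data$contig_id) |>
    group_split() |>
    map(function(runs) {
      cuts <- sort(unique(c(runs$start, runs$end)))
      piece <- tibble(contig_id = runs$contig_id[1],
                      start = cuts[-length(cuts)], end = cuts[-1])
      piece$depth <- map_dbl(seq_len(nrow(piece)), function(i) {
        sum(runs$depth[runs$start <= piece$start[i] & runs$end >= piece$end[i]])
      })
      # re-merge equal-depth neighbours into maximal runs
      grp <- cumsum(c(TRUE, piece$depth[-1] != piece$depth[-nrow(piece)]))
      piece |>
        group_by(grp2 = grp) |>
        summarise(contig_id = .data$contig_id[1], start = min(.data$start),
                  end = max(.data$end), depth = .data$depth[1],
                  .groups = "drop") |>
        select("contig_id", "start", "end", "depth")
    })
  bind_rows(combined)
}

#' Identify partially mapped reads to rescue
#'
#' A read is rescued for re-assembly when the union of its aligned query
#' intervals covers less than `max_mapped_fraction` of its length (reads with
#' no alignments at all are rescued). The default threshold of 10% matches the
#' rescue rule for reads that can only partially be placed on the primary
#' assembly; a read at exactly the threshold is not rescued.
#'
#' @param alignments PAF tibble with reads as query.
#' @param read_lengths Named vector mapping every read id to its length
#'   (including reads absent from `alignments`).
#' @param max_mapped_fraction Strict upper bound on the mapped fraction of a
#'   rescued read (default 0.10).
#' @return Tibble `read_id`, `read_length`, `mapped_bases`, `mapped_fraction`,
#'   `rescued`.
#' @export
classify_partially_mapped_reads <- function(alignments, read_lengths,
                                            max_mapped_fraction = 0.10) {
  unknown <- setdiff(unique(alignments$query_name), names(read_lengths))
  if (length(unknown)) {
    abort(paste0("alignment for unknown read: ", paste(unknown, collapse = ", ")))
  }
  mapped <- alignments |>
    group_by(read_id = .data$query_name) |>
    summarise(mapped_bases = sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = .data$query_start + 1, end = .data$query_end)))))
  out <- tibble(read_id = names(read_lengths),
                read_length = as.numeric(read_lengths)) |>
    left_join(mapped, by = "read_id") |>
    mutate(mapped_bases = dplyr::coalesce(.data$mapped_bases, 0),
           mapped_fraction = .data$mapped_bases / .data$read_length,
           rescued = .data$mapped_fraction < max_mapped_fraction)
  out
}

#' Reconciliation splits from a companion assembly
#'
#' Compares assembly A to a companion assembly B built from the same reads
#' with different parameters: regions of an A-contig not covered by any
#' A-on-B alignment mark discrepancies between the two assemblies, which are
#' candidate misassemblies. Abutting or near-abutting alignments (gap at most
#' `coverage_tolerance`) count as continuous coverage regardless of which
#' B-contig they hit; each remaining internal uncovered run longer than
#' `coverage_tolerance` yields one split at its midpoint.
#'
#' @param alignments PAF tibble, A-contigs as query, B-contigs as target.
#' @param contig_lengths_A Named vector of A-contig lengths.
#' @param coverage_tolerance Maximum alignment gap (bases) still treated as
#'   continuous coverage (default 100).
#' @return Split tibble (`contig_id`, `position`, `reason = "reconciliation"`).
#' @export
reconcile_assemblies <- function(alignments, contig_lengths_A,
                                 coverage_tolerance = 100) {
  per_contig <- alignments |>
    group_by(.data$query_name) |>
    group_split() |>
    map(function(a) {
      merged <- IRanges::reduce(
        IRanges::IRanges(start = a$query_start + 1, end = a$query_end),
        min.gapwidth = coverage_tolerance + 1)
      if (length(merged) < 2) return(NULL)
      gap_start <- head(IRanges::end(merged), -1)      # 0-based half-open
      gap_end <- tail(IRanges::start(merged), -1) - 1
      tibble(contig_id = a$query_name[1],
             position = floor((gap_start + gap_end) / 2),
             reason = "reconciliation")
    })
  out <- bind_rows(per_contig)
  if (nrow(out) == 0) {
    out <- tibble(contig_id = character(), position = numeric(),
                  reason = character())
  }
  arrange(out, .data$contig_id, .data$position)
}

#' Materialize split points
#'
#' Cuts each contig before the stated positions. A contig with `k` splits
#' becomes `k + 1` fragments named `<id>.1 .. <id>.k+1` in left-to-right
#' order; the concatenation of the fragments equals the original sequence
#' (base conservation). Contigs without splits pass through unchanged.
#'
#' @param records Sequence table of contigs.
#' @param splits Split tibble with `contig_id` and `position` (0-based; cut is
#'   before this base, so `0 < position < length`).
#' @return Sequence table of fragments.
#' @export
apply_splits <- function(records, splits) {
  if (nrow(splits) > 0) {
    unknown <- setdiff(unique(splits$contig_id), records$id)
    if (length(unknown)) {
      abort(paste0("split for unknown contig: ", paste(unknown, collapse = ", ")))
    }
  }
  pieces <- map2(records$id, records$seq, function(id, s) {
    pos <- sort(unique(splits$position[splits$contig_id == id]))
    if (length(pos) == 0) return(tibble(id = id, seq = s))
    len <- nchar(s)
    if (any(pos <= 0 | pos >= len)) {
      abort(sprintf("split position outside (0, %d) for contig %s", len, id))
    }
    starts <- c(0, pos)
    ends <- c(pos, len)
    tibble(id = paste0(id, ".", seq_along(starts)),
           seq = substring(s, starts + 1, ends))
  })
  out <- bind_rows(pieces)
  seq_records(out$id, out$seq, normalize = FALSE)
}

#' Run the full Step-1 curation stage
#'
#' Combines the three curation signals: reconciliation splits against a
#' companion assembly (optional), zero-coverage splits from combined read and
#' read-end-pair coverage, and rescue classification of partially mapped
#' reads.
#'
#' @param contigs Sequence table of primary contigs.
#' @param read_paf Reads-on-contigs PAF tibble.
#' @param endpair_paf Optional end-pairs-on-contigs PAF tibble (coverage from
#'   it is summed with the read coverage before zero-run detection).
#' @param alt_paf Optional contigs-on-companion-assembly PAF tibble.
#' @param read_lengths Named read-length vector for rescue classification
#'   (optional; defaults to query lengths seen in `read_paf`).
#' @param min_mapq Minimum mapping quality for coverage evidence (default 0).
#' @param coverage_tolerance Reconciliation gap tolerance in bases
#'   (default 100).
#' @param min_zero_run Minimum zero-coverage run for a split (default 1).
#' @param max_mapped_fraction Rescue threshold (default 0.10).
#' @return List with `contigs` (curated fragments), `splits`, `trims`,
#'   `rescue` (classification tibble), and `counts` (one-row log tibble).
#' @export
curate_contigs <- function(contigs, read_paf, endpair_paf = NULL,
                           alt_paf = NULL, read_lengths = NULL, min_mapq = 0,
                           coverage_tolerance = 100, min_zero_run = 1,
                           max_mapped_fraction = 0.10) {
  lens <- seq_len_map(contigs)
  cov <- coverage_from_alignments(read_paf, lens, min_mapq = min_mapq)
  if (!is.null(endpair_paf) && nrow(endpair_paf) > 0) {
    cov <- combine_coverage(cov, coverage_from_alignments(endpair_paf, lens,
                                                          min_mapq = min_mapq))
  }
  zc <- find_zero_coverage_splits(cov, min_zero_run = min_zero_run)
  splits <- as_tibble(zc)
  if (!is.null(alt_paf)) {
    splits <- bind_rows(splits, reconcile_assemblies(
      alt_paf, lens, coverage_tolerance = coverage_tolerance))
  }
  if (is.null(read_lengths)) {
    read_lengths <- setNames(read_paf$query_length, read_paf$query_name)
    read_lengths <- read_lengths[!duplicated(names(read_lengths))]
  }
  rescue <- classify_partially_mapped_reads(
    read_paf, read_lengths, max_mapped_fraction = max_mapped_fraction)
  curated <- apply_splits(contigs, splits)
  list(
    contigs = curated,
    splits = splits,
    trims = attr(zc, "trims"),
    rescue = rescue,
    counts = tibble(
      n_contigs_in = nrow(contigs), n_contigs_out = nrow(curated),
      n_zero_coverage_splits = sum(splits$reason == "zero_coverage"),
      n_reconciliation_splits = sum(splits$reason == "reconciliation"),
      n_trims = nrow(attr(zc, "trims")), n_rescued = sum(rescue$rescued))
  )
}
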