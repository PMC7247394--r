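#' Extract read windows around scaffold gaps and ends
#'
#' For local reassembly, reads mapping within `window` bases of a scaffold gap
#' (or of a scaffold terminus) are collected per gap into distinct sets; a
#' read whose alignment overlaps a window by at least one base is included,
#' and a read may appear in several windows.
#'
#' @param plan A [scaffold_plan()].
#' @param read_alignments PAF tibble of reads aligned to the plan's scaffold
#'   sequences.
#' @param window Window half-width in bases around each gap, and the width of
#'   the terminal windows (default 20000).
#' @return Tibble `gap_id`, `scaffold_id`, `start`, `end` (0-based half-open,
#'   clamped to the scaffold), `kind` (`"gap"` or `"terminus"`), and a
#'   `read_ids` list-column.
#' @export
extract_gap_windows <- function(plan, read_alignments, window = 20000) {
  td <- tidy(plan)
  scaf_len <- td |>
    group_by(.data$scaffold_id) |>
    summarise(len = max(.data$scaffold_end))
  gaps <- td |>
    filter(.data$type == "N") |>
    group_by(.data$scaffold_id) |>
    mutate(gap_id = paste0(.data$scaffold_id, ":gap", row_number())) |>
    ungroup() |>
    left_join(scaf_len, by = "scaffold_id") |>
    mutate(start = pmax(0, .data$scaffold_start - window),
           end = pmin(.data$len, .data$scaffold_end + window),
           kind = "gap") |>
    select("gap_id", "scaffold_id", "start", "end", "kind")
  term <- scaf_len |>
    dplyr::reframe(
      gap_id = c(paste0(.data$scaffold_id, ":start"),
                 paste0(.data$scaffold_id, ":end")),
      scaffold_id = rep(.data$scaffold_id, 2),
      start = c(rep(0, n()), pmax(0, .data$len - window)),
      end = c(pmin(window, .data$len), .data$len),
      kind = "terminus")
  windows <- bind_rows(gaps, term) |>
    arrange(.data$scaffold_id, .data$start, .data$gap_id)
  windows$read_ids <- pmap(windows, function(scaffold_id, start, end, ...) {
    hit <- read_alignments$target_name == scaffold_id &
      read_alignments$target_start < end & read_alignments$target_end > start
    sort(unique(read_alignments$query_name[hit]))
  })
  windows
}

#' Chunk contigs into overlapping pseudo-reads
#'
#' Splits contigs into overlapping chunks so they can be fed back to a
#' long-read assembler alongside locally reassembled gap sequence; chunks are
#' capped at 256 kb to respect assembler read-length limits. Chunks start at
#' multiples of `step`; the final chunk ends at the contig end and may be
#' shorter, so the chunk union always covers the whole contig. Adjacent
#' chunks overlap by `chunk_length - step`.
#'
#' @param contigs Sequence table.
#' @param chunk_length Chunk size in bases (default 250000; must be
#'   `<= 256000`).
#' @param step Distance between chunk starts (default 200000; `0 < step <=
#'   chunk_length`).
#' @return Sequence table of pseudo-reads with ids `<contig>:<start>-<end>`
#'   encoding the origin offsets (0-based half-open).
#' @export
chunk_pseudo_reads <- function(contigs, chunk_length = 250000, step = 200000) {
  if (step <= 0) abort("step must be positive")
  if (step > chunk_length) abort("step must not exceed chunk_length")
  if (chunk_length > 256000) abort("chunk_length must not exceed 256000")
  pieces <- map2(contigs$id, contigs$seq, function(id, s) {
    len <- nchar(s)
    starts <- 0
    while (tail(starts, 1) + chunk_length < len) {
      starts <- c(starts, tail(starts, 1) + step)
    }
    ends <- pmin(starts + chunk_length, len)
    tibble(id = sprintf("%s:%d-%d", id, starts, ends),
           seq = substring(s, starts + 1, ends))
  })
  out <- bind_rows(pieces)
  seq_records(out$id, out$seq, normalize = FALSE)
}

#' Greedy overlap assembly of a read window
#'
#' A deliberately transparent, desk-scale overlap assembler used for local
#' gap reassembly: it repeatedly merges the pair of sequences (in either
#' orientation) with the longest suffix-prefix overlap of at least
#' `min_overlap` bases and identity at least `min_identity`, breaking ties by
#' identity (descending) then lexicographic id, until no merge qualifies.
#' Sequences exactly contained in another (either orientation) are absorbed
#' first. The interface is pluggable: any external assembler producing FASTA
#' can be substituted per window.
#'
#' @param sequences Sequence table of a window's reads (and/or pseudo-reads).
#' @param min_overlap Minimum merge overlap in bases (default 1000).
#' @param min_identity Minimum overlap identity (default 0.95).
#' @param kmer Seed k-mer length for overlap candidate detection (default 15).
#' @return Sequence table of assembled contigs; every input base is contained
#'   in exactly one output contig.
#' @export
greedy_overlap_assemble <- function(sequences, min_overlap = 1000,
                                    min_identity = 0.95, kmer = 15) {
  seqs <- setNames(as.character(sequences$seq), sequences$id)
  # absorb exact containments (either orientation)
  repeat {
    absorbed <- FALSE
    ids <- names(sort(nchar(seqs)))   # shortest first
    for (id in ids) {
      if (length(seqs) < 2) break
      others <- seqs[setdiff(names(seqs), id)]
      hit <- map_lgl(others, function(o) {
        nchar(o) >= nchar(seqs[[id]]) &&
          (grepl(seqs[[id]], o, fixed = TRUE) ||
             grepl(revcomp(seqs[[id]]), o, fixed = TRUE))
      })
      if (any(hit)) {
        seqs <- seqs[setdiff(names(seqs), id)]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) break
  }
  # pair overlaps are cached across rounds; a merge only invalidates pairs
  # that involve one of the two merged sequences
  cache <- new.env(parent = emptyenv())
  pair_overlap <- function(i, j, ori) {
    k <- paste(i, j, ori, sep = "\r")
    hit <- cache[[k]]
    if (!is.null(hit)) return(if (isFALSE(hit$ok)) NULL else hit)
    a <- if (ori == "RF") revcomp(seqs[[i]]) else seqs[[i]]
    b <- if (ori == "FR") revcomp(seqs[[j]]) else seqs[[j]]
    hit <- find_suffix_prefix_overlap(
      a, b, min_overlap = min_overlap, min_identity = min_identity,
      max_search = max(nchar(a), nchar(b)), kmer = kmer)
    cache[[k]] <- hit %||% list(ok = FALSE)
    hit
  }
  repeat {
    if (length(seqs) < 2) break
    best <- NULL
    ids <- sort(names(seqs))
    for (i in ids) {
      for (j in ids) {
        if (i == j) next
        for (ori in c("FF", "FR", "RF")) {
          hit <- pair_overlap(i, j, ori)
          if (is.null(hit)) next
          cand <- list(i = i, j = j, ori = ori, overlap = hit$overlap,
                       identity = hit$identity)
          if (is.null(best) || cand$overlap > best$overlap ||
              (cand$overlap == best$overlap && cand$identity > best$identity)) {
            best <- cand
          }
        }
      }
    }
    if (is.null(best)) break
    a <- if (best$ori == "RF") revcomp(seqs[[best$i]]) else seqs[[best$i]]
    b <- if (best$ori == "FR") revcomp(seqs[[best$j]]) else seqs[[best$j]]
    merged <- paste0(a, substr(b, best$overlap + 1, nchar(b)))
    new_id <- min(best$i, best$j)
    seqs <- seqs[setdiff(names(seqs), c(best$i, best$j))]
    seqs[[new_id]] <- merged
    stale <- Filter(function(k) {
      ids2 <- strsplit(k, "\r", fixed = TRUE)[[1]][1:2]
      any(ids2 %in% c(best$i, best$j))
    }, ls(cache, all.names = TRUE))
    rm(list = stale, envir = cache)
  }
  seq_records(names(seqs), unname(seqs), normalize = FALSE)
}

# oriented sequence of a W plan row
oriented_seq <- function(seqs, component_id, orientation) {
  s <- seqs[[component_id]]
  if (orientation == "-") revcomp(s) else s
}

#' Close scaffold gaps by patch contigs and direct stitching
#'
#' For every gap in the plan, first attempts patch-mediated closure: a patch
#' contig (e.g. from [greedy_overlap_assemble()] on the gap's read window)
#' whose ends overlap both flanks by at least `min_overlap` bases at identity
#' at least `min_identity` replaces the gap with its inter-flank sequence.
#' Failing that, the flanks are offered to [stitch_gap()] directly. Each
#' closure merges two components into one; running `close_gaps()` again on
#' its own output closes nothing further.
#'
#' @param plan A [scaffold_plan()].
#' @param contigs Sequence table containing every plan component.
#' @param patches Optional sequence table of patch contigs.
#' @param min_overlap,min_identity,max_search Acceptance thresholds, as in
#'   [stitch_gap()].
#' @return List with `plan` (updated [scaffold_plan()]), `contigs` (sequence
#'   table for the new plan: merged components plus untouched contigs), and
#'   `report` (per-gap tibble: `scaffold_id`, `gap_index`, `left_id`,
#'   `right_id`, `outcome` in patched/stitched/open, `overlap_left`,
#'   `overlap_right`, `identity`, `inserted_bases`).
#' @export
close_gaps <- function(plan, contigs, patches = NULL, min_overlap = 1000,
                       min_identity = 0.95, max_search = 100000) {
  validate_scaffold_plan(plan)
  seqs <- setNames(as.character(contigs$seq), contigs$id)
  patch_seqs <- if (!is.null(patches) && nrow(patches) > 0) {
    setNames(as.character(patches$seq), patches$id)
  } else {
    character(0)
  }
  report <- list()
  new_rows <- list()
  for (sid in unique(plan$scaffold_id)) {
    rows <- as_tibble(plan)[plan$scaffold_id == sid, ]
    # current walk state: last open component (id, orientation, seq)
    comps <- list()   # finished rows for this scaffold
    cur <- NULL
    pending_gap <- NULL
    gap_index <- 0
    for (r in seq_len(nrow(rows))) {
      row <- rows[r, ]
      if (row$type == "N") {
        pending_gap <- row$length
        next
      }
      nxt <- list(id = row$component_id, orientation = row$orientation,
                  seq = oriented_seq(seqs, row$component_id, row$orientation))
      if (is.null(cur)) {
        cur <- nxt
      } else {
        gap_index <- gap_index + 1
        closure <- close_one_gap(cur, nxt, patch_seqs, min_overlap,
                                 min_identity, max_search)
        report[[length(report) + 1]] <- mutate(
          closure$report, scaffold_id = sid, gap_index = gap_index,
          gap_length = pending_gap)
        if (closure$report$outcome == "open") {
          if (!cur$id %in% names(seqs)) seqs[[cur$id]] <- cur$seq
          comps[[length(comps) + 1]] <- tibble(
            scaffold_id = sid, type = "W", component_id = cur$id,
            orientation = cur$orientation, length = nchar(cur$seq))
          comps[[length(comps) + 1]] <- tibble(
            scaffold_id = sid, type = "N", component_id = NA_character_,
            orientation = NA_character_, length = pending_gap)
          cur <- nxt
        } else {
          cur <- closure$merged
        }
        pending_gap <- NULL
      }
    }
    if (!is.null(cur)) {
      comps[[length(comps) + 1]] <- tibble(
        scaffold_id = sid, type = "W", component_id = cur$id,
        orientation = cur$orientation, length = nchar(cur$seq))
      # merged components are stored already oriented, under orientation "+"
      if (!cur$id %in% names(seqs)) seqs[[cur$id]] <- cur$seq
    }
    new_rows[[length(new_rows) + 1]] <- bind_rows(comps)
  }
  components <- bind_rows(new_rows) |>
    group_by(.data$scaffold_id) |>
    mutate(part_number = row_number()) |>
    ungroup() |>
    select("scaffold_id", "part_number", "type", "component_id",
           "orientation", "length")
  new_plan <- scaffold_plan(components, unplaced = unplaced_ids(plan))
  used <- c(components$component_id[components$type == "W"],
            unplaced_ids(plan))
  report_tbl <- bind_rows(report)
  if (nrow(report_tbl) == 0) {
    report_tbl <- tibble(left_id = character(), right_id = character(),
                         outcome = character(), overlap_left = numeric(),
                         overlap_right = numeric(), identity = numeric(),
                         inserted_bases = numeric(),
                         scaffold_id = character(), gap_index = integer(),
                         gap_length = numeric())
  }
  list(plan = new_plan,
       contigs = seq_records(used, unname(seqs[used]), normalize = FALSE),
       report = select(report_tbl, "scaffold_id", "gap_index", "left_id",
                       "right_id", "outcome", "overlap_left", "overlap_right",
                       "identity", "inserted_bases", "gap_length"))
}

# attempt to close the gap between two oriented flank components
close_one_gap <- function(left, right, patch_seqs, min_overlap, min_identity,
                          max_search) {
  open_report <- tibble(left_id = left$id, right_id = right$id,
                        outcome = "open", overlap_left = NA_real_,
                        overlap_right = NA_real_, identity = NA_real_,
                        inserted_bases = NA_real_)
  merged_id <- paste0(left$id, "|", right$id)
  # 1) patch-mediated closure: a patch aligning across both flanks
  best <- NULL
  for (pid in names(patch_seqs)) {
    for (p in c(patch_seqs[[pid]], revcomp(patch_seqs[[pid]]))) {
      ov1 <- find_suffix_prefix_overlap(left$seq, p, min_overlap,
                                        min_identity, max_search)
      if (is.null(ov1)) next
      ov2 <- find_suffix_prefix_overlap(p, right$seq, min_overlap,
                                        min_identity, max_search)
      if (is.null(ov2)) next
      insert_len <- nchar(p) - ov1$overlap - ov2$overlap
      if (insert_len < 0) next
      score <- ov1$overlap + ov2$overlap
      if (is.null(best) || score > best$score) {
        best <- list(p = p, ov1 = ov1, ov2 = ov2, insert_len = insert_len,
                     score = score)
      }
    }
  }
  if (!is.null(best)) {
    insert <- substr(best$p, best$ov1$overlap + 1,
                     nchar(best$p) - best$ov2$overlap)
    merged <- paste0(left$seq, insert, right$seq)
    return(list(
      merged = list(id = merged_id, orientation = "+", seq = merged),
      report = tibble(left_id = left$id, right_id = right$id,
                      outcome = "patched", overlap_left = best$ov1$overlap,
                      overlap_right = best$ov2$overlap,
                      identity = min(best$ov1$identity, best$ov2$identity),
                      inserted_bases = best$insert_len)))
  }
  # 2) direct flank-to-flank stitch
  st <- stitch_gap(list(id = left$id, seq = left$seq),
                   list(id = right$id, seq = right$seq),
                   min_overlap = min_overlap, min_identity = min_identity,
                   max_search = max_search)
  if (!is.null(st)) {
    return(list(
      merged = list(id = merged_id, orientation = "+", seq = st$merged_seq),
      report = tibble(left_id = left$id, right_id = right$id,
                      outcome = "stitched", overlap_left = st$overlap_length,
                      overlap_right = NA_real_, identity = st$identity,
                      inserted_bases = -st$overlap_length)))
  }
  list(merged = NULL, report = open_report)
}
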