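#' Simulate a multi-chromosome reference genome
#'
#' I.i.d. bases with the requested GC content; chromosomes are named
#' `chr1..chrK`. Bit-reproducible for a fixed seed.
#'
#' @param chrom_lengths Vector of chromosome lengths (bases, all `>= 1`).
#' @param gc GC fraction in `(0, 1)` (default 0.5).
#' @param seed Integer seed.
#' @return Sequence table of chromosomes.
#' @export
simulate_reference <- function(chrom_lengths, gc = 0.5, seed = 1) {
  if (gc <= 0 || gc >= 1) abort("gc must be strictly between 0 and 1")
  stopifnot(all(chrom_lengths >= 1))
  set.seed(seed)
  bytes <- charToRaw("ACGT")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- map_chr(chrom_lengths, function(len) {
    rawToChar(bytes[sample.int(4, len, replace = TRUE, prob = probs)])
  })
  seq_records(paste0("chr", seq_along(chrom_lengths)), seqs, normalize = FALSE)
}

# --- segment maps -----------------------------------------------------------
# A sample chromosome is described by an ordered tibble of segments
# (ref_name, ref_start, ref_end, strand); concatenating the segments (reverse-
# complemented for "-") reproduces its sequence. Rearrangements are edits of
# this list, so truth alignments are exact by construction.

identity_segments <- function(genome) {
  setNames(map2(genome$id, genome$length, function(id, len) {
    tibble(ref_name = id, ref_start = 0, ref_end = len, strand = "+")
  }), genome$id)
}

seg_sample_ends <- function(segs) cumsum(segs$ref_end - segs$ref_start)

# cut the segment list so that sample position `pos` is a segment boundary
split_segs_at <- function(segs, pos) {
  ends <- seg_sample_ends(segs)
  starts <- ends - (segs$ref_end - segs$ref_start)
  if (pos %in% c(0, ends)) return(segs)
  k <- which(starts < pos & ends > pos)[1]
  off <- pos - starts[k]
  seg <- segs[k, ]
  if (seg$strand == "+") {
    left <- mutate(seg, ref_end = seg$ref_start + off)
    right <- mutate(seg, ref_start = seg$ref_start + off)
  } else {
    left <- mutate(seg, ref_start = seg$ref_end - off)
    right <- mutate(seg, ref_end = seg$ref_end - off)
  }
  bind_rows(segs[seq_len(k - 1), ], left, right,
            segs[setdiff(seq_len(nrow(segs)), seq_len(k)), ])
}

seg_indices_between <- function(segs, s, e) {
  ends <- seg_sample_ends(segs)
  starts <- ends - (segs$ref_end - segs$ref_start)
  which(starts >= s & ends <= e)
}

invert_segments <- function(segs, s, e) {
  segs <- split_segs_at(split_segs_at(segs, s), e)
  idx <- seg_indices_between(segs, s, e)
  mid <- segs[rev(idx), ] |>
    mutate(strand = ifelse(.data$strand == "+", "-", "+"))
  bind_rows(segs[seq_len(min(idx) - 1), ], mid,
            segs[setdiff(seq_len(nrow(segs)), seq_len(max(idx))), ])
}

translocate_segments <- function(segs, s, e, insert_at) {
  segs <- split_segs_at(split_segs_at(segs, s), e)
  idx <- seg_indices_between(segs, s, e)
  moved <- segs[idx, ]
  rest <- segs[-idx, ]
  # insertion point in post-excision coordinates
  p <- if (insert_at >= e) insert_at - (e - s) else insert_at
  rest <- split_segs_at(rest, p)
  ends <- seg_sample_ends(rest)
  k <- sum(ends <= p)
  bind_rows(rest[seq_len(k), ], moved,
            rest[setdiff(seq_len(nrow(rest)), seq_len(k)), ])
}

# sample-coordinate positions of internal segment boundaries (prior events)
internal_boundaries <- function(segs) head(seg_sample_ends(segs), -1)

# pick a position at least `margin` from the ends, from `avoid` intervals and
# from existing boundaries
pick_position <- function(len, size, segs, margin, avoid = NULL, tries = 200) {
  lo <- margin
  hi <- len - margin - size
  if (hi < lo) return(NULL)
  bounds <- internal_boundaries(segs)
  for (t in seq_len(tries)) {
    s <- floor(runif(1, lo, hi + 1))
    ok <- !any(bounds > s - margin & bounds < s + size + margin)
    if (ok && !is.null(avoid)) {
      ok <- !any(avoid$start < s + size + margin & avoid$end > s - margin)
    }
    if (ok) return(s)
  }
  NULL
}

#' Plant large-scale rearrangements into a genome
#'
#' Derives a sample genome from a reference by planting inversions
#' (reverse-complement in place), intra-chromosomal translocations (excise and
#' reinsert elsewhere on the same chromosome), and fusions (join two
#' chromosomes end-to-end) or fissions (split one). Event locations are drawn
#' uniformly at least `margin` bases from chromosome ends and from previously
#' planted events. The returned truth object records every event and the full
#' sample-to-reference segment maps.
#'
#' @param genome Reference sequence table from [simulate_reference()].
#' @param events Tibble (or data frame) with columns `kind` (one of
#'   `inversion`, `intra_translocation`, `fusion`, `fission`) and `size`
#'   (bases; ignored for fusion).
#' @param seed Integer seed.
#' @param margin Minimum distance of an event from chromosome ends and other
#'   events (default 1000000).
#' @return List with `genome` (sample sequence table) and `truth` (a
#'   `synthetic_truth` object: `events`, per-chromosome `segments`, `seed`).
#' @export
plant_rearrangements <- function(genome, events, seed = 1, margin = 1000000) {
  set.seed(seed)
  events <- as_tibble(events)
  segs <- identity_segments(genome)
  lens <- setNames(genome$length, genome$id)
  planted <- list()
  # structural (size-carrying) events first, chromosome-count events last so
  # that fusing never invalidates pending event locations
  ord <- order(match(events$kind, c("inversion", "intra_translocation",
                                    "fission", "fusion")))
  for (ev in seq_len(nrow(events))) {
    kind <- events$kind[ord][ev]
    size <- events$size[ord][ev]
    if (kind %in% c("inversion", "intra_translocation")) {
      eligible <- names(lens)[lens >= size + 2 * margin +
                                (kind == "intra_translocation") * 2 * margin]
      if (length(eligible) == 0) {
        abort(sprintf("no chromosome can host a %s of %d bases", kind, size))
      }
      placed <- FALSE
      for (chrom in sample(eligible)) {
        s <- pick_position(lens[[chrom]], size, segs[[chrom]], margin)
        if (is.null(s)) next
        if (kind == "inversion") {
          segs[[chrom]] <- invert_segments(segs[[chrom]], s, s + size)
          planted[[length(planted) + 1]] <- tibble(
            kind = kind, chrom = chrom, start = s, end = s + size, size = size)
          placed <- TRUE
          break
        }
        p <- pick_position(lens[[chrom]], 0, segs[[chrom]], margin,
                           avoid = tibble(start = s - margin,
                                          end = s + size + margin))
        if (is.null(p)) next
        segs[[chrom]] <- translocate_segments(segs[[chrom]], s, s + size, p)
        planted[[length(planted) + 1]] <- tibble(
          kind = kind, chrom = chrom, start = s, end = s + size, size = size)
        placed <- TRUE
        break
      }
      if (!placed) abort(sprintf("could not place %s of %d bases", kind, size))
    } else if (kind == "fusion") {
      if (length(lens) < 2) abort("fusion needs at least 2 chromosomes")
      pair <- sample(names(lens), 2)
      new_id <- paste(pair, collapse = "-")
      segs[[new_id]] <- bind_rows(segs[[pair[1]]], segs[[pair[2]]])
      new_len <- sum(lens[pair])
      planted[[length(planted) + 1]] <- tibble(
        kind = kind, chrom = new_id, start = lens[[pair[1]]],
        end = lens[[pair[1]]], size = NA_real_)
      segs[pair] <- NULL
      lens <- lens[setdiff(names(lens), pair)]
      lens[[new_id]] <- new_len
    } else if (kind == "fission") {
      eligible <- names(lens)[lens >= 2 * margin]
      if (length(eligible) == 0) abort("no chromosome long enough for fission")
      chrom <- sample(eligible, 1)
      at <- pick_position(lens[[chrom]], 0, segs[[chrom]], margin)
      if (is.null(at)) abort("could not place fission")
      cut <- split_segs_at(segs[[chrom]], at)
      ends <- seg_sample_ends(cut)
      k <- sum(ends <= at)
      ids <- paste0(chrom, c(".a", ".b"))
      segs[[ids[1]]] <- cut[seq_len(k), ]
      segs[[ids[2]]] <- cut[setdiff(seq_len(nrow(cut)), seq_len(k)), ]
      planted[[length(planted) + 1]] <- tibble(
        kind = kind, chrom = chrom, start = at, end = at, size = NA_real_)
      segs[[chrom]] <- NULL
      lens <- lens[setdiff(names(lens), chrom)]
      lens[ids] <- c(at, sum(cut$ref_end - cut$ref_start) - at)
    } else {
      abort(paste0("unknown event kind: ", kind))
    }
  }
  sample_genome <- materialize_segments(segs, genome)
  truth <- structure(
    list(events = bind_rows(planted) %||% tibble(),
         segments = segs, ref_lengths = setNames(genome$length, genome$id),
         seed = seed),
    class = "synthetic_truth")
  list(genome = sample_genome, truth = truth)
}

materialize_segments <- function(segs, reference) {
  ref <- setNames(reference$seq, reference$id)
  seqs <- map_chr(segs, function(sg) {
    parts <- pmap(sg, function(ref_name, ref_start, ref_end, strand) {
      s <- substr(ref[[ref_name]], ref_start + 1, ref_end)
      if (strand == "-") revcomp(s) else s
    })
    paste0(unlist(parts), collapse = "")
  })
  seq_records(names(segs), unname(seqs), normalize = FALSE)
}

#' Fragment a genome into contigs with recorded provenance
#'
#' Cuts each chromosome into contigs that tile it exactly, assigns random
#' orientations, and shuffles contig ids, emulating a curated contig set of a
#' known genome. Fragment lengths are drawn from an exponential distribution
#' calibrated so the achieved N50 is close to `target_n50` (the N50 of
#' exponential fragments is about 1.68 times their mean); fragments shorter
#' than `min_len` are merged into their neighbour.
#'
#' @param genome Sequence table to fragment.
#' @param target_n50 Target contig N50 in bases (ignored when `breakpoints`
#'   are given).
#' @param breakpoints Optional named list of explicit cut positions (0-based)
#'   per chromosome.
#' @param min_len Minimum contig length (default 1000).
#' @param seed Integer seed.
#' @return List with `contigs` (sequence table, shuffled ids `ctg_...`) and
#'   `provenance` (tibble `contig_id`, `chrom`, `start`, `end`, `strand`;
#'   intervals tile each chromosome exactly).
#' @export
fragment_into_contigs <- function(genome, target_n50 = NULL,
                                  breakpoints = NULL, min_len = 1000,
                                  seed = 1) {
  set.seed(seed)
  if (min_len > min(genome$length)) {
    abort("min_len exceeds the shortest chromosome")
  }
  frags <- map2(genome$id, genome$length, function(chrom, len) {
    cuts <- if (!is.null(breakpoints)) {
      sort(unique(breakpoints[[chrom]]))
    } else {
      mean_len <- target_n50 / 1.678
      n_draw <- ceiling(len / mean_len) * 3 + 10
      lens <- ceiling(stats::rexp(n_draw, rate = 1 / mean_len))
      ends <- cumsum(lens)
      ends[ends < len]
    }
    cuts <- cuts[cuts > 0 & cuts < len]
    edges <- unique(c(0, cuts, len))
    # merge short fragments into their left neighbour
    repeat {
      w <- diff(edges)
      short <- which(w < min_len)
      if (length(short) == 0) break
      drop <- if (short[1] == 1) 2 else short[1]
      edges <- edges[-drop]
    }
    tibble(chrom = chrom, start = head(edges, -1), end = edges[-1])
  })
  prov <- bind_rows(frags)
  prov$strand <- sample(c("+", "-"), nrow(prov), replace = TRUE)
  prov <- prov[sample.int(nrow(prov)), ]
  prov$contig_id <- sprintf("ctg_%05d", seq_len(nrow(prov)))
  ref <- setNames(genome$seq, genome$id)
  seqs <- pmap(prov, function(chrom, start, end, strand, contig_id) {
    s <- substr(ref[[chrom]], start + 1, end)
    if (strand == "-") revcomp(s) else s
  })
  contigs <- seq_records(prov$contig_id, unlist(seqs), normalize = FALSE)
  list(contigs = contigs,
       provenance = select(prov, "contig_id", "chrom", "start", "end",
                           "strand"))
}

#' Simulate noisy long reads with recorded provenance
#'
#' Read starts are Poisson-distributed along each chromosome at the requested
#' coverage; lengths are normal (truncated at 50 bases and the chromosome
#' end); about half the reads are reverse-complemented; substitution,
#' insertion and deletion errors are applied independently per base. The
#' error model is deliberately simple (no homopolymer structure): it is meant
#' to exercise mapping and threshold logic, not to emulate an instrument.
#'
#' @param genome Sequence table to sample reads from.
#' @param coverage Mean fold-coverage (> 0).
#' @param mean_length,length_sd Read length distribution in bases.
#' @param sub_rate,ins_rate,del_rate Per-base error rates, each in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return List with `reads` (sequence table) and `provenance` (tibble
#'   `read_id`, `chrom`, `start`, `end`, `strand`, `n_errors`).
#' @export
simulate_reads <- function(genome, coverage, mean_length = 10000,
                           length_sd = 2000, sub_rate = 0, ins_rate = 0,
                           del_rate = 0, seed = 1) {
  stopifnot(coverage > 0)
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) abort("error rates must lie in [0, 0.2]")
  set.seed(seed)
  per_chrom <- map2(genome$id, genome$length, function(chrom, len) {
    n <- rpois(1, coverage * len / mean_length)
    if (n == 0) return(NULL)
    start <- floor(runif(n, 0, len))
    rl <- pmax(50, round(rnorm(n, mean_length, length_sd)))
    end <- pmin(len, start + rl)
    keep <- end - start >= 50
    tibble(chrom = chrom, start = start[keep], end = end[keep],
           strand = sample(c("+", "-"), sum(keep), replace = TRUE))
  })
  prov <- bind_rows(per_chrom)
  if (nrow(prov) == 0) abort("no reads simulated; increase coverage")
  prov$read_id <- sprintf("read_%06d", seq_len(nrow(prov)))
  ref <- setNames(genome$seq, genome$id)
  out <- pmap(prov, function(chrom, start, end, strand, read_id) {
    s <- substr(ref[[chrom]], start + 1, end)
    if (strand == "-") s <- revcomp(s)
    mutate_sequence(s, sub_rate, ins_rate, del_rate)
  })
  prov$n_errors <- map_int(out, "n_errors")
  reads <- seq_records(prov$read_id, map_chr(out, "seq"), normalize = FALSE)
  list(reads = reads,
       provenance = select(prov, "read_id", "chrom", "start", "end",
                           "strand", "n_errors"))
}

# i.i.d. per-base substitutions, insertions and deletions
mutate_sequence <- function(s, sub_rate, ins_rate, del_rate) {
  if (sub_rate + ins_rate + del_rate == 0) {
    return(list(seq = s, n_errors = 0L))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  sub_at <- which(runif(n) < sub_rate)
  if (length(sub_at)) {
    repl <- map_chr(chars[sub_at], function(b) sample(setdiff(bases, b), 1))
    chars[sub_at] <- repl
  }
  del_at <- which(runif(n) < del_rate)
  ins_at <- which(runif(n) < ins_rate)
  out <- chars
  if (length(ins_at)) {
    ins_base <- sample(bases, length(ins_at), replace = TRUE)
    pieces <- character(n)
    pieces[] <- out
    pieces[ins_at] <- paste0(pieces[ins_at], ins_base)
    out <- pieces
  }
  if (length(del_at)) out[del_at] <- sub("^.", "", out[del_at])
  list(seq = paste0(out, collapse = ""),
       n_errors = length(sub_at) + length(del_at) + length(ins_at))
}

#' Exact read-to-contig alignments from recorded provenance
#'
#' Projects read origin intervals (on the sample genome) onto the contig
#' tiling of the same genome, yielding the read-to-assembly PAF that an
#' aligner would produce for error-free reads: one record per read/contig
#' overlap, with strands composed from read and contig orientation and
#' mapq 60. Intended for error-free reads (with read errors the coordinates
#' are only approximate and records are clamped to the read length).
#'
#' @param read_provenance Read provenance from [simulate_reads()].
#' @param contig_provenance Contig provenance from [fragment_into_contigs()]
#'   on the same genome.
#' @param read_lengths,contig_lengths Named length vectors.
#' @return PAF tibble (reads as query, contigs as target).
#' @export
reads_to_contigs_truth <- function(read_provenance, contig_provenance,
                                   read_lengths, contig_lengths) {
  ordered <- arrange(contig_provenance, .data$chrom, .data$start)
  segs <- lapply(split(ordered, ordered$chrom), function(p) {
    tibble(ref_name = p$contig_id, ref_start = 0,
           ref_end = p$end - p$start, strand = p$strand)
  })
  fake_truth <- structure(list(segments = segs, ref_lengths = contig_lengths),
                          class = "synthetic_truth")
  paf <- truth_alignments(rename(read_provenance, contig_id = "read_id"),
                          fake_truth, read_lengths)
  # with read errors the origin interval can exceed the actual read length
  paf$query_end <- pmin(paf$query_end, paf$query_length)
  paf <- paf[paf$query_start < paf$query_end, ]
  paf$matches <- pmin(paf$matches, paf$query_end - paf$query_start)
  paf$block_length <- pmax(paf$block_length, paf$matches)
  validate_paf(paf)
}

#' Exact contig-to-reference alignments from recorded provenance
#'
#' Composes each contig's provenance interval on the sample genome with the
#' sample-to-reference segment maps of the planted rearrangements, emitting
#' one PAF record per maximal collinear segment (mapq 60, matches equal to
#' the segment length). A contig spanning a planted breakpoint therefore
#' yields several records, with opposite strands across an inversion
#' boundary. This replaces an external aligner in tests and desk-scale runs;
#' real aligner PAF can be substituted anywhere a PAF tibble is accepted.
#'
#' @param provenance Contig provenance from [fragment_into_contigs()].
#' @param truth A `synthetic_truth` from [plant_rearrangements()], or `NULL`
#'   when the sample genome is the reference itself (identity maps).
#' @param contig_lengths Named vector of contig lengths.
#' @param ref_lengths Named vector of reference chromosome lengths (defaults
#'   to the truth's recorded lengths).
#' @return PAF tibble sorted by contig and query start.
#' @export
truth_alignments <- function(provenance, truth = NULL, contig_lengths,
                             ref_lengths = NULL) {
  if (is.null(truth)) {
    segs <- setNames(map2(names(ref_lengths), ref_lengths, function(id, len) {
      tibble(ref_name = id, ref_start = 0, ref_end = len, strand = "+")
    }), names(ref_lengths))
  } else {
    segs <- truth$segments
    ref_lengths <- ref_lengths %||% truth$ref_lengths
  }
  unknown <- setdiff(unique(provenance$chrom), names(segs))
  if (length(unknown)) {
    abort(paste0("provenance on unknown chromosome: ",
                 paste(unknown, collapse = ", ")))
  }
  recs <- pmap(provenance, function(contig_id, chrom, start, end, strand, ...) {
    sg <- segs[[chrom]]
    ends <- seg_sample_ends(sg)
    starts <- ends - (sg$ref_end - sg$ref_start)
    hit <- which(starts < end & ends > start)
    pieces <- map(hit, function(k) {
      i0 <- max(starts[k], start)
      i1 <- min(ends[k], end)
      if (sg$strand[k] == "+") {
        t0 <- sg$ref_start[k] + (i0 - starts[k])
        t1 <- sg$ref_start[k] + (i1 - starts[k])
      } else {
        t0 <- sg$ref_end[k] - (i1 - starts[k])
        t1 <- sg$ref_end[k] - (i0 - starts[k])
      }
      if (strand == "+") {
        q0 <- i0 - start; q1 <- i1 - start
      } else {
        q0 <- end - i1; q1 <- end - i0
      }
      tibble(query_name = contig_id,
             query_length = contig_lengths[[contig_id]],
             query_start = q0, query_end = q1,
             strand = if (sg$strand[k] == strand) "+" else "-",
             target_name = sg$ref_name[k],
             target_length = ref_lengths[[sg$ref_name[k]]],
             target_start = t0, target_end = t1,
             matches = i1 - i0, block_length = i1 - i0, mapq = 60,
             tags = NA_character_)
    })
    bind_rows(pieces)
  })
  paf <- bind_rows(recs) |> arrange(.data$query_name, .data$query_start)
  if (nrow(paf) == 0) return(empty_paf())
  # merge perfectly contiguous same-strand neighbours (collinear pieces)
  validate_paf(chain_records(paf, max_gap = 0) |>
                 select(-"n_members", -"weight") |>
                 mutate(tags = NA_character_))
}
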