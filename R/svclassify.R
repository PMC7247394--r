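#' Classify and count large-scale rearrangements
#'
#' Counts three classes of large-scale (default >300 kb) discrepancy between
#' an assembly and a reference from chained, MQ-filtered whole-genome
#' alignments:
#' \describe{
#'   \item{fusion_fission (f)}{a junction joining segments from two different
#'     reference chromosomes in one query scaffold;}
#'   \item{intra_translocation (t)}{a same-chromosome segment displaced out of
#'     collinear order — operationally, a chain excluded from the
#'     weight-maximal monotone subsequence of reference starts on the query's
#'     dominant chromosome and strand;}
#'   \item{inversion (i)}{a maximal run of chains on the dominant chromosome
#'     aligned opposite to the dominant strand, with query span at least
#'     `min_event_size`.}
#' }
#' A whole-scaffold reverse complement is not an inversion: the dominant
#' strand itself defines the expected orientation. Chains with query span
#' below `min_event_size` are ignored entirely. A displaced and inverted
#' segment is counted independently in both classes.
#'
#' @param chains Chain tibble from [chain_alignments()].
#' @param min_event_size Minimum query span of a countable event in bases
#'   (default 300000).
#' @return An `sv_calls` object: list with `events` (tibble `kind`,
#'   `query_name`, `query_start`, `query_end`, `ref_names`, `size`) and
#'   `counts` (one-row tibble `f`, `t`, `i`). Use [tidy()] / [glance()] to
#'   extract them.
#' @export
classify_events <- function(chains, min_event_size = 300000) {
  events <- list()
  add <- function(kind, q, qs, qe, refs) {
    events[[length(events) + 1]] <<- tibble(
      kind = kind, query_name = q, query_start = qs, query_end = qe,
      ref_names = paste(refs, collapse = ","), size = qe - qs)
  }
  retained <- chains |>
    filter(.data$query_end - .data$query_start >= min_event_size) |>
    arrange(.data$query_name, .data$query_start)
  for (q in unique(retained$query_name)) {
    ch <- retained[retained$query_name == q, ]
    n <- nrow(ch)
    # (1) fusion/fission: adjacent chains on different chromosomes
    if (n > 1) {
      for (k in 1:(n - 1)) {
        if (ch$target_name[k] != ch$target_name[k + 1]) {
          add("fusion_fission", q, ch$query_start[k], ch$query_end[k + 1],
              c(ch$target_name[k], ch$target_name[k + 1]))
        }
      }
    }
    # (2)-(4) per chromosome hit by this query (a fused scaffold spans two):
    # dominant strand by weight majority within the chromosome's chains
    for (chrom in unique(ch$target_name)) {
      on_dom <- ch[ch$target_name == chrom, ]
      w_plus <- sum(on_dom$weight[on_dom$strand == "+"])
      w_minus <- sum(on_dom$weight[on_dom$strand == "-"])
      dom_strand <- if (w_minus > w_plus) "-" else "+"
      # (3) inversions: maximal opposite-strand runs, long enough in query
      # span; a wholly reverse-complemented block is not an inversion since
      # the dominant strand defines the expected orientation
      opp <- on_dom$strand != dom_strand
      if (any(opp)) {
        runs <- rle(opp)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        for (r in which(runs$values)) {
          qs <- on_dom$query_start[starts[r]]
          qe <- on_dom$query_end[ends[r]]
          if (qe - qs >= min_event_size) {
            add("inversion", q, qs, qe, chrom)
          }
        }
      }
      # (4) intra-chromosomal translocations: dominant-strand chains excluded
      # from the weight-maximal monotone subsequence of ref starts
      fw <- on_dom[on_dom$strand == dom_strand, ]
      if (nrow(fw) > 1) {
        key <- if (dom_strand == "+") fw$target_start else -fw$target_start
        keep <- max_weight_monotone(key, fw$weight)
        for (k in which(!keep)) {
          add("intra_translocation", q, fw$query_start[k], fw$query_end[k],
              chrom)
        }
      }
    }
  }
  events <- bind_rows(events)
  if (nrow(events) == 0) {
    events <- tibble(kind = character(), query_name = character(),
                     query_start = numeric(), query_end = numeric(),
                     ref_names = character(), size = numeric())
  }
  structure(
    list(events = events,
         counts = tibble(f = sum(events$kind == "fusion_fission"),
                         t = sum(events$kind == "intra_translocation"),
                         i = sum(events$kind == "inversion")),
         min_event_size = min_event_size),
    class = "sv_calls")
}

# indices kept in the weight-maximal non-decreasing subsequence (O(n^2) DP)
max_weight_monotone <- function(key, weight) {
  n <- length(key)
  best <- weight
  prev <- rep(NA_integer_, n)
  if (n > 1) {
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (key[j] <= key[i] && best[j] + weight[i] > best[i]) {
          best[i] <- best[j] + weight[i]
          prev[i] <- j
        }
      }
    }
  }
  keep <- logical(n)
  at <- which.max(best)
  while (!is.na(at)) {
    keep[at] <- TRUE
    at <- prev[at]
  }
  keep
}

#' @export
print.sv_calls <- function(x, ...) {
  cat(sprintf("<sv_calls> f:%d t:%d i:%d (min event size %s bp)\n",
              x$counts$f, x$counts$t, x$counts$i,
              format(x$min_event_size, big.mark = ",")))
  invisible(x)
}

#' @rdname classify_events
#' @param x An `sv_calls` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-event tibble.
#' @export
tidy.sv_calls <- function(x, ...) x$events

#' @rdname classify_events
#' @return `glance()` returns the one-row `f`/`t`/`i` count tibble.
#' @export
glance.sv_calls <- function(x, ...) {
  mutate(x$counts, min_event_size = x$min_event_size,
         n_events = nrow(x$events))
}

#' Lift contig alignments into scaffold coordinates
#'
#' Rewrites a contig-to-reference PAF so the query is the scaffold each
#' contig belongs to, using the scaffold plan's component offsets and
#' orientations (`-` components flip both coordinates and strand). This
#' yields the scaffold-to-reference alignment set that re-mapping the
#' scaffold FASTA would produce, without running an aligner; records for
#' contigs absent from the plan's scaffolds are dropped.
#'
#' @param paf Contig-to-reference PAF tibble.
#' @param plan A [scaffold_plan()] whose W components are the PAF's queries.
#' @return PAF tibble with scaffolds as query, sorted by query and start.
#' @export
project_paf_to_scaffolds <- function(paf, plan) {
  td <- tidy(plan) |> filter(.data$type == "W")
  scaf_len <- tidy(plan) |>
    group_by(.data$scaffold_id) |>
    summarise(scaf_len = max(.data$scaffold_end))
  comp <- td |>
    left_join(scaf_len, by = "scaffold_id") |>
    select(query_name = "component_id", "scaffold_id", comp_offset = "scaffold_start",
           comp_len = "length", comp_ori = "orientation", "scaf_len")
  out <- paf |>
    dplyr::inner_join(comp, by = "query_name") |>
    mutate(
      qs = ifelse(.data$comp_ori == "+",
                  .data$comp_offset + .data$query_start,
                  .data$comp_offset + .data$comp_len - .data$query_end),
      qe = ifelse(.data$comp_ori == "+",
                  .data$comp_offset + .data$query_end,
                  .data$comp_offset + .data$comp_len - .data$query_start),
      strand = ifelse(.data$comp_ori == "+", .data$strand,
                      ifelse(.data$strand == "+", "-", "+")),
      query_name = .data$scaffold_id,
      query_length = .data$scaf_len,
      query_start = .data$qs, query_end = .data$qe) |>
    select(dplyr::all_of(names(empty_paf()))) |>
    arrange(.data$query_name, .data$query_start)
  validate_paf(out)
}

#' Scaffold plan implied by contig provenance
#'
#' Builds the plan of a perfect assembly: one scaffold per source chromosome,
#' with the contigs in their true order and orientation and no gaps. Useful
#' for turning truth alignments of fragments into chromosome-scale alignment
#' sets (see [project_paf_to_scaffolds()]).
#'
#' @param provenance Contig provenance from [fragment_into_contigs()].
#' @param prefix Scaffold name prefix (default `"scf_"`).
#' @return A [scaffold_plan()] without gap rows.
#' @export
plan_from_provenance <- function(provenance, prefix = "scf_") {
  comp <- provenance |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(part_number = row_number()) |>
    ungroup() |>
    mutate(scaffold_id = paste0(prefix, .data$chrom), type = "W",
           component_id = .data$contig_id, orientation = .data$strand,
           length = .data$end - .data$start) |>
    select("scaffold_id", "part_number", "type", "component_id",
           "orientation", "length")
  scaffold_plan(comp)
}

#' Dot-plot segment table from chained alignments
#'
#' Lays all reference chromosomes and all query scaffolds end-to-end (each in
#' lexicographically sorted name order) and emits one segment per chain in
#' the resulting cumulative coordinates — the data behind a whole-genome
#' alignment dot plot.
#'
#' @param chains Chain tibble from [chain_alignments()].
#' @param ref_lengths Named vector of reference chromosome lengths.
#' @param query_lengths Named vector of query scaffold lengths.
#' @return Tibble with one row per chain: raw and offset coordinates
#'   (`ref_x0`, `ref_x1`, `query_y0`, `query_y1`) and `strand`; for `-`
#'   strand chains the reference interval is drawn descending.
#' @export
dotplot_data <- function(chains, ref_lengths, query_lengths) {
  unknown <- setdiff(unique(chains$target_name), names(ref_lengths))
  if (length(unknown)) {
    abort(paste0("chain on unknown reference: ", paste(unknown, collapse = ", ")))
  }
  unknown <- setdiff(unique(chains$query_name), names(query_lengths))
  if (length(unknown)) {
    abort(paste0("chain on unknown query: ", paste(unknown, collapse = ", ")))
  }
  roff <- cumsum(c(0, as.numeric(ref_lengths[sort(names(ref_lengths))])))
  roff <- setNames(head(roff, -1), sort(names(ref_lengths)))
  qoff <- cumsum(c(0, as.numeric(query_lengths[sort(names(query_lengths))])))
  qoff <- setNames(head(qoff, -1), sort(names(query_lengths)))
  chains |>
    mutate(
      ref_offset = unname(roff[.data$target_name]),
      query_offset = unname(qoff[.data$query_name]),
      ref_x0 = .data$ref_offset +
        ifelse(.data$strand == "+", .data$target_start, .data$target_end),
      ref_x1 = .data$ref_offset +
        ifelse(.data$strand == "+", .data$target_end, .data$target_start),
      query_y0 = .data$query_offset + .data$query_start,
      query_y1 = .data$query_offset + .data$query_end) |>
    select(ref_name = "target_name", "query_name", "strand",
           ref_start = "target_start", ref_end = "target_end",
           "query_start", "query_end", "ref_x0", "ref_x1",
           "query_y0", "query_y1")
}
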