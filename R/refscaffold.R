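#' Build anchor blocks from contig-to-reference alignments
#'
#' Anchor blocks are merged collinear alignment evidence tying a contig
#' interval to a reference interval on one strand — the raw material for
#' reference-guided placement. Alignments below `min_mapq` are discarded;
#' surviving records on the same (contig, chromosome, strand) are chained
#' when collinear with query and target gaps at most `max_chain_gap`; blocks
#' whose merged contig span is below `min_block` are dropped (these are
#' typically spurious repeat anchors).
#'
#' @param alignments PAF tibble, contigs as query, reference as target.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param min_block Minimum merged contig span in bases (default 5000).
#' @param max_chain_gap Maximum chaining gap in bases (default 100000).
#' @return Block tibble: `contig_id`, `contig_length`, `contig_start`,
#'   `contig_end`, `ref_name`, `ref_length`, `ref_start`, `ref_end`, `strand`,
#'   `n_members`, `weight` (summed matching bases).
#' @export
build_anchor_blocks <- function(alignments, min_mapq = 30, min_block = 5000,
                                max_chain_gap = 100000) {
  chained <- chain_records(filter_mq(alignments, min_mapq), max_chain_gap)
  chained |>
    filter(.data$query_end - .data$query_start >= min_block) |>
    select(contig_id = "query_name", contig_length = "query_length",
           contig_start = "query_start", contig_end = "query_end",
           ref_name = "target_name", ref_length = "target_length",
           ref_start = "target_start", ref_end = "target_end",
           "strand", "n_members", "weight")
}

# weighted median: smallest value v with cumulative weight >= half the total
weighted_median <- function(values, weights) {
  o <- order(values)
  values <- values[o]; weights <- weights[o]
  values[which(cumsum(weights) >= sum(weights) / 2)[1]]
}

#' Place contigs on reference chromosomes
#'
#' Each contig is assigned to the chromosome carrying the majority of its
#' anchor weight (ties broken to the lexicographically smallest name), with
#' orientation from the weight majority of anchor strands on that chromosome
#' (tie: `+`) and an ordering key equal to the weight-weighted median of its
#' anchor midpoints. `ambiguity` is the runner-up chromosome's weight divided
#' by the chosen chromosome's weight (0 when only one chromosome is hit).
#'
#' @param blocks Anchor-block tibble from [build_anchor_blocks()].
#' @return Placement tibble: `contig_id`, `ref_name`, `position_key`,
#'   `orientation`, `support`, `ambiguity`. Contigs without blocks are absent
#'   (they become unplaced downstream).
#' @export
place_contigs <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(contig_id = character(), ref_name = character(),
                  position_key = numeric(), orientation = character(),
                  support = numeric(), ambiguity = numeric()))
  }
  blocks |>
    group_by(.data$contig_id) |>
    group_split() |>
    map(function(b) {
      per_chrom <- b |>
        group_by(.data$ref_name) |>
        summarise(w = sum(.data$weight)) |>
        arrange(desc(.data$w), .data$ref_name)
      chosen <- per_chrom$ref_name[1]
      on_chosen <- b[b$ref_name == chosen, ]
      w_plus <- sum(on_chosen$weight[on_chosen$strand == "+"])
      w_minus <- sum(on_chosen$weight[on_chosen$strand == "-"])
      tibble(
        contig_id = b$contig_id[1],
        ref_name = chosen,
        position_key = weighted_median(
          (on_chosen$ref_start + on_chosen$ref_end) / 2, on_chosen$weight),
        orientation = if (w_minus > w_plus) "-" else "+",
        support = per_chrom$w[1],
        ambiguity = if (nrow(per_chrom) > 1) per_chrom$w[2] / per_chrom$w[1] else 0)
    }) |>
    bind_rows() |>
    arrange(.data$ref_name, .data$position_key, .data$contig_id)
}

#' Order placed contigs into chromosome scaffolds with estimated gaps
#'
#' Builds one scaffold per reference chromosome holding at least one placed
#' contig. Contigs are sorted by `position_key` (ties: longer contig first,
#' then lexicographic id). The gap between neighbours is estimated from the
#' reference distance between their facing anchors, reduced by the unaligned
#' contig tails projected into the gap, and floored at `min_gap`.
#'
#' @param placements Placement tibble from [place_contigs()].
#' @param blocks Anchor-block tibble (used for facing-anchor coordinates).
#' @param contig_lengths Named vector of all contig lengths (placed and not).
#' @param min_gap Minimum estimated gap in bases (default 100).
#' @param prefix Scaffold name prefix; scaffolds are named
#'   `<prefix><chromosome>` (default `"scf_"`).
#' @return A [scaffold_plan()]; contigs without placements are unplaced.
#' @export
order_and_gap <- function(placements, blocks, contig_lengths, min_gap = 100,
                          prefix = "scf_") {
  lens <- contig_lengths
  # per (contig, chosen chromosome) anchor extremes and unaligned tails
  extremes <- placements |>
    left_join(blocks, by = c("contig_id", "ref_name")) |>
    group_by(.data$contig_id, .data$ref_name, .data$orientation) |>
    summarise(ref_min = min(.data$ref_start), ref_max = max(.data$ref_end),
              ctg_min = min(.data$contig_start), ctg_max = max(.data$contig_end),
              .groups = "drop") |>
    mutate(ctg_len = unname(lens[.data$contig_id]),
           left_head = ifelse(.data$orientation == "+", .data$ctg_min,
                              .data$ctg_len - .data$ctg_max),
           right_tail = ifelse(.data$orientation == "+",
                               .data$ctg_len - .data$ctg_max, .data$ctg_min))
  ordered <- placements |>
    mutate(ctg_len = unname(lens[.data$contig_id])) |>
    arrange(.data$ref_name, .data$position_key, desc(.data$ctg_len),
            .data$contig_id) |>
    left_join(select(extremes, "contig_id", "ref_min", "ref_max",
                     "left_head", "right_tail"), by = "contig_id")
  rows <- ordered |>
    group_by(.data$ref_name) |>
    group_split() |>
    map(function(g) {
      n <- nrow(g)
      comp <- tibble(scaffold_id = paste0(prefix, g$ref_name[1]),
                     type = "W", component_id = g$contig_id,
                     orientation = g$orientation, length = g$ctg_len)
      if (n == 1) return(mutate(comp, part_number = 1L))
      gaps <- pmax(min_gap,
                   g$ref_min[-1] - g$ref_max[-n] -
                     g$right_tail[-n] - g$left_head[-1])
      gap_rows <- tibble(scaffold_id = comp$scaffold_id[1], type = "N",
                         component_id = NA_character_,
                         orientation = NA_character_, length = gaps)
      interleaved <- vector("list", 2 * n - 1)
      interleaved[seq(1, 2 * n - 1, by = 2)] <- split(comp, seq_len(n))
      interleaved[seq(2, 2 * n - 2, by = 2)] <- split(gap_rows, seq_len(n - 1))
      bind_rows(interleaved) |> mutate(part_number = row_number())
    })
  components <- bind_rows(rows) |>
    select("scaffold_id", "part_number", "type", "component_id",
           "orientation", "length")
  scaffold_plan(components,
                unplaced = setdiff(names(contig_lengths),
                                   placements$contig_id))
}

#' Detect conflicts between improved contigs and a prior scaffold plan
#'
#' After local reassembly, improved contigs are aligned back to the prior
#' scaffolds; a contig whose alignment jumps between scaffolds, or by more
#' than `max_jump` within one scaffold, carries a likely misassembly and is
#' split at the junction. Both sides of a reported junction must be supported
#' by at least `min_side` aligned query bases.
#'
#' @param alignments PAF tibble, improved contigs as query, prior scaffolds as
#'   target.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param max_jump Maximum tolerated within-scaffold target jump in bases
#'   (default 1000000).
#' @param min_side Minimum aligned query bases on each side of a junction
#'   (default 50000).
#' @return Split tibble (`contig_id`, `position`, `reason = "scaffold_conflict"`).
#' @export
detect_scaffold_conflicts <- function(alignments, min_mapq = 30,
                                      max_jump = 1000000, min_side = 50000) {
  aln <- filter_mq(alignments, min_mapq)
  per_contig <- aln |>
    group_by(.data$query_name) |>
    group_split() |>
    map(function(a) {
      a <- arrange(a, .data$query_start)
      n <- nrow(a)
      if (n < 2) return(NULL)
      aligned <- a$query_end - a$query_start
      left_cum <- cumsum(aligned)
      right_cum <- rev(cumsum(rev(aligned)))
      pos <- numeric(0)
      for (i in 1:(n - 1)) {
        jump <- max(a$target_start[i + 1] - a$target_end[i],
                    a$target_start[i] - a$target_end[i + 1], 0)
        conflict <- a$target_name[i + 1] != a$target_name[i] || jump > max_jump
        supported <- left_cum[i] >= min_side && right_cum[i + 1] >= min_side
        if (conflict && supported) {
          pos <- c(pos, floor((a$query_end[i] + a$query_start[i + 1]) / 2))
        }
      }
      if (length(pos) == 0) return(NULL)
      tibble(contig_id = a$query_name[1], position = pos,
             reason = "scaffold_conflict")
    })
  out <- bind_rows(per_contig)
  if (nrow(out) == 0) {
    out <- tibble(contig_id = character(), position = numeric(),
                  reason = character())
  }
  out
}

#' Materialize a scaffold plan into sequences
#'
#' Concatenates oriented component sequences (`-` components are
#' reverse-complemented) separated by `N` runs of the planned gap lengths.
#' Unplaced contigs are emitted unchanged under their own ids. Total non-`N`
#' bases are conserved.
#'
#' @param plan A [scaffold_plan()].
#' @param contigs Sequence table containing every plan component.
#' @param gap_char Gap fill character (default `"N"`).
#' @return Sequence table of scaffolds followed by unplaced contigs.
#' @export
plan_to_sequences <- function(plan, contigs, gap_char = "N") {
  validate_scaffold_plan(plan)
  seqs <- setNames(contigs$seq, contigs$id)
  w_ids <- plan$component_id[plan$type == "W"]
  unknown <- setdiff(w_ids, names(seqs))
  if (length(unknown)) {
    abort(paste0("unknown plan component: ", paste(unknown, collapse = ", ")))
  }
  scafs <- as_tibble(plan) |>
    group_by(.data$scaffold_id) |>
    group_split() |>
    map(function(rows) {
      parts <- pmap(rows, function(type, component_id, orientation, length, ...) {
        if (type == "N") return(strrep(gap_char, length))
        s <- seqs[[component_id]]
        if (orientation == "-") revcomp(s) else s
      })
      tibble(id = rows$scaffold_id[1], seq = paste0(unlist(parts), collapse = ""))
    }) |>
    bind_rows()
  un <- unplaced_ids(plan)
  out <- bind_rows(scafs, tibble(id = un, seq = unname(seqs[un])))
  seq_records(out$id, out$seq, normalize = FALSE)
}

#' Reference-guided scaffolding of curated contigs
#'
#' Runs anchor-block construction, placement and ordering against one or more
#' reference genomes supplied in precedence order (closest relative first).
#' References are consumed sequentially: contigs still unplaced after
#' reference `k`, or placed with ambiguity above `max_ambiguity`, are offered
#' to reference `k+1`; a confident earlier placement is never overridden.
#'
#' @param contigs Sequence table of contigs.
#' @param ref_paf A PAF tibble (contigs on reference) or a list of them, one
#'   per reference in precedence order.
#' @param min_mapq,min_block,max_chain_gap Anchor filters; see
#'   [build_anchor_blocks()].
#' @param min_gap,prefix Gap floor and scaffold naming; see [order_and_gap()].
#' @param max_ambiguity Placements above this ambiguity are re-offered to the
#'   next reference (default 0.8).
#' @return List with `plan` (a [scaffold_plan()]), `placements`, and `blocks`.
#' @export
scaffold_contigs <- function(contigs, ref_paf, min_mapq = 30, min_block = 5000,
                             max_chain_gap = 100000, min_gap = 100,
                             prefix = "scf_", max_ambiguity = 0.8) {
  pafs <- if (is.data.frame(ref_paf)) list(ref_paf) else ref_paf
  lens <- seq_len_map(contigs)
  placements <- NULL
  blocks_all <- NULL
  pending <- contigs$id
  for (k in seq_along(pafs)) {
    pref_k <- if (k == 1) prefix else paste0(prefix, "r", k, "_")
    blocks <- build_anchor_blocks(pafs[[k]], min_mapq = min_mapq,
                                  min_block = min_block,
                                  max_chain_gap = max_chain_gap) |>
      filter(.data$contig_id %in% pending)
    pl <- place_contigs(blocks) |> mutate(reference = k, prefix = pref_k)
    if (!is.null(placements) && nrow(pl) > 0) {
      # a later confident placement supersedes an earlier ambiguous one
      placements <- filter(placements, !.data$contig_id %in% pl$contig_id)
    }
    placements <- bind_rows(placements, pl)
    blocks_all <- bind_rows(blocks_all, mutate(blocks, reference = k))
    pending <- c(setdiff(pending, placements$contig_id),
                 placements$contig_id[placements$ambiguity > max_ambiguity])
    if (length(pending) == 0) break
  }
  plans <- placements |>
    group_by(.data$reference) |>
    group_split() |>
    map(function(pl) {
      blk <- filter(blocks_all, .data$reference == pl$reference[1],
                    .data$contig_id %in% pl$contig_id)
      order_and_gap(select(pl, -"reference", -"prefix"), blk,
                    lens[pl$contig_id], min_gap = min_gap,
                    prefix = pl$prefix[1])
    })
  components <- bind_rows(map(plans, as_tibble))
  plan <- scaffold_plan(components,
                        unplaced = setdiff(contigs$id, placements$contig_id))
  list(plan = plan, placements = select(placements, -"prefix"),
       blocks = blocks_all)
}
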