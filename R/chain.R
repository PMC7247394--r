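# Collinear chaining of query-sorted alignment records.
#
# Shared by anchor-block construction (contig-to-reference) and rearrangement
# counting (assembly-to-reference). Records are grouped per query, sorted by
# query_start, and consecutive records are merged into one chain when they
# share (target, strand), both the query gap and the target gap are at most
# max_gap, and the target order is collinear for the strand (increasing for +,
# decreasing for -). Output intervals are the members' convex hulls.
chain_records <- function(paf, max_gap) {
  if (!"n_members" %in% names(paf)) paf$n_members <- rep(1L, nrow(paf))
  if (!"weight" %in% names(paf)) paf$weight <- paf$matches
  if (nrow(paf) == 0) {
    return(select(empty_paf(), -"tags") |>
             mutate(n_members = integer(), weight = numeric()))
  }
  paf <- arrange(paf, .data$query_name, .data$query_start, .data$target_start)
  chains <- paf |>
    group_by(.data$query_name) |>
    group_split() |>
    map(function(a) {
      n <- nrow(a)
      grp <- integer(n)
      grp[1] <- 1
      if (n > 1) {
        for (i in 2:n) {
          prev <- i - 1
          same <- a$target_name[i] == a$target_name[prev] &&
            a$strand[i] == a$strand[prev]
          qgap_ok <- a$query_start[i] - a$query_end[prev] <= max_gap
          tgap_ok <- if (!same) FALSE else if (a$strand[i] == "+") {
            a$target_start[i] >= a$target_start[prev] &&
              a$target_start[i] - a$target_end[prev] <= max_gap
          } else {
            a$target_end[i] <= a$target_end[prev] &&
              a$target_start[prev] - a$target_end[i] <= max_gap
          }
          grp[i] <- if (same && qgap_ok && tgap_ok) grp[prev] else grp[prev] + 1
        }
      }
      a |>
        group_by(grp = grp) |>
        summarise(
          query_name = .data$query_name[1],
          query_length = .data$query_length[1],
          query_start = min(.data$query_start),
          query_end = max(.data$query_end),
          strand = .data$strand[1],
          target_name = .data$target_name[1],
          target_length = .data$target_length[1],
          target_start = min(.data$target_start),
          target_end = max(.data$target_end),
          matches = sum(.data$matches),
          block_length = sum(.data$block_length),
          mapq = min(.data$mapq),
          n_members = sum(.data$n_members),
          weight = sum(.data$weight),
          .groups = "drop") |>
        select(-"grp")
    })
  bind_rows(chains) |> arrange(.data$query_name, .data$query_start)
}

#' Combine split neighbouring alignments into chains
#'
#' Long-read assemblies aligned to a reference are typically reported as many
#' split records; before counting large-scale rearrangements, neighbouring
#' records of the same query that continue collinearly on the same reference
#' chromosome and strand are combined into a single chained alignment.
#' Chaining is idempotent.
#'
#' @param alignments PAF tibble (usually MQ-filtered via [filter_mq()]).
#' @param max_chain_gap Maximum query and target gap (bases) bridged within a
#'   chain (default 300000, matching the event-size threshold so that splits
#'   smaller than a countable event never fragment a chain).
#' @return Chain tibble in PAF-like columns plus `n_members` (records merged)
#'   and `weight` (summed matches), sorted by query and query_start.
#' @export
chain_alignments <- function(alignments, max_chain_gap = 300000) {
  chain_records(alignments, max_chain_gap)
}
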