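#' Construct a scaffold plan
#'
#' A scaffold plan is the ordered, oriented layout of contig components and
#' estimated gaps for each scaffold, plus the set of unplaced contigs. It is a
#' tibble of component rows with class `scaffold_plan`:
#' \describe{
#'   \item{scaffold_id}{scaffold name}
#'   \item{part_number}{1-based consecutive row index within the scaffold}
#'   \item{type}{`"W"` for a contig component, `"N"` for an estimated gap}
#'   \item{component_id}{contig id for `W` rows, `NA` for gaps}
#'   \item{orientation}{`"+"`/`"-"` for `W` rows, `NA` for gaps}
#'   \item{length}{component length for `W` rows, gap length for `N` rows}
#' }
#'
#' @param components Tibble as described above.
#' @param unplaced Character vector of contig ids not placed in any scaffold.
#' @return A `scaffold_plan` object.
#' @export
scaffold_plan <- function(components, unplaced = character()) {
  components <- as_tibble(components)
  canon <- c("scaffold_id", "part_number", "type", "component_id",
             "orientation", "length")
  if (all(canon %in% names(components))) {
    components <- components[, c(canon, setdiff(names(components), canon))]
  }
  out <- structure(components, unplaced = unique(as.character(unplaced)),
                   class = c("scaffold_plan", class(components)))
  validate_scaffold_plan(out)
}

#' @export
print.scaffold_plan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<scaffold_plan> %d scaffold(s), %d component(s), %d gap(s) (%s gap bases), %d unplaced\n",
    g$n_scaffolds, g$n_components, g$n_gaps,
    format(g$gap_bases, big.mark = ","), g$n_unplaced))
  NextMethod()
}

#' Validate scaffold-plan invariants
#'
#' Checks consecutive part numbers, alternation (no two adjacent gap rows, no
#' terminal gap rows), positive lengths, and that no contig id appears both
#' placed and unplaced (or twice placed).
#'
#' @param plan A `scaffold_plan`.
#' @return `plan`, unchanged.
#' @export
validate_scaffold_plan <- function(plan) {
  need <- c("scaffold_id", "part_number", "type", "component_id",
            "orientation", "length")
  miss <- setdiff(need, names(plan))
  if (length(miss)) abort(paste0("plan missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!all(plan$type %in% c("W", "N"))) abort("component type must be W or N")
  if (any(plan$length < 1)) abort("component/gap lengths must be >= 1")
  w <- plan[plan$type == "W", ]
  if (anyNA(w$component_id) || anyDuplicated(w$component_id)) {
    abort("every W row needs a unique component_id")
  }
  if (!all(w$orientation %in% c("+", "-"))) {
    abort("W-row orientation must be + or -")
  }
  both <- intersect(w$component_id, attr(plan, "unplaced"))
  if (length(both)) abort(paste0("contig both placed and unplaced: ",
                                 paste(both, collapse = ", ")))
  for (sid in unique(plan$scaffold_id)) {
    rows <- plan[plan$scaffold_id == sid, ]
    if (!identical(as.integer(rows$part_number), seq_len(nrow(rows)))) {
      abort(paste0("part numbers not consecutive from 1 in scaffold ", sid))
    }
    ty <- rows$type
    if (ty[1] == "N" || ty[length(ty)] == "N" ||
        any(ty[-1] == "N" & ty[-length(ty)] == "N")) {
      abort(paste0("gap rows must alternate with components in scaffold ", sid))
    }
  }
  plan
}

unplaced_ids <- function(plan) attr(plan, "unplaced") %||% character()

#' @rdname scaffold_plan
#' @param x A `scaffold_plan`.
#' @param ... Unused.
#' @return `tidy()` returns the component rows with 0-based half-open scaffold
#'   coordinates (`scaffold_start`, `scaffold_end`) added.
#' @export
tidy.scaffold_plan <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$scaffold_id) |>
    mutate(scaffold_end = cumsum(.data$length),
           scaffold_start = .data$scaffold_end - .data$length) |>
    ungroup()
}

#' @rdname scaffold_plan
#' @return `glance()` returns a one-row summary: scaffold, component, gap and
#'   unplaced counts plus gap and total bases.
#' @export
glance.scaffold_plan <- function(x, ...) {
  tibble(
    n_scaffolds = length(unique(x$scaffold_id)),
    n_components = sum(x$type == "W"),
    n_gaps = sum(x$type == "N"),
    gap_bases = sum(x$length[x$type == "N"]),
    total_length = sum(x$length),
    n_unplaced = length(unplaced_ids(x))
  )
}
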