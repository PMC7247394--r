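#' Write a scaffold plan as AGP v2.1
#'
#' Emits one object per scaffold whose rows tile `[1, scaffold_length]` in
#' 1-based inclusive coordinates (the format's native convention; all internal
#' coordinates stay 0-based half-open). Gap rows are `N` rows of the plan's
#' estimated length with gap type `scaffold`, linkage `yes`, evidence
#' `align_genus`. Unplaced contigs are emitted as single-component objects
#' under their own ids.
#'
#' @param plan A [scaffold_plan()].
#' @param path Output path.
#' @param contig_lengths Named vector of contig lengths; required only when the
#'   plan has unplaced contigs (their lengths are not part of the plan rows).
#' @return `path`, invisibly.
#' @export
write_agp <- function(plan, path, contig_lengths = NULL) {
  validate_scaffold_plan(plan)
  td <- tidy(plan)
  rows <- ifelse(
    td$type == "W",
    paste(td$scaffold_id, td$scaffold_start + 1, td$scaffold_end,
          td$part_number, "W", td$component_id, 1, td$length, td$orientation,
          sep = "\t"),
    paste(td$scaffold_id, td$scaffold_start + 1, td$scaffold_end,
          td$part_number, "N", td$length, "scaffold", "yes", "align_genus",
          sep = "\t"))
  un <- unplaced_ids(plan)
  if (length(un)) {
    if (is.null(contig_lengths) || !all(un %in% names(contig_lengths))) {
      abort("contig_lengths must cover all unplaced contigs")
    }
    rows <- c(rows, paste(un, 1, contig_lengths[un], 1, "W", un, 1,
                          contig_lengths[un], "+", sep = "\t"))
  }
  writeLines(c("##agp-version\t2.1", rows), path)
  invisible(path)
}

#' Read an AGP file into a scaffold plan
#'
#' Accepts AGP v2.0/2.1 with `W` (contig) and `N`/`U` (gap) rows. Verifies that
#' the rows of each object tile it without overlap or holes and that each `W`
#' row spans its full component. Coordinates are converted from the format's
#' 1-based inclusive convention to the package's 0-based half-open one.
#'
#' @param path Path to an AGP file.
#' @return A [scaffold_plan()] (with an empty unplaced set: AGP does not
#'   distinguish unplaced contigs from single-contig scaffolds).
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(scaffold_plan(tibble(
      scaffold_id = character(), part_number = integer(), type = character(),
      component_id = character(), orientation = character(),
      length = numeric())))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 8)) abort("AGP rows need at least 8 columns")
  get <- function(i) map_chr(f, function(x) if (length(x) >= i) x[i] else NA)
  type <- get(5)
  beg <- as.numeric(get(2)); end <- as.numeric(get(3))
  comp <- tibble(
    scaffold_id = get(1),
    part_number = as.integer(get(4)),
    type = ifelse(type %in% c("N", "U"), "N", "W"),
    component_id = ifelse(type %in% c("N", "U"), NA_character_, get(6)),
    orientation = ifelse(type %in% c("N", "U"), NA_character_, get(9)),
    length = end - beg + 1
  )
  # tiling check against the stated object coordinates
  expected <- comp |>
    group_by(.data$scaffold_id) |>
    mutate(exp_end = cumsum(.data$length), exp_beg = .data$exp_end - .data$length + 1) |>
    ungroup()
  if (!all(beg == expected$exp_beg & end == expected$exp_end)) {
    abort("AGP rows do not tile their objects without overlap or holes")
  }
  wrow <- comp$type == "W"
  span <- as.numeric(get(8)[wrow]) - as.numeric(get(7)[wrow]) + 1
  if (!all(span == comp$length[wrow])) {
    abort("W-row object span must equal its component span")
  }
  scaffold_plan(comp)
}

#' Write intervals as BED3+1
#'
#' @param intervals Tibble with columns `name`, `start`, `end` (0-based
#'   half-open) and optionally `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start < 0 | intervals$start >= intervals$end)) {
    abort("BED intervals require 0 <= start < end")
  }
  label <- if ("label" %in% names(intervals)) intervals$label else rep(".", nrow(intervals))
  writeLines(paste(intervals$name,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   label, sep = "\t"), path)
  invisible(path)
}
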