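#' Default pipeline configuration
#'
#' All stage parameters with their package defaults. Input paths are empty
#' and must be filled in (or supplied by [simulate_to_dir()] output).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    threads = 1,
    skip_curation = FALSE,
    inputs = list(
      contigs = "", reads = "", reads_paf = "", endpair_paf = "",
      alt_paf = "", ref_paf = list(), reads_on_scaffolds_paf = "",
      contigs_on_scaffolds_paf = "", scaffolds_on_ref_paf = "",
      ref_lengths = ""),
    external = list(mapper = "", assembler = ""),
    curate = list(min_mapq = 0, coverage_tolerance = 100, min_zero_run = 1,
                  max_mapped_fraction = 0.10, end_length = 500),
    scaffold = list(min_mapq = 30, min_block = 5000, max_chain_gap = 100000,
                    min_gap = 100, prefix = "scf_", max_ambiguity = 0.8),
    conflicts = list(min_mapq = 30, max_jump = 1000000, min_side = 50000),
    gapfill = list(window = 20000, chunk_length = 250000, step = 200000,
                   min_overlap = 1000, min_identity = 0.95,
                   max_search = 100000),
    svstats = list(min_mapq = 60, max_chain_gap = 300000,
                   min_event_size = 300000),
    stats = list(top_n = 0, min_gap_run = 10)
  )
}

#' Write the default configuration file
#'
#' Emits a commented YAML config containing every default; the file
#' round-trips through [read_config()].
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  header <- c(
    "# chromoscaf pipeline configuration",
    "# - inputs.ref_paf lists contig-to-reference PAF files in precedence",
    "#   order (closest reference first)",
    "# - alignments are pluggable: supply PAF from any aligner, or truth PAF",
    "#   from the synthetic generator",
    "# - external.mapper/assembler are optional command templates",
    "")
  body <- yaml::as.yaml(default_config())
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' Unknown keys (at any level) are rejected by name; missing keys fall back
#' to the defaults of [default_config()].
#'
#' @param path Path to a YAML config file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user %||% list(), prefix = "")
}

merge_config <- function(defaults, user, prefix) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key: ", prefix, unknown[1]))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

read_paf_maybe <- function(path) {
  if (is.null(path) || !nzchar(path)) return(NULL)
  read_paf(path)
}

# rewrite PAF records of split contigs onto their fragments; alignments are
# intersected with fragment intervals so downstream stages need no re-mapping
translate_paf_after_splits <- function(paf, splits, contig_lengths) {
  if (nrow(splits) == 0 || nrow(paf) == 0) return(paf)
  frag_map <- splits |>
    group_by(.data$contig_id) |>
    summarise(cuts = list(sort(unique(.data$position)))) |>
    mutate(len = contig_lengths[.data$contig_id])
  pieces <- pmap(frag_map, function(contig_id, cuts, len) {
    edges <- c(0, cuts, len)
    tibble(old_id = contig_id,
           new_id = paste0(contig_id, ".", seq_len(length(edges) - 1)),
           f_start = head(edges, -1), f_end = edges[-1])
  }) |> bind_rows()
  untouched <- paf[!paf$query_name %in% pieces$old_id, ]
  touched <- paf[paf$query_name %in% pieces$old_id, ] |>
    left_join(pieces, by = c(query_name = "old_id"),
              relationship = "many-to-many") |>
    filter(.data$query_start < .data$f_end, .data$query_end > .data$f_start) |>
    mutate(
      clip_lo = pmax(.data$query_start, .data$f_start),
      clip_hi = pmin(.data$query_end, .data$f_end),
      scale = (.data$clip_hi - .data$clip_lo) /
        (.data$query_end - .data$query_start),
      matches = floor(.data$matches * .data$scale),
      block_length = pmax(floor(.data$block_length * .data$scale),
                          floor(.data$matches)),
      target_start = ifelse(
        .data$strand == "+",
        .data$target_start + (.data$clip_lo - .data$query_start),
        .data$target_start + (.data$query_end - .data$clip_hi)),
      target_end = .data$target_start + (.data$clip_hi - .data$clip_lo),
      query_name = .data$new_id,
      query_length = .data$f_end - .data$f_start,
      query_start = .data$clip_lo - .data$f_start,
      query_end = .data$clip_hi - .data$f_start) |>
    filter(.data$matches >= 1) |>
    select(names(untouched))
  bind_rows(untouched, touched) |>
    arrange(.data$query_name, .data$query_start)
}

#' Run the full pipeline
#'
#' Orchestrates curation, reference-guided scaffolding, conflict splitting,
#' gap closing/stitching and final statistics over pluggable alignment
#' inputs, writing all artifacts plus a checksum manifest and a structured
#' stage log to `outdir`. Stages whose optional inputs are absent are skipped
#' and logged: curation needs `reads_paf`, conflict splitting needs
#' `contigs_on_scaffolds_paf`, patch-based gap filling needs `reads` plus
#' `reads_on_scaffolds_paf` (direct flank stitching always runs), and
#' rearrangement counting needs `scaffolds_on_ref_paf`. Scaffolding
#' (`ref_paf`) is required. After curation, alignments of split contigs are
#' translated onto the fragments, so no re-mapping step is needed.
#'
#' @param config A config list from [read_config()]/[default_config()], or a
#'   path to a YAML config file.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (tibble: stage, file, md5),
#'   `log` (per-stage counter tibble), and the final `plan`, `scaffolds`,
#'   `report`, `stats`, and `sv` (or `NULL` where skipped).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- tibble(stage = stage, ...)
  }
  inp <- config$inputs
  if (!nzchar(inp$contigs)) abort("inputs.contigs is required")
  contigs <- read_fasta(inp$contigs)

  # -- step 1: curation ------------------------------------------------------
  reads_paf <- read_paf_maybe(inp$reads_paf)
  splits <- tibble(contig_id = character(), position = numeric(),
                   reason = character())
  if (!isTRUE(config$skip_curation) && !is.null(reads_paf)) {
    cur <- curate_contigs(
      contigs, reads_paf,
      endpair_paf = read_paf_maybe(inp$endpair_paf),
      alt_paf = read_paf_maybe(inp$alt_paf),
      min_mapq = config$curate$min_mapq,
      coverage_tolerance = config$curate$coverage_tolerance,
      min_zero_run = config$curate$min_zero_run,
      max_mapped_fraction = config$curate$max_mapped_fraction)
    splits <- cur$splits
    lens_before <- seq_len_map(contigs)
    contigs <- cur$contigs
    note("curate", n_splits = nrow(splits), n_rescued = sum(cur$rescue$rescued))
    readr::write_lines(cur$rescue$read_id[cur$rescue$rescued],
                       file.path(outdir, "rescue_reads.txt"))
    if (nrow(splits) > 0) {
      write_bed(tibble(name = splits$contig_id, start = splits$position,
                       end = splits$position + 1, label = splits$reason),
                file.path(outdir, "splits.bed"))
    }
  } else {
    lens_before <- seq_len_map(contigs)
    note("curate", skipped = TRUE)
  }
  write_fasta(contigs, file.path(outdir, "curated_contigs.fa"))

  # -- step 2: reference-guided scaffolding ---------------------------------
  if (length(inp$ref_paf) == 0) abort("inputs.ref_paf is required")
  ref_pafs <- map(inp$ref_paf, read_paf)
  ref_pafs <- map(ref_pafs, translate_paf_after_splits, splits = splits,
                  contig_lengths = lens_before)
  sc <- scaffold_contigs(
    contigs, ref_pafs, min_mapq = config$scaffold$min_mapq,
    min_block = config$scaffold$min_block,
    max_chain_gap = config$scaffold$max_chain_gap,
    min_gap = config$scaffold$min_gap, prefix = config$scaffold$prefix,
    max_ambiguity = config$scaffold$max_ambiguity)
  plan <- sc$plan
  note("scaffold", n_scaffolds = glance(plan)$n_scaffolds,
       n_placed = nrow(sc$placements),
       n_unplaced = glance(plan)$n_unplaced)
  readr::write_tsv(sc$placements, file.path(outdir, "placements.tsv"))

  # -- step 3: conflict splitting against the prior plan --------------------
  conflict_paf <- read_paf_maybe(inp$contigs_on_scaffolds_paf)
  if (!is.null(conflict_paf)) {
    conflicts <- detect_scaffold_conflicts(
      conflict_paf, min_mapq = config$conflicts$min_mapq,
      max_jump = config$conflicts$max_jump,
      min_side = config$conflicts$min_side)
    note("conflicts", n_splits = nrow(conflicts))
    if (nrow(conflicts) > 0) {
      lens_now <- seq_len_map(contigs)
      contigs <- apply_splits(contigs, conflicts)
      ref_pafs <- map(ref_pafs, translate_paf_after_splits,
                      splits = conflicts, contig_lengths = lens_now)
      sc <- scaffold_contigs(
        contigs, ref_pafs, min_mapq = config$scaffold$min_mapq,
        min_block = config$scaffold$min_block,
        max_chain_gap = config$scaffold$max_chain_gap,
        min_gap = config$scaffold$min_gap, prefix = config$scaffold$prefix,
        max_ambiguity = config$scaffold$max_ambiguity)
      plan <- sc$plan
    }
  } else {
    note("conflicts", skipped = TRUE)
  }

  # -- step 3/4: gap filling and stitching ----------------------------------
  patches <- NULL
  reads <- if (nzchar(inp$reads)) read_fasta(inp$reads) else NULL
  windows_paf <- read_paf_maybe(inp$reads_on_scaffolds_paf)
  if (!is.null(reads) && !is.null(windows_paf)) {
    windows <- extract_gap_windows(plan, windows_paf,
                                   window = config$gapfill$window)
    win_dir <- file.path(outdir, "gap_windows")
    dir.create(win_dir, showWarnings = FALSE)
    patch_list <- pmap(windows, function(gap_id, read_ids, ...) {
      win_reads <- reads[reads$id %in% read_ids, ]
      if (nrow(win_reads) == 0) return(NULL)
      write_fasta(win_reads,
                  file.path(win_dir, paste0(gsub(":", "_", gap_id), ".fa")))
      asm <- greedy_overlap_assemble(
        win_reads, min_overlap = config$gapfill$min_overlap,
        min_identity = config$gapfill$min_identity)
      mutate(asm, id = paste0(gap_id, "|", .data$id))
    })
    patches <- bind_rows(patch_list)
    if (!is.null(patches) && nrow(patches) > 0) {
      patches <- seq_records(patches$id, patches$seq, normalize = FALSE)
    }
    note("gapfill_windows", n_windows = nrow(windows),
         n_patches = if (is.null(patches)) 0L else nrow(patches))
  }
  closed <- close_gaps(plan, contigs, patches = patches,
                       min_overlap = config$gapfill$min_overlap,
                       min_identity = config$gapfill$min_identity,
                       max_search = config$gapfill$max_search)
  plan <- closed$plan
  note("gapclose",
       n_closed = sum(closed$report$outcome != "open"),
       n_patched = sum(closed$report$outcome == "patched"),
       n_stitched = sum(closed$report$outcome == "stitched"),
       n_open = sum(closed$report$outcome == "open"))
  readr::write_tsv(closed$report, file.path(outdir, "gap_report.tsv"))
  scaffolds <- plan_to_sequences(plan, closed$contigs)
  write_fasta(scaffolds, file.path(outdir, "scaffolds.fa"))
  write_agp(plan, file.path(outdir, "scaffolds.agp"),
            contig_lengths = seq_len_map(closed$contigs))

  # -- statistics and rearrangement counting --------------------------------
  stats <- assembly_report(scaffolds, n = config$stats$top_n,
                           min_gap_run = config$stats$min_gap_run)
  readr::write_tsv(stats, file.path(outdir, "assembly_stats.tsv"))
  sv <- NULL
  sv_paf <- read_paf_maybe(inp$scaffolds_on_ref_paf)
  if (!is.null(sv_paf)) {
    chains <- chain_alignments(filter_mq(sv_paf, config$svstats$min_mapq),
                               max_chain_gap = config$svstats$max_chain_gap)
    sv <- classify_events(chains,
                          min_event_size = config$svstats$min_event_size)
    readr::write_tsv(tidy(sv), file.path(outdir, "sv_events.tsv"))
    readr::write_tsv(glance(sv), file.path(outdir, "sv_counts.tsv"))
    ref_lengths <- setNames(sv_paf$target_length, sv_paf$target_name)
    ref_lengths <- ref_lengths[!duplicated(names(ref_lengths))]
    readr::write_tsv(
      dotplot_data(chains, ref_lengths, seq_len_map(scaffolds)),
      file.path(outdir, "dotplot.tsv"))
    note("svstats", f = sv$counts$f, t = sv$counts$t, i = sv$counts$i)
  } else {
    note("svstats", skipped = TRUE)
  }

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- tibble(
    file = list.files(outdir, recursive = TRUE),
    md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  log_tbl <- bind_rows(log)
  readr::write_tsv(log_tbl, file.path(outdir, "pipeline_log.tsv"))
  invisible(list(manifest = manifest, log = log_tbl, plan = plan,
                 scaffolds = scaffolds, report = closed$report,
                 stats = stats, sv = sv))
}

#' Write a synthetic benchmark data set to a directory
#'
#' Generates a reference, a rearranged sample genome, contigs, reads and
#' truth alignments, and writes them as FASTA/PAF/TSV so the pipeline (or an
#' external tool chain) can consume them as ordinary files.
#'
#' @param outdir Output directory.
#' @param chrom_lengths Reference chromosome lengths.
#' @param events Event tibble for [plant_rearrangements()] (default: none).
#' @param target_n50 Contig fragmentation target N50.
#' @param coverage Read coverage (0 disables read simulation).
#' @param seed Integer seed.
#' @param margin Event placement margin (see [plant_rearrangements()]).
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
simulate_to_dir <- function(outdir, chrom_lengths, events = NULL,
                            target_n50 = 1000000, coverage = 0, seed = 1,
                            margin = 1000000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(chrom_lengths, seed = seed)
  if (!is.null(events) && nrow(as_tibble(events)) > 0) {
    planted <- plant_rearrangements(reference, events, seed = seed + 1,
                                    margin = margin)
    sample_genome <- planted$genome
    truth <- planted$truth
  } else {
    sample_genome <- reference
    truth <- NULL
  }
  frag <- fragment_into_contigs(sample_genome, target_n50 = target_n50,
                                seed = seed + 2)
  paf <- truth_alignments(frag$provenance, truth,
                          contig_lengths = seq_len_map(frag$contigs),
                          ref_lengths = seq_len_map(reference))
  write_fasta(reference, file.path(outdir, "reference.fa"))
  write_fasta(sample_genome, file.path(outdir, "sample.fa"))
  write_fasta(frag$contigs, file.path(outdir, "contigs.fa"))
  write_paf(paf, file.path(outdir, "contigs_on_reference.paf"))
  readr::write_tsv(frag$provenance, file.path(outdir, "contig_provenance.tsv"))
  reads <- NULL
  if (coverage > 0) {
    sim <- simulate_reads(sample_genome, coverage = coverage, seed = seed + 3)
    reads <- sim$reads
    write_fasta(reads, file.path(outdir, "reads.fa"))
    readr::write_tsv(sim$provenance, file.path(outdir, "read_provenance.tsv"))
    reads_paf <- reads_to_contigs_truth(sim$provenance, frag$provenance,
                                        seq_len_map(reads),
                                        seq_len_map(frag$contigs))
    write_paf(reads_paf, file.path(outdir, "reads_on_contigs.paf"))
  }
  if (!is.null(truth)) {
    readr::write_tsv(truth$events, file.path(outdir, "truth_events.tsv"))
  }
  invisible(list(reference = reference, sample = sample_genome,
                 contigs = frag$contigs, provenance = frag$provenance,
                 truth = truth, paf = paf, reads = reads, outdir = outdir))
}
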