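test_that("anchor blocks chain collinear records and filter by size/mapq", {
  aln <- dplyr::bind_rows(
    paf_row(query_name = "c1", query_length = 50000, query_start = 0,
            query_end = 10000, target_name = "chr1", target_length = 1e6,
            target_start = 100000, target_end = 110000),
    paf_row(query_name = "c1", query_length = 50000, query_start = 20000,
            query_end = 30000, target_name = "chr1", target_length = 1e6,
            target_start = 122000, target_end = 132000))
  blk <- build_anchor_blocks(aln, max_chain_gap = 100000)
  expect_equal(nrow(blk), 1)
  expect_equal(blk$weight, 20000)
  expect_equal(blk$contig_start, 0)
  expect_equal(blk$contig_end, 30000)
  expect_equal(blk$n_members, 2)

  # opposite strands never merge
  aln2 <- aln
  aln2$strand[2] <- "-"
  expect_equal(nrow(build_anchor_blocks(aln2, max_chain_gap = 1e5,
                                        min_block = 1000)), 2)

  # below min_mapq is dropped
  aln3 <- aln
  aln3$mapq <- c(20, 60)
  blk3 <- build_anchor_blocks(aln3, min_mapq = 30, min_block = 5000)
  expect_equal(blk3$weight, 10000)

  # merged span below min_block is discarded
  expect_equal(nrow(build_anchor_blocks(aln, min_block = 50000)), 0)
})

test_that("place_contigs picks majority chromosome, strand, and ambiguity", {
  blocks <- tibble::tibble(
    contig_id = "c1", contig_length = 100000,
    contig_start = c(0, 50000), contig_end = c(40000, 90000),
    ref_name = c("chr1", "chr2"), ref_length = 1e6,
    ref_start = c(0, 0), ref_end = c(40000, 40000),
    strand = "+", n_members = 1L, weight = c(800, 200))
  pl <- place_contigs(blocks)
  expect_equal(pl$ref_name, "chr1")
  expect_equal(pl$ambiguity, 0.25)
  expect_equal(pl$support, 800)

  # strand majority -> minus
  blocks2 <- dplyr::mutate(blocks, ref_name = "chr1",
                           strand = c("+", "-"), weight = c(300, 700))
  expect_equal(place_contigs(blocks2)$orientation, "-")

  # exact chromosome tie -> lexicographically smallest, ambiguity 1
  blocks3 <- dplyr::mutate(blocks, weight = c(500, 500))
  pl3 <- place_contigs(blocks3)
  expect_equal(pl3$ref_name, "chr1")
  expect_equal(pl3$ambiguity, 1.0)
})

test_that("order_and_gap projects reference distance into gap estimates", {
  blocks <- dplyr::bind_rows(
    tibble::tibble(contig_id = "A", contig_length = 200000, contig_start = 0,
                   contig_end = 200000, ref_name = "chr1", ref_length = 5e6,
                   ref_start = 900000, ref_end = 1100000, strand = "+",
                   n_members = 1L, weight = 200000),
    tibble::tibble(contig_id = "B", contig_length = 200000, contig_start = 0,
                   contig_end = 200000, ref_name = "chr1", ref_length = 5e6,
                   ref_start = 1900000, ref_end = 2100000, strand = "+",
                   n_members = 1L, weight = 200000))
  pl <- place_contigs(blocks)
  plan <- order_and_gap(pl, blocks, c(A = 200000, B = 200000))
  expect_equal(plan$component_id[plan$type == "W"], c("A", "B"))
  expect_equal(plan$length[plan$type == "N"], 800000)

  # anchor overlap projects a negative gap: floored at min_gap
  blocks$ref_start[2] <- 1050000
  blocks$ref_end[2] <- 1250000
  plan2 <- order_and_gap(place_contigs(blocks), blocks,
                         c(A = 200000, B = 200000), min_gap = 100)
  expect_equal(plan2$length[plan2$type == "N"], 100)

  # single placed contig: one-component scaffold, no gap rows
  plan3 <- order_and_gap(place_contigs(blocks[1, ]), blocks[1, ],
                         c(A = 200000))
  expect_equal(nrow(plan3), 1)
  expect_equal(plan3$scaffold_id, "scf_chr1")
})

test_that("unaligned contig tails shrink the projected gap", {
  # A aligns on its first half only: 100 kb unaligned tail faces the gap
  blocks <- dplyr::bind_rows(
    tibble::tibble(contig_id = "A", contig_length = 200000, contig_start = 0,
                   contig_end = 100000, ref_name = "chr1", ref_length = 5e6,
                   ref_start = 1000000, ref_end = 1100000, strand = "+",
                   n_members = 1L, weight = 100000),
    tibble::tibble(contig_id = "B", contig_length = 100000, contig_start = 0,
                   contig_end = 100000, ref_name = "chr1", ref_length = 5e6,
                   ref_start = 2000000, ref_end = 2100000, strand = "+",
                   n_members = 1L, weight = 100000))
  plan <- order_and_gap(place_contigs(blocks), blocks,
                        c(A = 200000, B = 100000))
  expect_equal(plan$length[plan$type == "N"], 900000 - 100000)
})

test_that("scaffold conflicts split at inter-scaffold and long-jump junctions", {
  two <- dplyr::bind_rows(
    paf_row(query_name = "c1", query_length = 1000000, query_start = 0,
            query_end = 600000, target_name = "scf1", target_length = 5e6,
            target_start = 0, target_end = 600000),
    paf_row(query_name = "c1", query_length = 1000000, query_start = 600000,
            query_end = 1000000, target_name = "scf2", target_length = 5e6,
            target_start = 0, target_end = 400000))
  sp <- detect_scaffold_conflicts(two)
  expect_equal(sp$position, 600000)
  expect_equal(sp$reason, "scaffold_conflict")

  jump <- dplyr::mutate(two, target_name = "scf1",
                        target_start = c(0, 5600000),
                        target_end = c(600000, 6000000),
                        target_length = 7e6)
  expect_equal(detect_scaffold_conflicts(jump, max_jump = 1e6)$position,
               600000)
  # within max_jump: clean collinear contig
  near <- dplyr::mutate(two, target_name = "scf1",
                        target_start = c(0, 700000),
                        target_end = c(600000, 1100000))
  expect_equal(nrow(detect_scaffold_conflicts(near)), 0)
  # unsupported side below min_side reports nothing
  expect_equal(nrow(detect_scaffold_conflicts(two, min_side = 700000)), 0)
})

test_that("plan_to_sequences orients components and conserves bases", {
  contigs <- seq_records(c("c1", "c2"), c("AAAAA", "AACC"))
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:3, type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), orientation = c("+", NA, "-"),
    length = c(5, 3, 4)))
  out <- plan_to_sequences(plan, contigs)
  expect_equal(out$seq, "AAAAANNNGGTT")
  expect_equal(out$length, 12)

  # only unplaced contigs: identity
  plan2 <- scaffold_plan(
    tibble::tibble(scaffold_id = character(), part_number = integer(),
                   type = character(), component_id = character(),
                   orientation = character(), length = numeric()),
    unplaced = c("c1", "c2"))
  out2 <- plan_to_sequences(plan2, contigs)
  expect_equal(out2$seq, contigs$seq)

  expect_error(plan_to_sequences(plan, contigs[1, ]), "unknown")
})

test_that("AGP written from a plan reconstructs identical scaffold sequences", {
  set.seed(77)
  contigs <- seq_records(c("c1", "c2", "c3"),
                         vapply(c(500, 300, 400), random_seq, ""))
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:5, type = c("W", "N", "W", "N", "W"),
    component_id = c("c2", NA, "c1", NA, "c3"),
    orientation = c("-", NA, "+", NA, "-"),
    length = c(300, 120, 500, 80, 400)))
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(plan, path)
  back <- read_agp(path)
  expect_identical(plan_to_sequences(back, contigs)$seq,
                   plan_to_sequences(plan, contigs)$seq)
})

test_that("scaffolding recovers order, orientation and sequence of a genome", {
  genome <- simulate_reference(c(1200000, 800000), seed = 201)
  frag <- fragment_into_contigs(genome, target_n50 = 60000, seed = 202)
  expect_gte(nrow(frag$contigs), 20)
  paf <- truth_alignments(frag$provenance, NULL,
                          contig_lengths = setNames(frag$contigs$length,
                                                    frag$contigs$id),
                          ref_lengths = setNames(genome$length, genome$id))
  sc <- scaffold_contigs(frag$contigs, paf, min_block = 1000)
  td <- tidy(sc$plan) |> dplyr::filter(type == "W")
  truth_order <- frag$provenance |> dplyr::arrange(chrom, start)
  expect_equal(td$component_id, truth_order$contig_id)
  expect_equal(td$orientation, truth_order$strand)
  expect_equal(length(attr(sc$plan, "unplaced")), 0)

  scafs <- plan_to_sequences(sc$plan, frag$contigs)
  expect_identical(gsub("N+", "", scafs$seq[order(scafs$id)]),
                   genome$seq[order(paste0("scf_", genome$id))])
})

test_that("scaffolding output is byte-identical across repeated runs", {
  genome <- simulate_reference(c(400000), seed = 301)
  frag <- fragment_into_contigs(genome, target_n50 = 40000, seed = 302)
  paf <- truth_alignments(frag$provenance, NULL,
                          setNames(frag$contigs$length, frag$contigs$id),
                          setNames(genome$length, genome$id))
  run <- function() {
    sc <- scaffold_contigs(frag$contigs, paf, min_block = 1000)
    list(as.data.frame(sc$plan), plan_to_sequences(sc$plan, frag$contigs)$seq)
  }
  expect_identical(run(), run())
})

test_that("a later reference places leftovers without unplacing earlier ones", {
  genome <- simulate_reference(c(500000, 300000), seed = 401)
  frag <- fragment_into_contigs(genome, target_n50 = 50000, seed = 402)
  lens <- setNames(frag$contigs$length, frag$contigs$id)
  paf <- truth_alignments(frag$provenance, NULL, lens,
                          setNames(genome$length, genome$id))
  # reference 1 only knows chr1; reference 2 only chr2
  paf1 <- paf[paf$target_name == "chr1", ]
  paf2 <- paf[paf$target_name == "chr2", ]
  sc <- scaffold_contigs(frag$contigs, list(paf1, paf2), min_block = 1000)
  expect_equal(length(attr(sc$plan, "unplaced")), 0)
  placed1 <- sc$placements$contig_id[sc$placements$reference == 1]
  chr1_ctgs <- frag$provenance$contig_id[frag$provenance$chrom == "chr1"]
  expect_setequal(placed1, chr1_ctgs)
  # every chr1 contig keeps its first-reference placement
  expect_true(all(sc$placements$ref_name[match(chr1_ctgs,
                                               sc$placements$contig_id)] ==
                    "chr1"))
})
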