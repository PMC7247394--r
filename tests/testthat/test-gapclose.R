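test_that("gap windows clamp to the scaffold and collect overlapping reads", {
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:3, type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), orientation = c("+", NA, "-"),
    length = c(10000, 100, 89900)))   # gap at [10000, 10100), scaffold 100 kb
  aln <- dplyr::bind_rows(
    paf_row(query_name = "rin", query_length = 1000, query_start = 0,
            query_end = 1000, target_name = "s1", target_length = 100000,
            target_start = 25000, target_end = 26000),
    paf_row(query_name = "rout", query_length = 1000, query_start = 0,
            query_end = 1000, target_name = "s1", target_length = 100000,
            target_start = 50000, target_end = 51000))
  win <- extract_gap_windows(plan, aln, window = 20000)
  gap <- win[win$kind == "gap", ]
  expect_equal(gap$start, 0)          # 10000 - 20000 clamped
  expect_equal(gap$end, 30100)
  expect_true("rin" %in% gap$read_ids[[1]])
  expect_false("rout" %in% gap$read_ids[[1]])
})

test_that("a gapless scaffold yields exactly two terminal windows", {
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1L, type = "W", component_id = "c1",
    orientation = "+", length = 100000))
  win <- extract_gap_windows(plan, paf_row()[0, ], window = 20000)
  expect_equal(nrow(win), 2)
  expect_equal(sort(win$start), c(0, 80000))
  expect_equal(sort(win$end), c(20000, 100000))
  expect_true(all(win$kind == "terminus"))
})

test_that("pseudo-read chunks tile the contig with the stated overlap", {
  ctg <- seq_records("c1", random_seq(600000), normalize = FALSE)
  ch <- chunk_pseudo_reads(ctg, chunk_length = 250000, step = 200000)
  expect_equal(ch$id, c("c1:0-250000", "c1:200000-450000", "c1:400000-600000"))
  expect_equal(ch$seq[2], substr(ctg$seq, 200001, 450000))

  small <- seq_records("c2", random_seq(100000))
  expect_equal(chunk_pseudo_reads(small)$id, "c2:0-100000")

  expect_error(chunk_pseudo_reads(ctg, step = 0), "positive")
  expect_error(chunk_pseudo_reads(ctg, chunk_length = 300000), "256000")

  # union of chunk intervals covers [0, len) for any valid parameters
  set.seed(19)
  for (rep in 1:20) {
    len <- sample(1000:80000, 1)
    chunk <- sample(500:20000, 1)
    step <- sample(seq_len(chunk), 1)
    ch <- chunk_pseudo_reads(seq_records("x", random_seq(len)),
                             chunk_length = chunk, step = step)
    ivs <- do.call(rbind, lapply(strsplit(sub("^x:", "", ch$id), "-"),
                                 as.numeric))
    expect_equal(min(ivs[, 1]), 0)
    expect_equal(max(ivs[, 2]), len)
    o <- order(ivs[, 1])
    expect_true(all(ivs[o, 1][-1] <= ivs[o, 2][-nrow(ivs)]))  # no holes
    expect_equal(nchar(ch$seq[o][1]), min(chunk, len))
  }
})

test_that("greedy assembly reconstructs a tiled sequence exactly", {
  set.seed(5)
  truth <- random_seq(20000)
  starts <- seq(1, 20000 - 4000 + 1, by = 2000)   # 4 kb reads, 2 kb overlap
  reads <- seq_records(sprintf("r%02d", seq_along(starts)),
                       substring(truth, starts, starts + 3999))
  out <- greedy_overlap_assemble(reads, min_overlap = 1000)
  expect_equal(nrow(out), 1)
  expect_equal(out$seq, truth)

  # no sufficient overlap: inputs pass through
  two <- seq_records(c("a", "b"), c(random_seq(3000), random_seq(3000)))
  out2 <- greedy_overlap_assemble(two, min_overlap = 1000)
  expect_setequal(out2$seq, two$seq)

  # strand symmetry: a reverse-complemented read changes nothing material
  reads_rc <- reads
  reads_rc$seq[3] <- revcomp(reads_rc$seq[3])
  out3 <- greedy_overlap_assemble(reads_rc, min_overlap = 1000)
  expect_equal(nrow(out3), 1)
  expect_true(out3$seq == truth || out3$seq == revcomp(truth))
})

test_that("greedy assembly equals exhaustive overlap search on small instances", {
  set.seed(606)
  for (case in 1:50) {
    n_frag <- sample(4:12, 1)
    parent <- random_seq(sample(1500:2500, 1))
    L <- nchar(parent)
    # random tiling with overlaps >= 60
    cuts <- sort(sample(100:(L - 100), n_frag - 1))
    cuts <- cuts[c(TRUE, diff(cuts) > 120)]
    starts <- c(1, pmax(1, cuts - sample(60:119, length(cuts), replace = TRUE)))
    ends <- c(cuts + 60, L)
    recs <- seq_records(sprintf("f%02d", seq_along(starts)),
                        substring(parent, starts, ends))
    # flip some fragments; sometimes add an unrelated singleton
    flip <- runif(nrow(recs)) < 0.4
    recs$seq[flip] <- revcomp(recs$seq[flip])
    if (runif(1) < 0.3) {
      recs <- dplyr::bind_rows(recs, seq_records("lone", random_seq(500)))
    }
    got <- greedy_overlap_assemble(recs, min_overlap = 50, kmer = 11)
    want <- oracle_assemble(recs, min_overlap = 50)
    expect_equal(canonical_set(got$seq), canonical_set(want))
  }
})

test_that("stitch_gap accepts exact junctions and enforces thresholds", {
  set.seed(61)
  junction <- random_seq(2000)
  left <- seq_records("L", paste0(random_seq(5000), junction))
  right <- seq_records("R", paste0(junction, random_seq(5000)))
  m <- stitch_gap(left, right, min_overlap = 1000)
  expect_equal(m$overlap_length, 2000)
  expect_equal(m$identity, 1.0)
  expect_equal(m$merged_length, 7000 + 7000 - 2000)
  expect_equal(m$merged_seq, paste0(left$seq, substr(right$seq, 2001, 7000)))

  # junction below min_overlap: no merge
  short_j <- random_seq(500)
  l2 <- seq_records("L", paste0(random_seq(5000), short_j))
  r2 <- seq_records("R", paste0(short_j, random_seq(5000)))
  expect_null(stitch_gap(l2, r2, min_overlap = 1000))

  # 10% mismatches: identity 0.90 < 0.95 rejected
  mut <- strsplit(junction, "")[[1]]
  at <- sample(2000, 200)
  mut[at] <- vapply(mut[at],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    "")
  r3 <- seq_records("R", paste0(paste(mut, collapse = ""), random_seq(5000)))
  expect_null(stitch_gap(left, r3, min_overlap = 1000, min_identity = 0.95))
  # ... but accepted at a matching threshold, with the identity reported
  m3 <- stitch_gap(left, r3, min_overlap = 1000, min_identity = 0.85)
  expect_equal(m3$overlap_length, 2000)
  expect_equal(m3$identity, 0.90, tolerance = 0.01)
  expect_equal(m3$merged_length,
               nchar(left$seq) + nchar(r3$seq) - m3$overlap_length)
})

test_that("close_gaps stitches overlapping flanks and is idempotent", {
  set.seed(62)
  chrom <- random_seq(30000)
  left <- substr(chrom, 1, 12000)
  right <- substr(chrom, 10001, 30000)   # 2000 bp true overlap
  contigs <- seq_records(c("c1", "c2"), c(left, right))
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:3, type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), orientation = c("+", NA, "+"),
    length = c(12000, 100, 20000)))
  res <- close_gaps(plan, contigs)
  expect_equal(res$report$outcome, "stitched")
  expect_equal(glance(res$plan)$n_gaps, 0)
  expect_equal(glance(res$plan)$n_components, 1)
  out <- plan_to_sequences(res$plan, res$contigs)
  expect_equal(out$seq, chrom)
  # scaffold shrank by planned gap + overlap
  expect_equal(glance(plan)$total_length - glance(res$plan)$total_length,
               100 + 2000)

  res2 <- close_gaps(res$plan, res$contigs)
  expect_equal(nrow(res2$report), 0)
  expect_equal(as.data.frame(res2$plan), as.data.frame(res$plan))
})

test_that("close_gaps leaves unclosable plans unchanged", {
  contigs <- seq_records(c("c1", "c2"),
                         c(random_seq(5000), random_seq(5000)))
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:3, type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), orientation = c("+", NA, "+"),
    length = c(5000, 500, 5000)))
  res <- close_gaps(plan, contigs)
  expect_equal(res$report$outcome, "open")
  expect_equal(as.data.frame(res$plan), as.data.frame(plan))
  expect_identical(plan_to_sequences(res$plan, res$contigs)$seq,
                   plan_to_sequences(plan, contigs)$seq)
})

test_that("an error-free patch spanning both flanks closes the gap exactly", {
  set.seed(63)
  chrom <- random_seq(40000)
  contigs <- seq_records(c("c1", "c2"),
                         c(substr(chrom, 1, 15000),
                           substr(chrom, 23001, 40000)))
  plan <- scaffold_plan(tibble::tibble(
    scaffold_id = "s1", part_number = 1:3, type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), orientation = c("+", NA, "+"),
    length = c(15000, 8000, 17000)))
  patch <- seq_records("p1", substr(chrom, 10001, 28000))  # 5 kb into each
  res <- close_gaps(plan, contigs, patches = patch)
  expect_equal(res$report$outcome, "patched")
  expect_equal(res$report$overlap_left, 5000)
  expect_equal(res$report$overlap_right, 5000)
  expect_equal(res$report$inserted_bases, 8000)
  expect_equal(plan_to_sequences(res$plan, res$contigs)$seq, chrom)

  # reverse-complemented patch works the same
  res_rc <- close_gaps(plan, contigs,
                       patches = seq_records("p1", revcomp(patch$seq)))
  expect_equal(res_rc$report$outcome, "patched")
  expect_equal(plan_to_sequences(res_rc$plan, res_rc$contigs)$seq, chrom)
})
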