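cov_paf <- function(intervals, contig = "c1", len = 10, mapq = 60) {
  dplyr::bind_rows(lapply(intervals, function(iv) {
    paf_row(query_name = "r", query_length = 100, query_start = 0,
            query_end = iv[2] - iv[1], target_name = contig,
            target_length = len, target_start = iv[1], target_end = iv[2],
            mapq = mapq)
  }))
}

depth_vector <- function(profile) {
  unlist(purrr::pmap(profile, function(start, end, depth, ...) {
    rep(depth, end - start)
  }))
}

test_that("coverage depth equals the number of covering alignments", {
  prof <- coverage_from_alignments(cov_paf(list(c(0, 4), c(6, 10))),
                                   c(c1 = 10))
  expect_equal(depth_vector(prof), c(1, 1, 1, 1, 0, 0, 1, 1, 1, 1))

  prof2 <- coverage_from_alignments(cov_paf(list(c(0, 6), c(4, 10))),
                                    c(c1 = 10))
  expect_equal(depth_vector(prof2), c(1, 1, 1, 1, 2, 2, 1, 1, 1, 1))

  prof3 <- coverage_from_alignments(cov_paf(list(c(0, 10)), mapq = 0),
                                    c(c1 = 10), min_mapq = 10)
  expect_equal(depth_vector(prof3), rep(0, 10))
})

test_that("coverage rejects unknown contigs and overlong alignments", {
  expect_error(coverage_from_alignments(cov_paf(list(c(0, 4))), c(cX = 10)),
               "unknown contig")
  expect_error(coverage_from_alignments(cov_paf(list(c(0, 9)), len = 9),
                                        c(c1 = 8)), "beyond declared length")
})

test_that("raising min_mapq never increases depth anywhere", {
  set.seed(91)
  aln <- dplyr::bind_rows(lapply(1:60, function(i) {
    s <- sample(0:900, 1)
    cov_paf(list(c(s, s + sample(10:100, 1))), len = 1000,
            mapq = sample(0:60, 1))
  }))
  prev <- depth_vector(coverage_from_alignments(aln, c(c1 = 1000), 0))
  for (mq in c(10, 30, 50, 60)) {
    cur <- depth_vector(coverage_from_alignments(aln, c(c1 = 1000), mq))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("read end pairs take 500 bp from each end, forward-stranded", {
  reads <- seq_records(c("r1", "r2", "r3"),
                       c(random_seq(1000), random_seq(999), random_seq(10000)))
  pairs <- make_read_end_pairs(reads, end_length = 500)
  expect_equal(attr(pairs, "n_skipped"), 1)   # r2 is below 2 x end_length
  expect_equal(pairs$id, c("r1/1", "r1/2", "r3/1", "r3/2"))
  expect_equal(pairs$seq[1], substr(reads$seq[1], 1, 500))
  expect_equal(pairs$seq[2], substr(reads$seq[1], 501, 1000))
  expect_equal(pairs$seq[3], substr(reads$seq[3], 1, 500))
  expect_equal(pairs$seq[4], substr(reads$seq[3], 9501, 10000))
  expect_match(pairs$desc[4], "9500-10000")
})

test_that("zero-coverage splits fall at run midpoints; end runs become trims", {
  prof <- coverage_from_alignments(cov_paf(list(c(0, 4), c(6, 10))),
                                   c(c1 = 10))
  sp <- find_zero_coverage_splits(prof)
  expect_equal(sp$position, 5)
  expect_equal(sp$reason, "zero_coverage")

  prof_end <- coverage_from_alignments(cov_paf(list(c(2, 10))), c(c1 = 10))
  sp_end <- find_zero_coverage_splits(prof_end)
  expect_equal(nrow(sp_end), 0)
  expect_equal(attr(sp_end, "trims")$start, 0)
  expect_equal(attr(sp_end, "trims")$end, 2)

  full <- coverage_from_alignments(cov_paf(list(c(0, 10))), c(c1 = 10))
  expect_equal(nrow(find_zero_coverage_splits(full)), 0)
})

test_that("min_zero_run suppresses short internal zero runs", {
  prof <- coverage_from_alignments(cov_paf(list(c(0, 4), c(6, 10))),
                                   c(c1 = 10))
  expect_equal(nrow(find_zero_coverage_splits(prof, min_zero_run = 3)), 0)
})

test_that("combine_coverage sums depth position-wise", {
  a <- coverage_from_alignments(cov_paf(list(c(0, 6))), c(c1 = 10))
  b <- coverage_from_alignments(cov_paf(list(c(4, 10))), c(c1 = 10))
  expect_equal(depth_vector(combine_coverage(a, b)),
               c(1, 1, 1, 1, 2, 2, 1, 1, 1, 1))
})

test_that("planted uncovered intervals each yield exactly one split", {
  set.seed(17)
  for (rep in 1:20) {
    len <- 100000
    gap_start <- sample(20000:70000, 1)
    gap_len <- sample(500:5000, 1)
    starts <- seq(0, len - 1000, by = 400)
    keep <- starts + 1000 <= gap_start | starts >= gap_start + gap_len
    aln <- cov_paf(lapply(starts[keep], function(s) c(s, s + 1000)),
                   len = len)
    prof <- coverage_from_alignments(aln, c(c1 = len))
    sp <- find_zero_coverage_splits(prof)
    inside <- sp$position > gap_start & sp$position < gap_start + gap_len
    expect_equal(sum(inside), 1)
    expect_equal(nrow(sp), 1)
  }
})

test_that("partial-mapping rescue uses a strict 10% threshold", {
  lens <- c(r1 = 10000, r2 = 10000, r3 = 10000)
  aln <- dplyr::bind_rows(
    paf_row(query_name = "r1", query_length = 10000, query_start = 100,
            query_end = 1000),                     # union 900 -> 0.09
    paf_row(query_name = "r2", query_length = 10000, query_start = 0,
            query_end = 600),
    paf_row(query_name = "r2", query_length = 10000, query_start = 400,
            query_end = 1000))                     # union 1000 -> 0.10
  cls <- classify_partially_mapped_reads(aln, lens)
  expect_true(cls$rescued[cls$read_id == "r1"])    # 0.09 < 0.10
  expect_false(cls$rescued[cls$read_id == "r2"])   # 0.10 is not < 0.10
  expect_true(cls$rescued[cls$read_id == "r3"])    # unmapped
  expect_error(classify_partially_mapped_reads(aln, lens[c("r1", "r3")]),
               "unknown read")
})

test_that("reconciliation splits at internal coverage gaps above tolerance", {
  mk <- function(ivs) {
    dplyr::bind_rows(lapply(seq_along(ivs), function(k) {
      paf_row(query_name = "a1", query_length = 100000,
              query_start = ivs[[k]][1], query_end = ivs[[k]][2],
              target_name = paste0("b", k), target_length = 200000)
    }))
  }
  sp <- reconcile_assemblies(mk(list(c(0, 40000), c(60000, 100000))),
                             c(a1 = 100000), coverage_tolerance = 100)
  expect_equal(sp$position, 50000)
  expect_equal(sp$reason, "reconciliation")

  # gap of 50 <= tolerance: continuous
  sp2 <- reconcile_assemblies(mk(list(c(0, 50000), c(50050, 100000))),
                              c(a1 = 100000), coverage_tolerance = 100)
  expect_equal(nrow(sp2), 0)

  # abutting alignments to two different partner contigs: no split
  sp3 <- reconcile_assemblies(mk(list(c(0, 50000), c(50000, 100000))),
                              c(a1 = 100000))
  expect_equal(nrow(sp3), 0)
})

test_that("raising the tolerance never increases reconciliation splits", {
  set.seed(23)
  aln <- dplyr::bind_rows(lapply(1:30, function(k) {
    s <- sample(0:90000, 1)
    paf_row(query_name = "a1", query_length = 100000, query_start = s,
            query_end = s + sample(2000:9000, 1), target_length = 300000)
  }))
  prev <- Inf
  for (tol in c(10, 100, 1000, 10000)) {
    cur <- nrow(reconcile_assemblies(aln, c(a1 = 100000), tol))
    expect_true(cur <= prev)
    prev <- cur
  }
})

test_that("apply_splits cuts at positions and conserves every base", {
  contigs <- seq_records("c1", random_seq(10))
  out <- apply_splits(contigs, tibble::tibble(contig_id = "c1", position = 5))
  expect_equal(out$length, c(5, 5))
  expect_equal(paste0(out$seq, collapse = ""), contigs$seq)

  out2 <- apply_splits(contigs, tibble::tibble(contig_id = character(),
                                               position = numeric()))
  expect_equal(out2$seq, contigs$seq)
  expect_equal(out2$id, contigs$id)

  out3 <- apply_splits(contigs, tibble::tibble(contig_id = "c1",
                                               position = c(3, 7)))
  expect_equal(out3$length, c(3, 4, 3))
  expect_equal(out3$id, c("c1.1", "c1.2", "c1.3"))

  expect_error(apply_splits(contigs, tibble::tibble(contig_id = "c1",
                                                    position = 0)),
               "outside")
  expect_error(apply_splits(contigs, tibble::tibble(contig_id = "c9",
                                                    position = 5)),
               "unknown contig")
})

test_that("apply_splits conserves bases on random fixtures", {
  set.seed(301)
  for (rep in 1:500) {
    len <- sample(10:500, 1)
    contigs <- seq_records("c", random_seq(len))
    k <- sample(0:4, 1)
    pos <- sort(sample(seq_len(len - 1), min(k, len - 1)))
    out <- apply_splits(contigs, tibble::tibble(
      contig_id = rep("c", length(pos)), position = pos))
    expect_identical(paste0(out$seq, collapse = ""), contigs$seq)
  }
})

test_that("curate_contigs combines evidence and reports counts", {
  len <- 100000
  contigs <- seq_records("c1", random_seq(len))
  starts <- seq(0, len - 1000, by = 500)
  keep <- starts + 1000 <= 40000 | starts >= 43000
  reads_paf <- cov_paf(lapply(starts[keep], function(s) c(s, s + 1000)),
                       len = len)
  reads_paf$query_name <- paste0("r", seq_len(nrow(reads_paf)))
  res <- curate_contigs(contigs, reads_paf)
  expect_equal(nrow(res$contigs), 2)
  expect_equal(res$counts$n_zero_coverage_splits, 1)
  expect_equal(sum(res$contigs$length), len)
})
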