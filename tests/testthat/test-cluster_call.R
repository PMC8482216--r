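no_feats <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       feature_class = character(0), gene_id = character(0),
                       name = character(0), stringsAsFactors = FALSE)

test_that("pileup matches a positional counting oracle", {
  region <- list(contig = "chr1", start = 100L, end = 400L)
  expect_equal(pileup(empty_reads_fixture(), region), integer(300))

  reads <- make_reads(starts = rep(list(100L), 20), ends = rep(list(160L), 20))
  d <- pileup(reads, region)
  expect_equal(d[1:60], rep(20L, 60))
  expect_equal(d[61:300], rep(0L, 240))

  set.seed(8)
  rs <- as.integer(sample(0:450, 500, TRUE))
  reads <- make_reads(starts = as.list(rs),
                      ends = as.list(rs + as.integer(sample(20:80, 500, TRUE))))
  expect_equal(pileup(reads, region), oracle_pileup(reads, region))
})

test_that("the 20-read rule is a sharp boundary", {
  feats <- no_feats
  r19 <- make_reads(starts = rep(list(100L), 19), ends = rep(list(160L), 19))
  r20 <- make_reads(starts = rep(list(100L), 20), ends = rep(list(160L), 20))
  expect_equal(nrow(call_clusters(r19, iR_labels(r19), feats)), 0)
  out <- call_clusters(r20, iR_labels(r20), feats)
  expect_equal(nrow(out), 1)
  expect_equal(out$read_count, 20L)
  expect_equal(c(out$start, out$end), c(100L, 160L))
  expect_equal(out$max_depth, 20L)
})

test_that("reads with labels other than iR/IR are rejected", {
  r <- make_reads(starts = list(0), ends = list(60))
  lab <- data.frame(read_id = "r1", label = "ER", stringsAsFactors = FALSE)
  expect_error(call_clusters(r, lab, no_feats), "iR/IR")
})

test_that("cluster calling matches the O(n^2) brute-force oracle on random read sets", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(40:90, 1)
    rs <- as.integer(sample(0:3000, n, TRUE))
    reads <- make_reads(starts = as.list(rs),
                        ends = as.list(rs + as.integer(sample(40:120, n, TRUE))))
    min_reads <- sample(2:6, 1)
    got <- call_clusters(reads, iR_labels(reads), no_feats,
                         min_reads = min_reads, min_length = 1,
                         refine_frac = 0)
    want <- oracle_clusters(reads, min_reads = min_reads)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
    expect_equal(got$read_count, as.integer(want$read_count))
  }
})

test_that("merge_gap bridges short uncovered runs", {
  reads <- make_reads(starts = as.list(c(rep(100, 10), rep(165, 10))),
                      ends = as.list(c(rep(160, 10), rep(225, 10))))
  split2 <- call_clusters(reads, iR_labels(reads), no_feats, min_reads = 5,
                          merge_gap = 0, refine_frac = 0)
  merged <- call_clusters(reads, iR_labels(reads), no_feats, min_reads = 5,
                          merge_gap = 5, refine_frac = 0)
  expect_equal(nrow(split2), 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$read_count, 20L)
})

test_that("kept and discarded clusters respect the threshold exhaustively", {
  set.seed(4)
  rs <- as.integer(sample(0:2000, 120, TRUE))
  reads <- make_reads(starts = as.list(rs),
                      ends = as.list(rs + 60L))
  got <- call_clusters(reads, iR_labels(reads), no_feats, min_reads = 10,
                       min_length = 1, refine_frac = 0)
  expect_true(all(got$read_count >= 10))
  all_runs <- oracle_clusters(reads, min_reads = 1)
  dropped <- all_runs[!(all_runs$start %in% got$start), , drop = FALSE]
  expect_true(all(dropped$read_count < 10))
  # no two candidates overlap
  if (nrow(got) > 1)
    expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
})

test_that("context is intronic only when the cluster lies inside an intron", {
  feats <- data.frame(contig = "chr1", start = 50L, end = 500L, strand = "+",
                      feature_class = "iR", gene_id = "g1", name = "t1",
                      stringsAsFactors = FALSE)
  inside <- make_reads(starts = rep(list(100L), 20), ends = rep(list(160L), 20))
  lab_iR <- data.frame(read_id = inside$read_id, label = "iR",
                       stringsAsFactors = FALSE)
  expect_equal(call_clusters(inside, lab_iR, feats)$context, "intronic")
  outside <- make_reads(starts = rep(list(600L), 20), ends = rep(list(660L), 20))
  expect_equal(call_clusters(outside, iR_labels(outside), feats)$context,
               "intergenic")
})

test_that("boundary refinement trims ragged ends to the half-peak core", {
  # 30 reads at the mature boundary plus 10 overhanging by 5 nt
  reads <- make_reads(starts = as.list(c(rep(100, 30), rep(95, 10))),
                      ends = as.list(c(rep(160, 30), rep(165, 10))))
  out <- call_clusters(reads, iR_labels(reads), no_feats, min_reads = 20)
  expect_equal(c(out$start, out$end), c(100L, 160L))
  expect_equal(c(out$raw_start, out$raw_end), c(95L, 165L))
})

test_that("sequence extraction honours strand and T->U normalisation", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTAAGGTT"))
  plus <- data.frame(candidate_id = "c1", contig = "chr1", start = 0L,
                     end = 4L, strand = "+", stringsAsFactors = FALSE)
  minus <- plus; minus$strand <- "-"
  expect_equal(extract_sequences(plus, genome)$sequence, "ACGU")
  expect_equal(extract_sequences(minus, genome)$sequence,
               chartr("T", "U", "ACGT"))  # revcomp of ACGT is ACGT
  tail_cand <- data.frame(candidate_id = "c2", contig = "chr1", start = 6L,
                          end = 10L, strand = "+", stringsAsFactors = FALSE)
  expect_equal(nchar(extract_sequences(tail_cand, genome)$sequence), 4L)
  oob <- data.frame(candidate_id = "c3", contig = "chr1", start = 6L,
                    end = 11L, strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_sequences(oob, genome), "c3")
})

test_that("size statistics match a sort-based oracle", {
  one <- data.frame(start = 0L, end = 100L)
  expect_equal(size_statistics(one),
               list(mean = 100, median = 100, min = 100, max = 100))
  printed <- data.frame(start = c(0L, 0L, 0L), end = c(52L, 126L, 772L))
  st <- size_statistics(printed)
  expect_equal(st$min, 52); expect_equal(st$max, 772)
  expect_equal(st$median, 126)
  set.seed(2)
  lens <- sample(50:800, 1001, TRUE)
  many <- data.frame(start = 0L, end = as.integer(lens))
  st <- size_statistics(many)
  sorted <- sort(lens)
  expect_equal(st$min, sorted[1]); expect_equal(st$max, sorted[1001])
  expect_equal(st$median, sorted[501])
  expect_equal(st$mean, sum(lens) / 1001)
  expect_error(size_statistics(many[0, ]), "no candidates")
})
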