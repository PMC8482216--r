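tu_fixture <- function(junction_support = 5) {
  # two-exon TU: exons [1000,1200) and [2000,2200), intron hosting the
  # candidate at [1500,1630)
  cov1 <- seq(1000, 1100, by = 25)
  cov2 <- seq(2000, 2100, by = 25)
  exonic <- make_reads(starts = as.list(c(cov1, cov2)),
                       ends = as.list(c(cov1 + 100, cov2 + 100)),
                       read_id = sprintf("cov%d", seq_along(c(cov1, cov2))))
  spliced <- do.call(rbind, lapply(seq_len(junction_support), function(i)
    make_spliced_read(c(1150, 2000), c(1200, 2050),
                      read_id = sprintf("sp%d", i))))
  rbind(exonic, spliced)
}

cand_fixture <- function(context = "intergenic") {
  data.frame(candidate_id = "cand_9", contig = "chr1", start = 1500L,
             end = 1630L, strand = "+", context = context,
             stringsAsFactors = FALSE)
}

test_that("junction extraction aggregates inter-block gaps with support filtering", {
  unspliced <- make_reads(starts = list(0, 100), ends = list(50, 180))
  expect_equal(nrow(extract_junctions(unspliced)), 0)

  three <- do.call(rbind, lapply(1:3, function(i)
    make_spliced_read(c(100, 330), c(130, 370), read_id = sprintf("s%d", i))))
  j <- extract_junctions(three, min_support = 1)
  expect_equal(nrow(j), 1)
  expect_equal(j$donor, 130L)
  expect_equal(j$acceptor, 330L)
  expect_equal(j$support, 3L)

  expect_equal(nrow(extract_junctions(three[1, , drop = FALSE],
                                      min_support = 2)), 0)
})

test_that("junction aggregation equals a plain counting oracle on random reads", {
  set.seed(51)
  reads <- do.call(rbind, lapply(1:120, function(i) {
    d <- sample(c(200, 500, 800), 1)
    a <- d + sample(c(100, 300), 1)
    make_spliced_read(c(d - 50, a), c(d, a + 50),
                      read_id = sprintf("s%d", i))
  }))
  got <- extract_junctions(reads, min_support = 1)
  key <- vapply(seq_len(nrow(reads)), function(i)
    paste(reads$ends[[i]][1], reads$starts[[i]][2]), character(1))
  want <- table(key)
  expect_equal(nrow(got), length(want))
  for (r in seq_len(nrow(got))) {
    k <- paste(got$donor[r], got$acceptor[r])
    expect_equal(got$support[r], as.integer(want[[k]]))
  }
})

test_that("a planted two-exon TU is reconstructed with exact junction edges", {
  reads <- tu_fixture()
  jx <- extract_junctions(reads, min_support = 2)
  tu <- assemble_tu(cand_fixture(), jx, reads)
  expect_s3_class(tu, "transcriptional_unit")
  expect_equal(nrow(tu$exons), 2)
  expect_equal(tu$exons$start, c(1000L, 2000L))
  expect_equal(tu$exons$end, c(1200L, 2200L))
  expect_equal(tu$hosting_intron_index, 0L)
  expect_equal(tu$min_junction_support, 5L)
  expect_true(all(tu$exons$soft_edge))  # outer edges are coverage-defined
})

test_that("no containing junction within the window yields no TU", {
  reads <- tu_fixture()
  jx <- extract_junctions(reads, min_support = 2)
  far <- cand_fixture(); far$start <- 50000L; far$end <- 50100L
  expect_null(assemble_tu(far, jx, reads))
  # junction present but intron does not contain the candidate
  beside <- cand_fixture(); beside$start <- 2050L; beside$end <- 2120L
  expect_null(assemble_tu(beside, jx, reads))
  expect_error(assemble_tu(cand_fixture(context = "intronic"), jx, reads),
               "intergenic")
})

test_that("chains extend through compatible junctions to three exons", {
  # exons [1000,1200), [2000,2200), [3000,3200); candidate in second intron
  cov <- c(seq(1000, 1100, 25), seq(2000, 2100, 25), seq(3000, 3100, 25))
  exonic <- make_reads(starts = as.list(cov), ends = as.list(cov + 100),
                       read_id = sprintf("cov%d", seq_along(cov)))
  spl <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      make_spliced_read(c(1150, 2000), c(1200, 2050),
                        read_id = sprintf("j1_%d", i)))),
    do.call(rbind, lapply(1:3, function(i)
      make_spliced_read(c(2150, 3000), c(2200, 3050),
                        read_id = sprintf("j2_%d", i)))))
  reads <- rbind(exonic, spl)
  jx <- extract_junctions(reads, min_support = 2)
  cand <- cand_fixture(); cand$start <- 2500L; cand$end <- 2600L
  tu <- assemble_tu(cand, jx, reads)
  expect_equal(nrow(tu$exons), 3)
  expect_equal(tu$exons$start, c(1000L, 2000L, 3000L))
  expect_equal(tu$exons$end, c(1200L, 2200L, 3200L))
  expect_equal(tu$hosting_intron_index, 1L)  # hosted in the second intron
  expect_equal(tu$min_junction_support, 3L)
  expect_equal(tu$exons$soft_edge, c(TRUE, FALSE, TRUE))
})

test_that("small junction graphs match a brute-force chain enumeration", {
  reads <- tu_fixture()
  jx <- extract_junctions(reads, min_support = 1)
  # brute force over all single containing junctions: best by support,
  # then smallest intron; exons are the covered runs at its flanks
  cand <- cand_fixture()
  containing <- jx[jx$donor < cand$start & jx$acceptor > cand$end, ]
  best <- containing[order(-containing$support,
                           containing$acceptor - containing$donor), ][1, ]
  tu <- assemble_tu(cand, jx, reads)
  expect_equal(tu$exons$end[1], best$donor)
  expect_equal(tu$exons$start[2], best$acceptor)
})

test_that("TU output satisfies its structural invariants and is deterministic", {
  reads <- tu_fixture()
  jx <- extract_junctions(reads, min_support = 2)
  t1 <- assemble_tu(cand_fixture(), jx, reads)
  t2 <- assemble_tu(cand_fixture(), jx, reads)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$exons$start) > 0))
  expect_true(all(t1$exons$end > t1$exons$start))
  i <- t1$hosting_intron_index + 1
  expect_true(t1$exons$end[i] < cand_fixture()$start)
  expect_true(t1$exons$start[i + 1] > cand_fixture()$end)
})

test_that("intergenic reclassification conserves candidate counts", {
  cands <- data.frame(candidate_id = sprintf("c%d", 1:10),
                      context = rep(c("intergenic", "intronic"), 5),
                      stringsAsFactors = FALSE)
  tus <- list(c1 = structure(list(), class = "transcriptional_unit"),
              c3 = NULL, c5 = NULL, c7 = NULL, c9 = NULL)
  out <- classify_intergenic(cands, tus)
  expect_equal(nrow(out), 5)  # one row per intergenic candidate
  expect_equal(out$status[out$candidate_id == "c1"], "intron_hosted_novel_TU")
  expect_equal(sum(out$status == "autonomous_or_unknown"), 4)
  expect_equal(sort(out$candidate_id),
               sort(cands$candidate_id[cands$context == "intergenic"]))
})

test_that("TU GFF3 export writes 1-based closed coordinates", {
  reads <- tu_fixture()
  jx <- extract_junctions(reads, min_support = 2)
  tu <- assemble_tu(cand_fixture(), jx, reads)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_tu_gff3(list(tu), f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  gene <- strsplit(lines[2], "\t")[[1]]
  expect_equal(gene[3], "gene")
  expect_equal(as.integer(gene[4]), 1001L)
  expect_equal(as.integer(gene[5]), 2200L)
  exon1 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(as.integer(exon1[4]), 1001L)
  expect_equal(as.integer(exon1[5]), 1200L)
})
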