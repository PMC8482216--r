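test_that("genome generation is byte-deterministic given the seed", {
  cfg <- sim_config(seed = 1, n_cd = 3, n_haca = 3, n_sca = 3, n_decoys = 2,
                    n_tu_hosted = 1, n_genes = 6, genome_length = 120000)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_genome(cfg, dir = d1)
  generate_genome(cfg, dir = d2)
  for (f in c("genome.fa", "annotation.gff3", "truth.tsv", "tu_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("truth table honours the configured class counts and invariants", {
  cfg <- sim_config(seed = 2, n_cd = 5, n_haca = 4, n_sca = 3, n_decoys = 2,
                    n_tu_hosted = 1, n_genes = 6, genome_length = 120000)
  g <- generate_genome(cfg)
  tr <- g$truth[!g$truth$is_decoy, ]
  expect_equal(sum(tr$sno_class == "CD"), 5)
  expect_equal(sum(tr$sno_class == "HACA"), 4)
  expect_equal(sum(tr$sno_class == "SCA"), 3)
  expect_equal(sum(g$truth$is_decoy), 2)

  # C/D box invariants by construction
  for (s in tr$sequence[tr$sno_class == "CD"]) {
    n <- nchar(s)
    expect_gte(length(oracle_scan_positions(s, "RUGAUGA")[[1]]), 1)
    d_pos <- oracle_scan_positions(s, "CUGA")[[1]]
    expect_true(any(d_pos >= n - 10))  # D box within the last 10 nt
  }
  # H/ACA: independent regex oracle for ANANNA and the 3' ACA
  haca <- tr$sequence[tr$sno_class %in% c("HACA", "SCA")]
  h_ok <- vapply(haca, function(s)
    length(oracle_scan_positions(s, "ANANNA")[[1]]) >= 1, logical(1))
  aca_ok <- vapply(haca, function(s)
    substr(s, nchar(s) - 5, nchar(s) - 3) == "ACA", logical(1))
  expect_true(all(h_ok))
  expect_true(all(aca_ok))
  # scaRNAs carry the CAB consensus, plain H/ACA must not
  expect_true(all(grepl("UGAG", tr$sequence[tr$sno_class == "SCA"])))
  expect_false(any(grepl("UGAG", tr$sequence[tr$sno_class == "HACA"])))
})

test_that("planted loci sit where the placement rules demand", {
  cfg <- sim_config(seed = 3)
  g <- generate_genome(cfg)
  introns <- g$features[g$features$feature_class == "iR", ]
  for (i in which(g$truth$context == "intronic")) {
    row <- g$truth[i, ]
    inside <- introns$start + 30 <= row$start & row$end <= introns$end - 30 &
      introns$gene_id == row$host_gene_id
    expect_true(any(inside), info = row$locus_id)
  }
  for (i in which(g$truth$context == "intergenic")) {
    row <- g$truth[i, ]
    dist <- pmax(g$genes$start - row$end, row$start - g$genes$end)
    expect_true(all(dist >= 1000), info = row$locus_id)
  }
  # genome sequence at each locus matches the truth sequence
  for (i in sample(nrow(g$truth), 5)) {
    row <- g$truth[i, ]
    got <- extract_sequences(data.frame(candidate_id = row$locus_id,
                                        contig = row$contig,
                                        start = row$start, end = row$end,
                                        strand = row$strand,
                                        stringsAsFactors = FALSE),
                             g$genome)$sequence
    expect_equal(got, row$sequence)
  }
})

test_that("impossible placements raise configuration errors", {
  expect_error(generate_genome(sim_config(genome_length = 10000)),
               "genome_length")
  expect_error(generate_genome(sim_config(n_genes = 1, n_cd = 40)),
               "placement impossible")
})

test_that("simulated depths respect the threshold construction", {
  cfg <- sim_config(seed = 4)
  g <- generate_genome(cfg)
  reads <- simulate_reads(g$truth, cfg)
  cnt <- table(sub("_r\\d+$", "", reads$read_id))
  planted <- g$truth$locus_id[!g$truth$is_decoy]
  decoys <- g$truth$locus_id[g$truth$is_decoy]
  expect_true(all(cnt[planted] >= 20))
  expect_true(all(cnt[decoys] < 20))
  expect_true(all(cnt[decoys] >= 1))
  # every read's blocks lie inside the genome
  expect_true(all(vapply(reads$starts, min, numeric(1)) >= 0))
  expect_true(all(vapply(reads$ends, max, numeric(1)) <= cfg$genome_length))
  # every planted locus is overlapped by at least one read
  for (i in seq_len(nrow(g$truth))) {
    row <- g$truth[i, ]
    rs <- reads[startsWith(reads$read_id, paste0(row$locus_id, "_")), ]
    ov <- vapply(seq_len(nrow(rs)), function(k)
      rs$starts[[k]] < row$end && rs$ends[[k]] > row$start, logical(1))
    expect_true(all(ov), info = row$locus_id)
  }
})

test_that("zero depth with zero dispersion yields no locus reads", {
  cfg <- sim_config(seed = 5, reads_per_locus = 0, dispersion = 0,
                    n_decoys = 0, background_per_exon = 0)
  g <- generate_genome(cfg)
  reads <- simulate_reads(g$truth, cfg)
  expect_equal(nrow(reads), 0)
})

test_that("mean simulated read length matches the clipped-jitter expectation", {
  cfg <- sim_config(seed = 6, n_cd = 1, n_haca = 0, n_sca = 0, n_decoys = 0,
                    n_tu_hosted = 0, frac_intergenic = 0,
                    reads_per_locus = 10000, dispersion = 0,
                    background_per_exon = 0)
  g <- generate_genome(cfg)
  reads <- simulate_reads(g$truth, cfg)
  expect_gte(nrow(reads), 10000)
  lens <- vapply(seq_len(nrow(reads)), function(i)
    sum(reads$ends[[i]] - reads$starts[[i]]), numeric(1))
  # closed-form expectation by enumerating the (start, end) jitter grid
  L <- g$truth$end[1] - g$truth$start[1]
  J <- cfg$jitter
  grid <- expand.grid(js = -J:J, je = -J:J)
  clip <- function(js, je) {
    len <- L + je - js
    min(max(len, cfg$insert_size_range[1]), cfg$insert_size_range[2])
  }
  expected <- mean(mapply(clip, grid$js, grid$je))
  expect_lt(abs(mean(lens) - expected), 2)
})

test_that("expression simulation hits degenerate and stochastic targets", {
  pairs <- data.frame(candidate_id = "c1", host_gene_id = "g1",
                      stringsAsFactors = FALSE)
  sim <- simulate_expression(pairs, 1, 10, seed = 1)
  expect_equal(unname(stats::cor(log(sim$candidate_counts[1, ] + 1),
                                 log(sim$host_counts[1, ] + 1))), 1.0)
  expect_error(simulate_expression(pairs, 1.5, 10, seed = 1), "r_target")
  expect_error(simulate_expression(pairs, 0.5, 2, seed = 1), "n_samples")

  # determinism
  s1 <- simulate_expression(pairs, 0.4, 8, seed = 9)
  s2 <- simulate_expression(pairs, 0.4, 8, seed = 9)
  expect_identical(s1, s2)

  # r = 0: mean sample correlation near zero over many replicates
  m <- vapply(1:1000, function(s) {
    sim <- simulate_expression(pairs, 0, 10, seed = s)
    suppressWarnings(pearson(sim$candidate_counts[1, ], sim$host_counts[1, ]))
  }, numeric(1))
  expect_lt(abs(mean(m, na.rm = TRUE)), 0.02)

  # r = 0.9 recovered within 0.05
  m9 <- vapply(1:500, function(s) {
    sim <- simulate_expression(pairs, 0.9, 12, seed = s)
    pearson(sim$candidate_counts[1, ], sim$host_counts[1, ])
  }, numeric(1))
  expect_lt(abs(mean(m9) - 0.9), 0.05)
})

test_that("planted truth classes are recoverable by the motif oracle at 100%", {
  cfg <- sim_config(seed = 7)
  g <- generate_genome(cfg)
  tr <- g$truth[!g$truth$is_decoy, ]
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    s <- tr$sequence[i]; n <- nchar(s)
    if (tr$sno_class[i] == "CD") {
      length(oracle_scan_positions(s, "RUGAUGA")[[1]]) >= 1 &&
        any(oracle_scan_positions(s, "CUGA")[[1]] >= n - 10)
    } else {
      length(oracle_scan_positions(s, "ANANNA")[[1]]) >= 1 &&
        substr(s, n - 5, n - 3) == "ACA"
    }
  }, logical(1))
  expect_true(all(ok))
})
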