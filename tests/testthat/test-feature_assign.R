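feat <- function(start, end, class, contig = "chr1", strand = ".",
                 gene_id = NA_character_, name = "") {
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             strand = strand, feature_class = class, gene_id = gene_id,
             name = name, stringsAsFactors = FALSE)
}

test_that("reads get exactly one label: IR, unique class, or MF", {
  feats <- rbind(feat(100, 200, "iR", gene_id = "g1"),
                 feat(300, 400, "5UR"),
                 feat(390, 500, "PR"))
  idx <- build_feature_index(feats)
  reads <- make_reads(starts = list(120, 395, 600, 10),
                      ends = list(160, 420, 650, 50))
  a <- assign_reads(reads, idx)
  expect_equal(a$label, c("iR", "MF", "IR", "IR"))
})

test_that("known sncRNA and repeat overlaps dominate any other class", {
  feats <- rbind(feat(0, 100, "iR"), feat(50, 80, "known_sncRNA"),
                 feat(200, 300, "ER"), feat(250, 260, "repeat"))
  idx <- build_feature_index(feats)
  reads <- make_reads(starts = list(40, 240), ends = list(90, 290))
  expect_equal(assign_reads(reads, idx)$label, c("known_sncRNA", "repeat"))
})

test_that("same-class ambiguity stays unique by default but is MF when disabled", {
  feats <- rbind(feat(0, 100, "iR", gene_id = "g1"),
                 feat(50, 150, "iR", gene_id = "g2"))
  idx <- build_feature_index(feats)
  reads <- make_reads(starts = list(60), ends = list(90))
  expect_equal(assign_reads(reads, idx)$label, "iR")
  expect_equal(assign_reads(reads, idx, same_class_is_unique = FALSE)$label, "MF")
})

test_that("stranded mode respects strand and '.' matches both", {
  feats <- feat(100, 200, "iR", strand = "+")
  idx <- build_feature_index(feats)
  plus <- make_reads(starts = list(120), ends = list(150), strand = "+")
  minus <- make_reads(starts = list(120), ends = list(150), strand = "-")
  both <- make_reads(starts = list(120), ends = list(150), strand = ".")
  expect_equal(assign_reads(plus, idx, stranded = TRUE)$label, "iR")
  expect_equal(assign_reads(minus, idx, stranded = TRUE)$label, "IR")
  expect_equal(assign_reads(both, idx, stranded = TRUE)$label, "iR")
  expect_equal(assign_reads(minus, idx, stranded = FALSE)$label, "iR")
})

test_that("contig absent from the index warns and yields IR", {
  idx <- build_feature_index(feat(0, 100, "ER"))
  reads <- make_reads(starts = list(10), ends = list(50), contig = "chrZ")
  expect_warning(a <- assign_reads(reads, idx), "chrZ")
  expect_equal(a$label, "IR")
})

test_that("assignment agrees with a linear-scan oracle on random instances", {
  set.seed(11)
  for (rep in 1:20) {
    nf <- 50
    fs <- as.integer(sample(0:5000, nf, TRUE))
    feats <- data.frame(contig = "chr1", start = fs,
                        end = fs + as.integer(sample(20:400, nf, TRUE)),
                        strand = ".",
                        feature_class = sample(c("ER", "iR", "PR", "5UR",
                                                 "3UR", "known_sncRNA",
                                                 "repeat"), nf, TRUE),
                        gene_id = NA_character_, name = "",
                        stringsAsFactors = FALSE)
    idx <- build_feature_index(feats)
    nr <- 500
    rs <- as.integer(sample(0:5200, nr, TRUE))
    reads <- make_reads(starts = as.list(rs),
                        ends = as.list(rs + as.integer(sample(30:150, nr, TRUE))))
    got <- assign_reads(reads, idx)$label
    want <- vapply(seq_len(nr), function(i) {
      ov <- feats$start < reads$ends[[i]] & reads$starts[[i]] < feats$end
      cls <- unique(feats$feature_class[ov])
      if ("known_sncRNA" %in% cls) "known_sncRNA"
      else if ("repeat" %in% cls) "repeat"
      else if (length(cls) == 0) "IR"
      else if (length(cls) == 1) cls
      else "MF"
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("composition summary conserves counts and fractions sum to one", {
  a <- data.frame(read_id = sprintf("r%d", 1:10),
                  label = c(rep("iR", 4), rep("MF", 6)),
                  stringsAsFactors = FALSE)
  cs <- composition_summary(a)
  expect_equal(sum(cs$count), 10)
  expect_equal(sum(cs$fraction), 1)
  expect_equal(cs$fraction[cs$label == "iR"], 0.4)
  expect_equal(cs$fraction[cs$label == "MF"], 0.6)

  set.seed(3)
  for (rep in 1:10) {
    labels <- sample(c("ER", "iR", "IR", "MF", "PR"), 200, TRUE)
    a <- data.frame(read_id = sprintf("r%d", 1:200), label = labels,
                    stringsAsFactors = FALSE)
    cs <- composition_summary(a)
    expect_equal(sum(cs$count), 200)
    tab <- table(labels)
    expect_equal(cs$count[match(names(tab), cs$label)], as.integer(tab))
  }
})

test_that("adding a feature record never moves a read from MF to a unique label", {
  set.seed(5)
  for (rep in 1:10) {
    nf <- 30
    fs <- as.integer(sample(0:2000, nf, TRUE))
    feats <- data.frame(contig = "chr1", start = fs,
                        end = fs + as.integer(sample(20:200, nf, TRUE)),
                        strand = ".",
                        feature_class = sample(c("ER", "iR", "PR", "5UR"),
                                               nf, TRUE),
                        gene_id = NA_character_, name = "",
                        stringsAsFactors = FALSE)
    rs <- as.integer(sample(0:2100, 100, TRUE))
    reads <- make_reads(starts = as.list(rs),
                        ends = as.list(rs + as.integer(sample(30:120, 100, TRUE))))
    before <- assign_reads(reads, build_feature_index(feats))$label
    extra <- data.frame(contig = "chr1", start = 500L, end = 1500L,
                        strand = ".", feature_class = "3UR",
                        gene_id = NA_character_, name = "",
                        stringsAsFactors = FALSE)
    after <- assign_reads(reads, build_feature_index(rbind(feats, extra)))$label
    expect_false(any(before == "MF" &
                       after %in% c("ER", "iR", "PR", "5UR", "3UR", "IR")))
  }
})
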