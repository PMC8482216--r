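# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation (linear scan, brute
# force, exhaustive enumeration) kept separate from the package's code
# paths.

make_reads <- function(starts, ends, contig = "chr1", strand = "+",
                       sample = "S1", mapq = 60L,
                       read_id = sprintf("r%d", seq_along(starts))) {
  stopifnot(length(starts) == length(ends))
  data.frame(read_id = read_id,
             sample = rep(sample, length.out = length(starts)),
             contig = rep(contig, length.out = length(starts)),
             strand = rep(strand, length.out = length(starts)),
             mapq = rep(as.integer(mapq), length.out = length(starts)),
             starts = I(lapply(starts, function(x) as.integer(x))),
             ends = I(lapply(ends, function(x) as.integer(x))),
             stringsAsFactors = FALSE)
}

make_spliced_read <- function(starts, ends, contig = "chr1", strand = "+",
                              read_id = "sp1", sample = "S1") {
  data.frame(read_id = read_id, sample = sample, contig = contig,
             strand = strand, mapq = 60L,
             starts = I(list(as.integer(starts))),
             ends = I(list(as.integer(ends))),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_reads_fixture <- function() {
  data.frame(read_id = character(0), sample = character(0),
             contig = character(0), strand = character(0), mapq = integer(0),
             starts = I(list()), ends = I(list()), stringsAsFactors = FALSE)
}

iR_labels <- function(reads) {
  data.frame(read_id = reads$read_id, label = rep("IR", nrow(reads)),
             stringsAsFactors = FALSE)
}

# position-by-position counting pileup
oracle_pileup <- function(reads, region) {
  depth <- integer(region$end - region$start)
  for (i in seq_len(nrow(reads))) {
    if (reads$contig[i] != region$contig) next
    for (b in seq_along(reads$starts[[i]])) {
      s <- reads$starts[[i]][b]; e <- reads$ends[[i]][b]
      for (p in seq.int(region$start, region$end - 1)) {
        if (p >= s && p < e) depth[p - region$start + 1] <- depth[p - region$start + 1] + 1L
      }
    }
  }
  depth
}

# O(n^2) connected-components clustering of single-contig reads: reads are
# connected when their block spans overlap or lie within merge_gap of each
# other; cluster bounds are min start / max end of members.
oracle_clusters <- function(reads, min_reads = 20, merge_gap = 0) {
  n <- nrow(reads)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0),
                                read_count = integer(0)))
  span_s <- vapply(reads$starts, min, numeric(1))
  span_e <- vapply(reads$ends, max, numeric(1))
  # interval-overlap graph on block footprints
  touches <- function(i, j) {
    for (a in seq_along(reads$starts[[i]]))
      for (b in seq_along(reads$starts[[j]])) {
        s1 <- reads$starts[[i]][a]; e1 <- reads$ends[[i]][a]
        s2 <- reads$starts[[j]][b]; e2 <- reads$ends[[j]][b]
        # same cluster when at most merge_gap uncovered positions separate
        # the two blocks (0 = overlapping or adjacent)
        if (max(s1, s2) - min(e1, e2) <= merge_gap) return(TRUE)
      }
    FALSE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (comp[i] != comp[j] && touches(i, j)) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(cc) {
    ix <- which(comp == cc)
    data.frame(start = min(span_s[ix]), end = max(span_e[ix]),
               read_count = length(ix))
  })
  out <- do.call(rbind, out)
  out <- out[out$read_count >= min_reads, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# expand an IUPAC motif into all concrete words, exact-match each
iupac_expand <- function(motif) {
  sets <- list(A = "A", C = "C", G = "G", U = "U", T = "U",
               R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
               W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
               B = c("C", "G", "U"), D = c("A", "G", "U"),
               H = c("A", "C", "U"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "U"))
  chars <- strsplit(motif, "")[[1]]
  words <- ""
  for (ch in chars) words <- as.vector(outer(words, sets[[ch]], paste0))
  words
}

oracle_scan_positions <- function(seqs, motif) {
  # list of 0-based exact-match hit positions per sequence; zero-width
  # lookahead finds overlapping occurrences
  words <- iupac_expand(motif)
  hits <- vector("list", length(seqs))
  for (w in words) {
    m <- gregexpr(paste0("(?=", w, ")"), seqs, perl = TRUE)
    for (i in seq_along(seqs)) {
      p <- m[[i]]
      if (p[1] != -1) hits[[i]] <- c(hits[[i]], as.integer(p) - 1L)
    }
  }
  lapply(hits, function(h) sort(unique(h)))
}

# exhaustive enumeration of all nested structures (no memoisation)
oracle_fold_maxpairs <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (!pairable(s[k], s[j])) next
      v <- 1L + rec(k + 1, j - 1) + if (k > i) rec(i, k - 1) else 0L
      if (v > best) best <- v
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}

# full Smith-Waterman DP in R (affine gaps, gap cost open + L * extend)
oracle_sw_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  a <- strsplit(chartr("T", "U", toupper(a)), "")[[1]]
  b <- strsplit(chartr("T", "U", toupper(b)), "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
    F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F[i - 1, j] + gap_extend)
    sc <- if (a[i - 1] == b[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                         replace = TRUE), collapse = "")

# a tandem scaRNA built from first principles: C/D terminal stems and
# boxes around an H/ACA body whose 5' hairpin loop carries the CAB box
make_tandem_seq <- function(cab = "UGAG") {
  t5 <- random_rna(5)
  s1 <- random_rna(10); s2 <- random_rna(10)
  paste0(
    t5, sample(c("A", "G"), 1), "UGAUGA",
    s1, "A", cab, "C", snoscout::revcomp_rna(s1),
    random_rna(3), "A", random_rna(1), "A", random_rna(2), "A", random_rna(3),
    s2, random_rna(6), snoscout::revcomp_rna(s2),
    "CUGA", snoscout::revcomp_rna(t5), "ACA", "AA")
}
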