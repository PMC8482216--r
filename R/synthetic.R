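#' Simulation configuration for the synthetic study conditions
#'
#' Defines a toy genome with multi-exon genes, planted snoRNA loci of each
#' class (intronic and intergenic), decoy loci kept below the 20-read
#' cluster threshold, unannotated two-exon transcriptional units hosting a
#' subset of the intergenic snoRNAs, and a size-selected read model
#' (inserts 50-200 nt, boundary jitter, negative-binomial depth).
#'
#' @param seed integer seed driving every random choice.
#' @param genome_length toy genome length in nt (default 200000).
#' @param contig contig name.
#' @param n_genes number of 3-exon genes (default 12).
#' @param n_cd,n_haca,n_sca planted snoRNAs per class (defaults 10 each).
#' @param n_decoys loci receiving fewer than 20 reads (default 10).
#' @param n_tu_hosted intergenic snoRNAs planted inside the intron of an
#'   unannotated two-exon TU (default 4).
#' @param frac_intergenic fraction of planted snoRNAs placed in intergenic
#'   space (default 0.3; never below what `n_tu_hosted` requires).
#' @param reads_per_locus mean reads per planted locus (default 50).
#' @param dispersion negative-binomial dispersion of locus depth (default
#'   0.3; 0 makes depth deterministic).
#' @param min_planted_reads planted loci are clamped to at least this many
#'   reads (default 25) so they exceed the 20-read threshold by
#'   construction; the clamp only applies when `reads_per_locus >= 20`.
#' @param insert_size_range min/max insert length in nt (default
#'   `c(50, 200)`, the library's size selection).
#' @param jitter read 5'/3' ends jitter uniformly within +/- this many nt
#'   of the locus boundaries (default 5).
#' @param n_samples number of samples reads are spread over (default 4).
#' @param background_per_exon mean background reads per annotated exon
#'   (default 2).
#' @param tu_exon_len,tu_intron_len geometry of planted novel TUs
#'   (defaults 200/800 nt).
#' @param tu_junction_reads spliced reads supporting each planted TU
#'   junction (default 6).
#' @param tu_read_len,tu_exon_depth_step length and tiling step of
#'   simulated total-RNA exon reads (defaults 100/25).
#' @param cab_box CAB consensus planted in scaRNA loops (default "UGAG",
#'   a configurable stand-in).
#' @param promoter_width promoter window used when annotating (default
#'   1000).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_length = 200000, contig = "chrS",
                       n_genes = 12, n_cd = 10, n_haca = 10, n_sca = 10,
                       n_decoys = 10, n_tu_hosted = 4, frac_intergenic = 0.3,
                       reads_per_locus = 50, dispersion = 0.3,
                       min_planted_reads = 25,
                       insert_size_range = c(50, 200), jitter = 5,
                       n_samples = 4, background_per_exon = 2,
                       tu_exon_len = 200, tu_intron_len = 800,
                       tu_junction_reads = 6, tu_read_len = 100,
                       tu_exon_depth_step = 25, cab_box = "UGAG",
                       promoter_width = 1000) {
  cfg <- as.list(environment())
  stopifnot(insert_size_range[1] >= 1,
            insert_size_range[1] < insert_size_range[2])
  counts <- c(n_genes, n_cd, n_haca, n_sca, n_decoys, n_tu_hosted, n_samples)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (abs(frac_intergenic) > 1) stop("frac_intergenic must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                             collapse = "")

# C/D architecture: terminal stem halves at both ends, C box in the first
# 12 nt, D box in the last 10 nt. The CAB consensus anywhere and an ACA
# near the 3' end are rejected so plain C/D loci cannot trip the scaRNA
# or H/ACA rules.
make_cd_seq <- function(len, cab_box) {
  for (try in 1:200) {
    stem <- rand_nt(5)
    head <- paste0(stem, sample(c("A", "G"), 1), "UGAUGA")
    tail <- paste0("CUGA", revcomp_rna(stem), rand_nt(1))
    seq <- paste0(head, rand_nt(len - nchar(head) - nchar(tail)), tail)
    aca_near_end <- any(vapply(1:5, function(o)
      substr(seq, len - o - 2, len - o) == "ACA", logical(1)))
    if (!aca_near_end && !grepl(cab_box, seq, fixed = TRUE)) return(seq)
  }
  stop("could not build a C/D sequence under the rejection constraints")
}

# H/ACA architecture: pad + hairpin arm + hinge (H box) + hairpin arm +
# ACA + 3 nt tail. Arms are perfect stems around a 6-nt loop; for scaRNAs
# the 5' loop is A + CAB + C, designed so no two loop positions can pair.
make_haca_seq <- function(stem_len, pad, cab = FALSE, cab_box = "UGAG") {
  for (try in 1:200) {
    loop5 <- if (cab) paste0("A", cab_box, "C") else rand_nt(6)
    loop3 <- rand_nt(6)
    s1 <- rand_nt(stem_len); s2 <- rand_nt(stem_len)
    arm5 <- paste0(s1, loop5, revcomp_rna(s1))
    arm3 <- paste0(s2, loop3, revcomp_rna(s2))
    hinge <- paste0(rand_nt(3), "A", rand_nt(1), "A", rand_nt(2), "A",
                    rand_nt(3))
    seq <- paste0(rand_nt(pad), arm5, hinge, arm3, "ACA", rand_nt(3))
    n_cab <- lengths(regmatches(seq, gregexpr(cab_box, seq, fixed = TRUE)))
    if (cab && n_cab != 1) next
    if (!cab && n_cab != 0) next
    # avoid accidental C/D passes that would force a tandem tie-break
    n <- nchar(seq)
    c_ok <- nrow(scan_motif(seq, "RUGAUGA", c(0L, min(16L, n)), 1)) > 0
    d_ok <- nrow(scan_motif(seq, "CUGA", c(n - 16L, n), 0)) > 0
    if (c_ok && d_ok) next
    return(seq)
  }
  stop("could not build an H/ACA sequence under the rejection constraints")
}

#' Generate the toy genome, annotation, and planted-locus truth table
#'
#' Deterministic given `config$seed`. Genes have three exons (so introns
#' exist); intronic snoRNAs sit at least 30 nt inside intron boundaries;
#' intergenic snoRNAs sit at least 1 kb from any gene; a configurable
#' number of intergenic snoRNAs is embedded in the intron of an
#' unannotated two-exon TU whose coordinates go to a separate truth table.
#' Planted sequences satisfy their class's box/structure invariants by
#' construction; decoy loci are random sequence.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `truth.tsv` and `tu_truth.tsv` there.
#' @return list with `genome` (DNAStringSet), `features` (annotation data
#'   frame), `truth` (planted loci incl. decoys), `tu_truth`, `genes`, and
#'   any written `paths`.
#' @export
generate_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ctg <- config$contig

  ## gene layout: 3 exons of 400/300/400 nt, two 1500-nt introns,
  ## 5-kb intergenic gaps, 6-kb lead-in
  gene_span <- 4100; gap_len <- 5000; lead <- 6000
  stride <- gene_span + gap_len
  gene_start <- lead + (seq_len(config$n_genes) - 1) * stride
  layout_end <- if (config$n_genes > 0) max(gene_start) + gene_span + gap_len else lead
  if (layout_end > config$genome_length)
    stop("placement impossible: genome_length (", config$genome_length,
         ") too small for ", config$n_genes,
         " genes without overlap (need >= ", layout_end, ")")
  genes <- data.frame(
    gene_id = sprintf("gene_%d", seq_len(config$n_genes)),
    start = gene_start, end = gene_start + gene_span,
    strand = rep(c("+", "-"), length.out = config$n_genes),
    stringsAsFactors = FALSE)
  exon_off <- cbind(c(0, 1900, 3700), c(400, 2200, 4100))

  ## slots
  intron_slots <- list()
  for (g in seq_len(config$n_genes)) {
    for (io in list(c(400, 1900), c(2200, 3700))) {
      i0 <- genes$start[g] + io[1]
      intron_slots[[length(intron_slots) + 1]] <-
        list(pos = i0 + 150, gene = genes$gene_id[g], strand = genes$strand[g])
      intron_slots[[length(intron_slots) + 1]] <-
        list(pos = i0 + 850, gene = genes$gene_id[g], strand = genes$strand[g])
    }
  }
  gap_starts <- if (config$n_genes > 0) genes$end else 0L
  n_tu <- config$n_tu_hosted
  if (n_tu > length(gap_starts))
    stop("placement impossible: need ", n_tu,
         " intergenic gaps for TUs but only ", length(gap_starts),
         " exist (increase n_genes)")
  tu_gaps <- gap_starts[seq_len(n_tu)]
  free_gaps <- gap_starts[setdiff(seq_along(gap_starts), seq_len(n_tu))]
  gap_slots <- list()
  for (gs in free_gaps) {
    gap_slots[[length(gap_slots) + 1]] <- list(pos = gs + 1300)
    gap_slots[[length(gap_slots) + 1]] <- list(pos = gs + 2700)
  }
  # lead-in region is also intergenic (clear of gene_1's promoter)
  gap_slots[[length(gap_slots) + 1]] <- list(pos = 1500)
  gap_slots[[length(gap_slots) + 1]] <- list(pos = 3000)

  ## planted loci: classes interleaved CD/HACA/SCA, intergenic quota
  ## spread evenly across the list
  total <- config$n_cd + config$n_haca + config$n_sca
  pool <- c(CD = config$n_cd, HACA = config$n_haca, SCA = config$n_sca)
  classes <- character(0)
  while (sum(pool) > 0) {
    for (cl in names(pool)) {
      if (pool[cl] > 0) {
        classes <- c(classes, cl)
        pool[cl] <- pool[cl] - 1
      }
    }
  }
  n_intergenic <- max(n_tu, round(config$frac_intergenic * total))
  if (n_intergenic > total) n_intergenic <- total
  is_intergenic <- rep(FALSE, total)
  if (n_intergenic > 0)
    is_intergenic[unique(round(seq(1, total, length.out = n_intergenic)))] <- TRUE
  while (sum(is_intergenic) < n_intergenic)
    is_intergenic[which(!is_intergenic)[1]] <- TRUE

  ## decoys: half intronic, half intergenic
  n_dec_intronic <- config$n_decoys %/% 2
  n_dec_intergenic <- config$n_decoys - n_dec_intronic

  need_intron <- sum(!is_intergenic) + n_dec_intronic
  if (need_intron > length(intron_slots))
    stop("placement impossible: ", need_intron,
         " intronic loci but only ", length(intron_slots),
         " intron slots (increase n_genes)")
  need_gap <- (sum(is_intergenic) - n_tu) + n_dec_intergenic
  if (need_gap > length(gap_slots))
    stop("placement impossible: ", need_gap,
         " free intergenic loci but only ", length(gap_slots),
         " gap slots (increase n_genes or genome_length)")

  loci <- list(); tu_truth <- list()
  i_intron <- 0L; i_gap <- 0L; i_tu <- 0L
  tu_seen <- 0L
  for (i in seq_len(total)) {
    cls <- classes[i]
    strand <- if (i %% 2 == 0) "-" else "+"
    seq <- switch(cls,
      CD = make_cd_seq(sample(75:110, 1), config$cab_box),
      HACA = make_haca_seq(sample(14:20, 1), sample(3:8, 1), cab = FALSE,
                           cab_box = config$cab_box),
      SCA = make_haca_seq(sample(14:20, 1), sample(3:8, 1), cab = TRUE,
                          cab_box = config$cab_box))
    len <- nchar(seq)
    if (is_intergenic[i] && tu_seen < n_tu) {
      # hosted inside the intron of an unannotated two-exon TU
      i_tu <- i_tu + 1L; tu_seen <- tu_seen + 1L
      gs <- tu_gaps[i_tu]
      e1 <- c(gs + 1300, gs + 1300 + config$tu_exon_len)
      e2 <- c(e1[2] + config$tu_intron_len, e1[2] + config$tu_intron_len +
                config$tu_exon_len)
      pos <- e1[2] + (config$tu_intron_len - len) %/% 2
      tu_truth[[length(tu_truth) + 1]] <- data.frame(
        tu_id = sprintf("true_tu_%d", i_tu), contig = ctg,
        exon1_start = e1[1], exon1_end = e1[2],
        exon2_start = e2[1], exon2_end = e2[2],
        strand = strand, locus_id = sprintf("sno_%d", i),
        stringsAsFactors = FALSE)
      host <- NA_character_; context <- "intergenic"
      tu_id <- sprintf("true_tu_%d", i_tu)
    } else if (is_intergenic[i]) {
      i_gap <- i_gap + 1L
      pos <- gap_slots[[i_gap]]$pos
      host <- NA_character_; context <- "intergenic"; tu_id <- NA_character_
    } else {
      i_intron <- i_intron + 1L
      slot <- intron_slots[[i_intron]]
      pos <- slot$pos
      host <- slot$gene; context <- "intronic"; tu_id <- NA_character_
    }
    loci[[length(loci) + 1]] <- data.frame(
      locus_id = sprintf("sno_%d", i), contig = ctg,
      start = pos, end = pos + len, strand = strand, sno_class = cls,
      context = context, host_gene_id = host, tu_id = tu_id,
      is_decoy = FALSE, sequence = seq, stringsAsFactors = FALSE)
  }
  for (d in seq_len(config$n_decoys)) {
    len <- sample(60:150, 1)
    seq <- rand_nt(len)
    strand <- if (d %% 2 == 0) "-" else "+"
    if (d <= n_dec_intronic) {
      i_intron <- i_intron + 1L
      slot <- intron_slots[[i_intron]]
      pos <- slot$pos; host <- slot$gene; context <- "intronic"
    } else {
      i_gap <- i_gap + 1L
      pos <- gap_slots[[i_gap]]$pos; host <- NA_character_
      context <- "intergenic"
    }
    loci[[length(loci) + 1]] <- data.frame(
      locus_id = sprintf("decoy_%d", d), contig = ctg,
      start = pos, end = pos + len, strand = strand, sno_class = "decoy",
      context = context, host_gene_id = host, tu_id = NA_character_,
      is_decoy = TRUE, sequence = seq, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, loci)
  tu_truth <- if (length(tu_truth) > 0) do.call(rbind, tu_truth) else
    data.frame(tu_id = character(0), contig = character(0),
               exon1_start = integer(0), exon1_end = integer(0),
               exon2_start = integer(0), exon2_end = integer(0),
               strand = character(0), locus_id = character(0),
               stringsAsFactors = FALSE)

  ## genome sequence with planted loci substituted
  chars <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
  for (r in seq_len(nrow(truth))) {
    s <- as_dna(truth$sequence[r])
    if (truth$strand[r] == "-") s <- as_dna(revcomp_rna(truth$sequence[r]))
    chars[(truth$start[r] + 1):truth$end[r]] <- strsplit(s, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- ctg

  ## annotation features (0-based half-open) + GFF3 text
  feats <- list(); gff <- "##gff-version 3"
  for (g in seq_len(config$n_genes)) {
    gid <- genes$gene_id[g]; txid <- sprintf("tx_%d", g)
    gs <- genes$start[g]; str <- genes$strand[g]
    gff <- c(gff,
      paste(ctg, "snoscout", "gene", gs + 1, gs + gene_span, ".", str, ".",
            sprintf("ID=%s", gid), sep = "\t"),
      paste(ctg, "snoscout", "mRNA", gs + 1, gs + gene_span, ".", str, ".",
            sprintf("ID=%s;Parent=%s", txid, gid), sep = "\t"))
    for (k in 1:3) {
      es <- gs + exon_off[k, 1]; ee <- gs + exon_off[k, 2]
      gff <- c(gff, paste(ctg, "snoscout", "exon", es + 1, ee, ".", str, ".",
                          sprintf("ID=%s.exon%d;Parent=%s", txid, k, txid),
                          sep = "\t"))
      feats[[length(feats) + 1]] <- data.frame(
        contig = ctg, start = es, end = ee, strand = str,
        feature_class = "ER", gene_id = gid, name = txid,
        stringsAsFactors = FALSE)
    }
    for (io in list(c(400, 1900), c(2200, 3700)))
      feats[[length(feats) + 1]] <- data.frame(
        contig = ctg, start = gs + io[1], end = gs + io[2], strand = str,
        feature_class = "iR", gene_id = gid, name = txid,
        stringsAsFactors = FALSE)
    pr <- if (str == "-") c(gs + gene_span, gs + gene_span + config$promoter_width)
          else c(gs - config$promoter_width, gs)
    feats[[length(feats) + 1]] <- data.frame(
      contig = ctg, start = max(0, pr[1]), end = pr[2], strand = str,
      feature_class = "PR", gene_id = gid, name = txid,
      stringsAsFactors = FALSE)
  }
  features <- if (length(feats) > 0) do.call(rbind, feats) else empty_features()

  out <- list(genome = genome, features = features, truth = truth,
              tu_truth = tu_truth, genes = genes, gff_lines = gff)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  annotation = file.path(dir, "annotation.gff3"),
                  truth = file.path(dir, "truth.tsv"),
                  tu_truth = file.path(dir, "tu_truth.tsv"))
    Biostrings::writeXStringSet(genome, paths$genome)
    writeLines(gff, paths$annotation)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(tu_truth, paths$tu_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

locus_read_count <- function(truth_row, config) {
  if (truth_row$is_decoy) return(sample(5:19, 1))
  mu <- config$reads_per_locus
  n <- if (mu == 0) 0L
       else if (config$dispersion == 0) as.integer(round(mu))
       else stats::rnbinom(1, size = 1 / config$dispersion, mu = mu)
  if (mu >= 20) n <- max(n, config$min_planted_reads)
  as.integer(n)
}

#' Simulate size-selected reads over the planted loci
#'
#' Per locus the read count is negative binomial
#' (`mean = reads_per_locus`, clamped so planted loci exceed the 20-read
#' threshold); decoys draw 5-19 reads. Read ends jitter uniformly within
#' +/- `jitter` nt of the locus boundaries and lengths are clipped to
#' `insert_size_range`. Background reads are scattered over annotated
#' exons. Deterministic given `config$seed`.
#'
#' @param truth truth table from [generate_genome()].
#' @param config the [sim_config()].
#' @param features optional annotation (for exonic background reads).
#' @param path optional output path (simplified alignment TSV).
#' @return reads data frame (and the file at `path` if given).
#' @export
simulate_reads <- function(truth, config, features = NULL, path = NULL) {
  stopifnot(nrow(truth) > 0)
  set.seed(config$seed + 1L)
  glen <- config$genome_length
  imin <- config$insert_size_range[1]; imax <- config$insert_size_range[2]
  J <- config$jitter
  samples <- sprintf("S%d", seq_len(max(1, config$n_samples)))
  out <- list()
  for (r in seq_len(nrow(truth))) {
    n <- locus_read_count(truth[r, , drop = FALSE], config)
    if (n == 0) next
    js <- sample(-J:J, n, replace = TRUE)
    je <- sample(-J:J, n, replace = TRUE)
    s <- truth$start[r] + js
    e <- truth$end[r] + je
    len <- e - s
    e[len > imax] <- s[len > imax] + imax
    len <- e - s
    e[len < imin] <- s[len < imin] + imin
    s <- pmax(0L, s); e <- pmin(as.integer(glen), e)
    out[[length(out) + 1]] <- data.frame(
      read_id = sprintf("%s_r%d", truth$locus_id[r], seq_len(n)),
      sample = sample(samples, n, replace = TRUE),
      contig = truth$contig[r], strand = truth$strand[r], mapq = 60L,
      stringsAsFactors = FALSE,
      starts = I(as.list(as.integer(s))), ends = I(as.list(as.integer(e))))
  }
  if (!is.null(features) && config$background_per_exon > 0) {
    ex <- features[features$feature_class == "ER", , drop = FALSE]
    for (r in seq_len(nrow(ex))) {
      nb <- stats::rpois(1, config$background_per_exon)
      if (nb == 0) next
      rl <- min(100L, ex$end[r] - ex$start[r])
      s <- sample(ex$start[r]:(ex$end[r] - rl), nb, replace = TRUE)
      out[[length(out) + 1]] <- data.frame(
        read_id = sprintf("bg_%d_r%d", r, seq_len(nb)),
        sample = sample(samples, nb, replace = TRUE),
        contig = ex$contig[r], strand = ex$strand[r], mapq = 60L,
        stringsAsFactors = FALSE,
        starts = I(as.list(as.integer(s))),
        ends = I(as.list(as.integer(s + rl))))
    }
  }
  reads <- if (length(out) > 0) do.call(rbind, out) else empty_reads()
  rownames(reads) <- NULL
  if (!is.null(path)) write_alignments(reads, path)
  reads
}

#' Simulate total-RNA reads over the planted novel TUs
#'
#' Exons are tiled with `tu_read_len`-nt reads every
#' `tu_exon_depth_step` nt (coverage >= 1 across each exon, zero outside),
#' and each TU junction receives `tu_junction_reads` spliced reads whose
#' blocks end/start exactly at the junction edges.
#'
#' @param tu_truth TU truth table from [generate_genome()].
#' @param config the [sim_config()].
#' @param path optional output path (simplified alignment TSV).
#' @return reads data frame.
#' @export
simulate_tu_reads <- function(tu_truth, config, path = NULL) {
  set.seed(config$seed + 2L)
  samples <- sprintf("S%d", seq_len(max(1, config$n_samples)))
  out <- list()
  for (r in seq_len(nrow(tu_truth))) {
    tu <- tu_truth[r, , drop = FALSE]
    exons <- list(c(tu$exon1_start, tu$exon1_end),
                  c(tu$exon2_start, tu$exon2_end))
    for (k in seq_along(exons)) {
      e <- exons[[k]]
      rl <- min(config$tu_read_len, e[2] - e[1])
      starts <- unique(c(seq(e[1], e[2] - rl, by = config$tu_exon_depth_step),
                         e[2] - rl))
      out[[length(out) + 1]] <- data.frame(
        read_id = sprintf("%s_e%d_r%d", tu$tu_id, k, seq_along(starts)),
        sample = sample(samples, length(starts), replace = TRUE),
        contig = tu$contig, strand = tu$strand, mapq = 60L,
        stringsAsFactors = FALSE,
        starts = I(as.list(as.integer(starts))),
        ends = I(as.list(as.integer(starts + rl))))
    }
    blk <- min(60L, config$tu_exon_len)
    nj <- config$tu_junction_reads
    out[[length(out) + 1]] <- data.frame(
      read_id = sprintf("%s_j_r%d", tu$tu_id, seq_len(nj)),
      sample = sample(samples, nj, replace = TRUE),
      contig = tu$contig, strand = tu$strand, mapq = 60L,
      stringsAsFactors = FALSE,
      starts = I(rep(list(as.integer(c(tu$exon1_end - blk, tu$exon2_start))), nj)),
      ends = I(rep(list(as.integer(c(tu$exon1_end, tu$exon2_start + blk))), nj)))
  }
  reads <- if (length(out) > 0) do.call(rbind, out) else empty_reads()
  rownames(reads) <- NULL
  if (!is.null(path)) write_alignments(reads, path)
  reads
}

#' Simulate candidate/host count matrices with a target correlation
#'
#' Per pair, log-abundances are drawn from a bivariate normal with
#' correlation `r_target`, exponentiated and rounded to counts. A host
#' gene shared by several candidates keeps one latent profile, each
#' candidate correlating with it at `r_target`.
#'
#' @param pairs data frame with `candidate_id` and `host_gene_id`.
#' @param r_target Pearson correlation of the latent log-abundances, in
#'   `[-1, 1]`.
#' @param n_samples number of samples (>= 3).
#' @param seed integer seed.
#' @param mean_log,sd_log latent log-abundance location/scale (defaults
#'   5/1).
#' @return list with matrices `candidate_counts` and `host_counts`
#'   (columns `S1..Sn`).
#' @export
simulate_expression <- function(pairs, r_target, n_samples, seed,
                                mean_log = 5, sd_log = 1) {
  if (abs(r_target) > 1) stop("r_target must be in [-1, 1]")
  if (n_samples < 3) stop("n_samples must be >= 3")
  set.seed(seed)
  samples <- sprintf("S%d", seq_len(n_samples))
  hosts <- unique(pairs$host_gene_id)
  host_z <- matrix(stats::rnorm(length(hosts) * n_samples),
                   nrow = length(hosts), dimnames = list(hosts, samples))
  resid <- sqrt(1 - r_target^2)
  cand_z <- t(vapply(seq_len(nrow(pairs)), function(i) {
    r_target * host_z[pairs$host_gene_id[i], ] +
      resid * stats::rnorm(n_samples)
  }, numeric(n_samples)))
  rownames(cand_z) <- pairs$candidate_id
  colnames(cand_z) <- samples
  to_counts <- function(z) round(exp(mean_log + sd_log * z))
  list(candidate_counts = to_counts(cand_z),
       host_counts = to_counts(host_z))
}

#' Generate a small reference of known sncRNA sequences
#'
#' Random members of each family (snoRNA references follow the C/D and
#' H/ACA architectures) used to exercise the homology stage; none are
#' planted in the genome, so synthetic candidates are expected to be
#' novel.
#'
#' @param config the [sim_config()].
#' @param path optional FASTA output path (family encoded as
#'   `family=<tag>` in the description).
#' @return named character vector of sequences with a `families`
#'   attribute.
#' @export
generate_reference <- function(config, path = NULL) {
  set.seed(config$seed + 3L)
  seqs <- c(
    ref_mir_1 = rand_nt(22), ref_mir_2 = rand_nt(22),
    ref_snrna_1 = rand_nt(120), ref_snrna_2 = rand_nt(150),
    ref_sno_cd_1 = make_cd_seq(90, config$cab_box),
    ref_sno_cd_2 = make_cd_seq(100, config$cab_box),
    ref_sno_haca_1 = make_haca_seq(16, 5, cab = FALSE,
                                   cab_box = config$cab_box),
    ref_trna_1 = rand_nt(75))
  fams <- c("miRNA", "miRNA", "snRNA", "snRNA", "snoRNA", "snoRNA",
            "snoRNA", "tRNA")
  attr(seqs, "families") <- fams
  if (!is.null(path)) {
    writeLines(unlist(lapply(seq_along(seqs), function(i)
      c(sprintf(">%s family=%s", names(seqs)[i], fams[i]), seqs[[i]]))),
      path)
  }
  seqs
}

#' Write and read count matrices as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
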