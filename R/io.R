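#' Read aligned reads from SAM-dialect or simplified TSV alignments
#'
#' Accepts either plain-text SAM (header lines starting with `@` are
#' ignored; the CIGAR string is walked to recover aligned blocks, so spliced
#' alignments with `N` operations yield multi-block reads) or the package's
#' simplified 7-column TSV dialect
#' (`read_id, sample, contig, strand, block_starts, block_ends, mapq`,
#' blocks comma-separated, 0-based half-open). All coordinates are returned
#' 0-based half-open.
#'
#' Only CIGAR operations `M`, `N`, `S`, `I`, `D` are honoured: `S`/`I`
#' consume no reference, `D` consumes reference within a block, `N` splits
#' blocks. Any other operation is a parse error.
#'
#' @param path path to the alignment file.
#' @param min_mapq minimum mapping quality; reads below it are dropped.
#' @param format `"auto"` (default), `"sam"` or `"tsv"`.
#' @return a data frame with one row per read: `read_id`, `sample`,
#'   `contig`, `strand` (`+`, `-` or `.`), `mapq`, and list-columns
#'   `starts`/`ends` holding the 0-based half-open aligned blocks.
#' @export
read_alignments <- function(path, min_mapq = 0, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines) & !startsWith(lines, "#"))
  if (format == "auto") {
    if (length(body) == 0) return(empty_reads())
    nf <- length(strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]])
    format <- if (nf >= 11) "sam" else "tsv"
  }
  if (length(body) == 0) return(empty_reads())
  recs <- if (format == "sam") {
    lapply(body, function(ln) parse_sam_line(lines[ln], ln))
  } else {
    lapply(body, function(ln) parse_tsv_line(lines[ln], ln))
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) return(empty_reads())
  reads <- data.frame(
    read_id = vapply(recs, `[[`, character(1), "read_id"),
    sample = vapply(recs, `[[`, character(1), "sample"),
    contig = vapply(recs, `[[`, character(1), "contig"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    mapq = vapply(recs, `[[`, integer(1), "mapq"),
    stringsAsFactors = FALSE
  )
  reads$starts <- I(lapply(recs, `[[`, "starts"))
  reads$ends <- I(lapply(recs, `[[`, "ends"))
  reads[reads$mapq >= min_mapq, , drop = FALSE]
}

parse_sam_line <- function(line, ln) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11)
    stop(sprintf("malformed SAM line %d: expected >= 11 fields, got %d",
                 ln, length(f)))
  flag <- suppressWarnings(as.integer(f[2]))
  if (is.na(flag)) stop(sprintf("malformed SAM line %d: non-numeric FLAG", ln))
  if (bitwAnd(flag, 4L) > 0 || f[3] == "*") return(NULL) # unmapped
  pos <- suppressWarnings(as.integer(f[4])) - 1L
  mapq <- suppressWarnings(as.integer(f[5]))
  if (is.na(pos) || is.na(mapq))
    stop(sprintf("malformed SAM line %d: non-numeric POS/MAPQ", ln))
  blocks <- cigar_blocks(f[6], pos, ln)
  sample <- "sample1"
  if (length(f) > 11) {
    rg <- grep("^RG:Z:", f[12:length(f)], value = TRUE)
    if (length(rg) > 0) sample <- sub("^RG:Z:", "", rg[1])
  }
  list(read_id = f[1], sample = sample, contig = f[3],
       strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
       mapq = mapq, starts = blocks$starts, ends = blocks$ends)
}

cigar_blocks <- function(cigar, pos, ln) {
  m <- gregexpr("\\d+[A-Z=]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  if (m[1] == -1 || paste(toks, collapse = "") != cigar)
    stop(sprintf("malformed SAM line %d: bad CIGAR '%s'", ln, cigar))
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  bad <- setdiff(ops, c("M", "N", "S", "I", "D"))
  if (length(bad) > 0)
    stop(sprintf("malformed SAM line %d: unsupported CIGAR op '%s'",
                 ln, bad[1]))
  starts <- integer(0); ends <- integer(0)
  ref <- pos; cur <- NA_integer_
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op %in% c("M", "D")) {
      if (is.na(cur)) cur <- ref
      ref <- ref + lens[k]
    } else if (op == "N") {
      if (!is.na(cur)) { starts <- c(starts, cur); ends <- c(ends, ref) }
      cur <- NA_integer_
      ref <- ref + lens[k]
    }
    # S and I consume no reference
  }
  if (!is.na(cur)) { starts <- c(starts, cur); ends <- c(ends, ref) }
  if (length(starts) == 0 || any(ends <= starts))
    stop(sprintf("malformed SAM line %d: CIGAR consumes no reference", ln))
  list(starts = starts, ends = ends)
}

parse_tsv_line <- function(line, ln) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 7)
    stop(sprintf("malformed line %d: expected 7 fields, got %d", ln, length(f)))
  starts <- suppressWarnings(as.integer(strsplit(f[5], ",", fixed = TRUE)[[1]]))
  ends <- suppressWarnings(as.integer(strsplit(f[6], ",", fixed = TRUE)[[1]]))
  if (anyNA(starts) || anyNA(ends))
    stop(sprintf("malformed line %d: non-numeric block coordinates", ln))
  if (length(starts) != length(ends))
    stop(sprintf("inconsistent block counts at line %d: %d starts vs %d ends",
                 ln, length(starts), length(ends)))
  if (any(ends <= starts) || is.unsorted(starts, strictly = TRUE) && length(starts) > 1)
    stop(sprintf("malformed line %d: blocks must be sorted, non-empty", ln))
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop(sprintf("malformed line %d: overlapping blocks", ln))
  if (!f[4] %in% c("+", "-", "."))
    stop(sprintf("malformed line %d: strand must be +, - or .", ln))
  mapq <- suppressWarnings(as.integer(f[7]))
  if (is.na(mapq)) stop(sprintf("malformed line %d: non-numeric mapq", ln))
  list(read_id = f[1], sample = f[2], contig = f[3], strand = f[4],
       mapq = mapq, starts = starts, ends = ends)
}

#' Write aligned reads in the simplified 7-column TSV dialect
#'
#' @param reads a reads data frame as returned by [read_alignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path) {
  validate_reads(reads)
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    paste(reads$read_id[i], reads$sample[i], reads$contig[i], reads$strand[i],
          paste(reads$starts[[i]], collapse = ","),
          paste(reads$ends[[i]], collapse = ","),
          reads$mapq[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

feature_vocab <- c("ER", "iR", "PR", "5UR", "3UR", "known_sncRNA", "repeat")

#' Read genomic feature annotation from GFF3 and/or BED files
#'
#' GFF3 input (1-based closed) and BED input (0-based half-open) are
#' normalised to internal 0-based half-open coordinates. From GFF3,
#' exons become `ER` records, UTR features become `5UR`/`3UR`, introns are
#' derived as gaps between consecutive exons of each transcript (unless an
#' `iR` BED file is supplied), and promoters are derived as
#' `promoter_width` nt upstream of each transcript start (unless a `PR` BED
#' file is supplied).
#'
#' @param gff_path optional GFF3 file with gene/transcript/exon (+ UTR)
#'   records.
#' @param bed_paths named list mapping a feature class (one of
#'   `ER, iR, PR, 5UR, 3UR, known_sncRNA, repeat`) to a BED file.
#' @param promoter_width promoter window in nt upstream of the transcript
#'   start (default 1000).
#' @return a data frame of feature records: `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `feature_class`, `gene_id`, `name`.
#' @export
read_annotation <- function(gff_path = NULL, bed_paths = list(),
                            promoter_width = 1000) {
  bad <- setdiff(names(bed_paths), feature_vocab)
  if (length(bad) > 0)
    stop("unknown feature_class key in bed_paths: ", paste(bad, collapse = ", "))
  out <- list()
  if (!is.null(gff_path)) {
    raw <- utils::read.delim(gff_path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (nrow(raw) > 0) {
      bad_rows <- which(as.numeric(raw[[5]]) < as.numeric(raw[[4]]))
      if (length(bad_rows) > 0)
        stop(sprintf("GFF3 record with end < start (record %d)", bad_rows[1]))
    }
    gr <- rtracklayer::import(gff_path, format = "gff3")
    out <- c(out, gff_features(gr,
                               derive_introns = !("iR" %in% names(bed_paths)),
                               derive_promoters = !("PR" %in% names(bed_paths)),
                               promoter_width = promoter_width))
  }
  for (cls in names(bed_paths)) {
    gr <- rtracklayer::import(bed_paths[[cls]], format = "BED")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else rep("", length(gr))
    out[[length(out) + 1]] <- data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      feature_class = cls,
      gene_id = if (cls %in% c("ER", "iR")) nm else NA_character_,
      name = nm,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(empty_features())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_features <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), feature_class = character(0),
             gene_id = character(0), name = character(0),
             stringsAsFactors = FALSE)
}

first_chr <- function(x) {
  # Parent et al. come back as CharacterList from rtracklayer
  vapply(as.list(x), function(v) if (length(v) > 0) v[[1]] else NA_character_,
         character(1))
}

gff_features <- function(gr, derive_introns, derive_promoters, promoter_width) {
  type <- as.character(gr$type)
  strand_chr <- sub("\\*", ".", as.character(GenomicRanges::strand(gr)))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) first_chr(gr$Parent) else rep(NA_character_, length(gr))

  is_tx <- type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")
  tx2gene <- stats::setNames(parent[is_tx], id[is_tx])
  gene_of <- function(p) {
    g <- unname(tx2gene[p])
    ifelse(is.na(g), p, g) # exon directly under a gene
  }

  out <- list()
  rec <- function(keep, cls) {
    if (!any(keep)) return(NULL)
    data.frame(contig = as.character(GenomicRanges::seqnames(gr))[keep],
               start = s0[keep], end = e0[keep],
               strand = strand_chr[keep], feature_class = cls,
               gene_id = gene_of(parent[keep]),
               name = ifelse(is.na(id[keep]), "", id[keep]),
               stringsAsFactors = FALSE)
  }
  out$er <- rec(type == "exon", "ER")
  out$u5 <- rec(type == "five_prime_UTR", "5UR")
  out$u3 <- rec(type == "three_prime_UTR", "3UR")

  ex_idx <- which(type == "exon")
  if (derive_introns && length(ex_idx) > 0) {
    by_tx <- split(ex_idx, parent[ex_idx])
    introns <- lapply(names(by_tx), function(txid) {
      ix <- by_tx[[txid]][order(s0[by_tx[[txid]]])]
      if (length(ix) < 2) return(NULL)
      data.frame(contig = as.character(GenomicRanges::seqnames(gr))[ix[-length(ix)]],
                 start = e0[ix[-length(ix)]], end = s0[ix[-1]],
                 strand = strand_chr[ix[1]], feature_class = "iR",
                 gene_id = gene_of(txid),
                 name = txid, stringsAsFactors = FALSE)
    })
    introns <- do.call(rbind, introns)
    if (!is.null(introns)) out$ir <- introns[introns$end > introns$start, , drop = FALSE]
  }
  if (derive_promoters) {
    tx_idx <- which(is_tx)
    if (length(tx_idx) == 0) tx_idx <- which(type == "gene")
    if (length(tx_idx) > 0) {
      minus <- strand_chr[tx_idx] == "-"
      pstart <- ifelse(minus, e0[tx_idx], pmax(0L, s0[tx_idx] - as.integer(promoter_width)))
      pend <- ifelse(minus, e0[tx_idx] + as.integer(promoter_width), s0[tx_idx])
      keep <- pend > pstart
      out$pr <- data.frame(
        contig = as.character(GenomicRanges::seqnames(gr))[tx_idx][keep],
        start = as.integer(pstart[keep]), end = as.integer(pend[keep]),
        strand = strand_chr[tx_idx][keep], feature_class = "PR",
        gene_id = gene_of(ifelse(is.na(parent[tx_idx][keep]),
                                 id[tx_idx][keep], id[tx_idx][keep])),
        name = ifelse(is.na(id[tx_idx][keep]), "", id[tx_idx][keep]),
        stringsAsFactors = FALSE)
      out$pr$gene_id <- unname(ifelse(is.na(tx2gene[out$pr$name]),
                                      out$pr$name, tx2gene[out$pr$name]))
    }
  }
  Filter(Negate(is.null), out)
}

#' Read a genome FASTA file
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] with names truncated to the first
#'   whitespace-delimited token.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

candidate_sidecar_path <- function(path) {
  if (grepl("\\.bed$", path)) sub("\\.bed$", ".tsv", path) else paste0(path, ".tsv")
}

candidate_columns <- c("candidate_id", "contig", "start", "end", "strand",
                       "read_count", "max_depth", "context", "sequence",
                       "sno_class", "confidence", "homology_family",
                       "homology_subject", "host_gene_id")

#' Write called candidates as BED6 plus a sidecar TSV
#'
#' The BED file carries `chrom, start, end, candidate_id, read_count,
#' strand`; the sidecar TSV (same path with `.tsv` extension) carries the
#' full candidate table (context, sequence, class call, homology, host
#' gene). [read_candidates()] round-trips both losslessly.
#'
#' @param candidates candidate data frame (see [call_clusters()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- as.data.frame(candidates, stringsAsFactors = FALSE)
  for (col in candidate_columns)
    if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  bed <- df[, c("contig", "start", "end", "candidate_id", "read_count", "strand")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(df[, candidate_columns], candidate_sidecar_path(path),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read candidates written by [write_candidates()]
#'
#' @param path the BED path given to [write_candidates()].
#' @return the candidate data frame.
#' @export
read_candidates <- function(path) {
  sc <- candidate_sidecar_path(path)
  df <- utils::read.delim(sc, stringsAsFactors = FALSE,
                          colClasses = c(
                            candidate_id = "character", contig = "character",
                            start = "integer", end = "integer",
                            strand = "character", read_count = "integer",
                            max_depth = "integer", context = "character",
                            sequence = "character", sno_class = "character",
                            confidence = "numeric",
                            homology_family = "character",
                            homology_subject = "character",
                            host_gene_id = "character"))
  df
}

#' Write transcriptional units as GFF3
#'
#' One `gene` record per TU with nested `exon` records; coordinates are
#' converted from internal 0-based half-open to GFF3 1-based closed.
#'
#' @param tus a list of TU objects from [assemble_tus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tu_gff3 <- function(tus, path) {
  lines <- "##gff-version 3"
  for (tu in tus) {
    if (is.null(tu)) next
    span <- c(min(tu$exons$start), max(tu$exons$end))
    lines <- c(lines, paste(
      tu$contig, "snoscout", "gene", span[1] + 1L, span[2], ".",
      tu$strand, ".",
      sprintf("ID=%s;hosted_candidate=%s;hosting_intron_index=%d;min_junction_support=%d",
              tu$tu_id, tu$hosted_candidate_id, tu$hosting_intron_index,
              tu$min_junction_support),
      sep = "\t"))
    for (k in seq_len(nrow(tu$exons))) {
      lines <- c(lines, paste(
        tu$contig, "snoscout", "exon",
        tu$exons$start[k] + 1L, tu$exons$end[k], ".", tu$strand, ".",
        sprintf("ID=%s.exon%d;Parent=%s;soft_edge=%s",
                tu$tu_id, k, tu$tu_id,
                tolower(as.character(tu$exons$soft_edge[k]))),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
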