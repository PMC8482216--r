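#' Per-base read depth over a region
#'
#' @param reads reads data frame (blocks on the region's contig count;
#'   other contigs are ignored).
#' @param region list or one-row data frame with `contig`, `start`, `end`
#'   (0-based half-open).
#' @return integer vector of length `end - start`; element `i` is the
#'   number of reads with an aligned block covering `start + i - 1`
#'   (0-based).
#' @export
pileup <- function(reads, region) {
  validate_reads(reads)
  width <- region$end - region$start
  depth <- integer(width)
  keep <- reads$contig == region$contig
  if (!any(keep)) return(depth)
  nb <- lengths(reads$starts[keep])
  s <- unlist(reads$starts[keep], use.names = FALSE)
  e <- unlist(reads$ends[keep], use.names = FALSE)
  s <- pmax(s, region$start); e <- pmin(e, region$end)
  ok <- e > s
  if (!any(ok)) return(depth)
  cov <- IRanges::coverage(
    IRanges::IRanges(start = s[ok] - region$start + 1L, end = e[ok] - region$start),
    width = width)
  as.integer(cov)
}

#' Call candidate sncRNA loci as read clusters
#'
#' Clusters are maximal covered runs (per-base depth >= 1) of the aligned
#' blocks of intronic (`iR`) and intergenic (`IR`) reads; runs separated by
#' at most `merge_gap` uncovered positions are merged. A cluster's
#' `read_count` is the number of distinct reads overlapping it; clusters
#' with fewer than `min_reads` reads (default 20, the discovery threshold)
#' or shorter than `min_length` nt are discarded. Cluster boundaries are
#' the min start / max end of member reads. Context is `intronic` when the
#' cluster lies fully inside an intron record, else `intergenic`; strand
#' is the majority strand of member reads (ties and strandless reads give
#' `.`).
#'
#' @param reads reads data frame.
#' @param assignments feature assignments for exactly these reads; only
#'   labels `iR` and `IR` are allowed (pre-filter with [assign_reads()]).
#' @param features feature data frame (used for intron context).
#' @param min_reads minimum distinct reads per cluster (default 20).
#' @param merge_gap merge covered runs separated by at most this many
#'   uncovered positions (default 0).
#' @param min_length minimum candidate length in nt (default 50, the lower
#'   bound of the size-selected library).
#' @param refine_frac candidate boundaries are trimmed to the outermost
#'   positions whose depth is at least this fraction of the cluster's peak
#'   depth (default 0.5), which recovers the mature RNA ends from pileups
#'   with ragged 5'/3' processing; the raw min-start/max-end of member
#'   reads are kept in `raw_start`/`raw_end`. Set to 0 to disable.
#' @return candidate data frame: `candidate_id`, `contig`, `start`, `end`,
#'   `raw_start`, `raw_end`, `strand`, `read_count`, `max_depth`,
#'   `context`.
#' @export
call_clusters <- function(reads, assignments, features,
                          min_reads = 20, merge_gap = 0, min_length = 50,
                          refine_frac = 0.5) {
  validate_reads(reads)
  stopifnot(nrow(reads) == nrow(assignments))
  bad <- setdiff(unique(assignments$label), c("iR", "IR"))
  if (length(bad) > 0)
    stop("call_clusters expects only iR/IR reads; found label(s): ",
         paste(bad, collapse = ", "), " (pre-filter with assign_reads)")
  empty <- data.frame(candidate_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      raw_start = integer(0), raw_end = integer(0),
                      strand = character(0), read_count = integer(0),
                      max_depth = integer(0), context = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(empty)
  bgr <- blocks_granges(reads)
  GenomicRanges::strand(bgr) <- "*"
  runs <- GenomicRanges::reduce(bgr, min.gapwidth = as.integer(merge_gap) + 1L)
  hits <- GenomicRanges::findOverlaps(bgr, runs, ignore.strand = TRUE)
  ridx <- S4Vectors::mcols(bgr)$read_idx[S4Vectors::queryHits(hits)]
  per_run_reads <- lapply(split(ridx, S4Vectors::subjectHits(hits)), unique)
  run_ids <- as.integer(names(per_run_reads))
  counts <- lengths(per_run_reads)
  widths <- GenomicRanges::width(runs)[run_ids]
  keep <- counts >= min_reads & widths >= min_length
  if (!any(keep)) return(empty)
  run_ids <- run_ids[keep]
  per_run_reads <- per_run_reads[keep]
  counts <- counts[keep]

  contig <- as.character(GenomicRanges::seqnames(runs))[run_ids]
  start0 <- GenomicRanges::start(runs)[run_ids] - 1L
  end0 <- GenomicRanges::end(runs)[run_ids]

  strand <- vapply(per_run_reads, function(ix) {
    s <- reads$strand[ix]
    np <- sum(s == "+"); nm <- sum(s == "-")
    if (np > nm) "+" else if (nm > np) "-" else "."
  }, character(1))

  raw_start <- start0; raw_end <- end0
  max_depth <- integer(length(run_ids))
  for (k in seq_along(run_ids)) {
    depth <- pileup(reads[per_run_reads[[k]], , drop = FALSE],
                    list(contig = contig[k], start = start0[k], end = end0[k]))
    max_depth[k] <- max(depth)
    if (refine_frac > 0) {
      core <- which(depth >= refine_frac * max_depth[k])
      start0[k] <- raw_start[k] + core[1] - 1L
      end0[k] <- raw_start[k] + core[length(core)]
    }
  }
  keep2 <- end0 - start0 >= min_length
  run_ids <- run_ids[keep2]; per_run_reads <- per_run_reads[keep2]
  counts <- counts[keep2]; contig <- contig[keep2]
  start0 <- start0[keep2]; end0 <- end0[keep2]
  raw_start <- raw_start[keep2]; raw_end <- raw_end[keep2]
  max_depth <- max_depth[keep2]; strand <- strand[keep2]
  if (length(run_ids) == 0) return(empty)

  introns <- features[features$feature_class == "iR", , drop = FALSE]
  context <- vapply(seq_along(run_ids), function(k) {
    inside <- introns$contig == contig[k] &
      introns$start <= start0[k] & end0[k] <= introns$end
    if (any(inside)) "intronic" else "intergenic"
  }, character(1))

  ord <- order(contig, start0)
  out <- data.frame(
    candidate_id = sprintf("cand_%d", seq_along(run_ids)),
    contig = contig[ord], start = start0[ord], end = end0[ord],
    raw_start = raw_start[ord], raw_end = raw_end[ord],
    strand = strand[ord], read_count = as.integer(counts[ord]),
    max_depth = max_depth[ord], context = context[ord],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fill candidate sequences from the genome
#'
#' Extracts the genomic substring for each candidate, reverse-complements
#' it for minus-strand candidates, and normalises `T` to `U`.
#'
#' @param candidates candidate data frame.
#' @param genome a [Biostrings::DNAStringSet] (or FASTA path).
#' @return `candidates` with a `sequence` column (RNA alphabet).
#' @export
extract_sequences <- function(candidates, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  seqs <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ctg <- candidates$contig[i]
    if (!ctg %in% names(genome))
      stop("contig not in genome for candidate ", candidates$candidate_id[i])
    glen <- Biostrings::width(genome[ctg])
    if (candidates$start[i] < 0 || candidates$end[i] > glen)
      stop("interval out of genome bounds for candidate ",
           candidates$candidate_id[i])
    s <- Biostrings::subseq(genome[[ctg]], candidates$start[i] + 1L,
                            candidates$end[i])
    if (identical(candidates$strand[i], "-"))
      s <- Biostrings::reverseComplement(s)
    seqs[i] <- as_rna(as.character(s))
  }
  candidates$sequence <- seqs
  candidates
}

#' Order statistics of candidate lengths
#'
#' @param candidates candidate data frame (non-empty).
#' @return list with `mean`, `median`, `min`, `max` of candidate lengths
#'   in nt.
#' @export
size_statistics <- function(candidates) {
  if (nrow(candidates) == 0) stop("no candidates: size statistics undefined")
  len <- candidates$end - candidates$start
  list(mean = mean(len), median = stats::median(len),
       min = min(len), max = max(len))
}
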