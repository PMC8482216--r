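`%||%` <- function(a, b) if (is.null(a)) b else a

str_reverse <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of an RNA/DNA string
#'
#' Operates on plain character vectors; `T` is treated as `U` so that DNA
#' input yields RNA output.
#'
#' @param x character vector of sequences over `A,C,G,U,T`.
#' @return character vector of reverse complements in the RNA alphabet.
#' @export
revcomp_rna <- function(x) {
  str_reverse(chartr("ACGUTacgut", "UGCAAugcaa", x))
}

as_rna <- function(x) chartr("Tt", "Uu", toupper(x))
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
feature_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
}

# one GRanges row per aligned block, with the owning read's row index
blocks_granges <- function(reads) {
  if (nrow(reads) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$read_idx <- integer(0)
    return(gr)
  }
  nb <- lengths(reads$starts)
  idx <- rep(seq_len(nrow(reads)), nb)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(reads$contig, nb),
    ranges = IRanges::IRanges(
      start = unlist(reads$starts, use.names = FALSE) + 1L,
      end = unlist(reads$ends, use.names = FALSE)
    ),
    strand = ifelse(rep(reads$strand, nb) %in% c("+", "-"),
                    rep(reads$strand, nb), "*")
  )
  S4Vectors::mcols(gr)$read_idx <- idx
  gr
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sample", "contig", "strand", "mapq",
                  "starts", "ends") %in% names(reads)))
  invisible(reads)
}

empty_reads <- function() {
  data.frame(
    read_id = character(0), sample = character(0), contig = character(0),
    strand = character(0), mapq = integer(0),
    starts = I(list()), ends = I(list()),
    stringsAsFactors = FALSE
  )
}

jaccard_interval <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  ifelse(uni > 0, inter / uni, 0)
}
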