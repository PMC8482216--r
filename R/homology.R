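#' Local alignment with affine gaps
#'
#' Smith–Waterman local alignment under a nucleotide-BLAST-like scoring
#' scheme. A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param query,subject sequences (RNA or DNA alphabet; compared as
#'   uppercase RNA).
#' @param match,mismatch,gap_open,gap_extend integer scores (penalties
#'   negative); defaults `+2/-3/-5/-2`.
#' @return list with `score`, `query_start`/`query_end` and
#'   `subject_start`/`subject_end` (0-based half-open spans of the aligned
#'   region), `matches`, `columns`, `identity` (matches / alignment
#'   columns).
#' @export
local_align <- function(query, subject, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2) {
  .sw_align_cpp(as_rna(query), as_rna(subject), as.integer(match),
                as.integer(mismatch), as.integer(gap_open),
                as.integer(gap_extend))
}

#' Build a k-mer seed index over a reference of known sncRNAs
#'
#' Indexes every k-mer of each reference sequence and of its reverse
#' complement, so queries can seed on either strand.
#'
#' @param reference named character vector of sequences, or a FASTA path.
#'   FASTA description lines may carry a `family=<tag>` token
#'   (miRNA/snRNA/snoRNA/tRNA/other); otherwise family is `other`.
#' @param families optional character vector of family tags parallel to
#'   `reference` (overrides FASTA tags).
#' @param k k-mer size (default 11).
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(reference, families = NULL, k = 11) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    ss <- Biostrings::readBStringSet(reference)
    full_names <- names(ss)
    seqs <- as_rna(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", full_names)
    if (is.null(families)) {
      fam <- regmatches(full_names, regexpr("family=[A-Za-z]+", full_names))
      families <- rep("other", length(seqs))
      has <- grepl("family=", full_names)
      families[has] <- sub("family=", "", fam)
    }
    reference <- seqs
  } else {
    reference <- as_rna(reference)
    if (is.null(families)) families <- rep("other", length(reference))
  }
  ids <- names(reference)
  if (is.null(ids) || any(!nzchar(ids))) stop("reference sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate subject IDs in reference")
  if (any(nchar(reference) < k)) stop("reference sequences shorter than k")
  post <- new.env(parent = emptyenv())
  add <- function(seq, id, strand) {
    L <- nchar(seq)
    for (o in 0:(L - k)) {
      km <- substr(seq, o + 1, o + k)
      post[[km]] <- rbind(post[[km]],
                          data.frame(subject = id, offset = o, strand = strand,
                                     stringsAsFactors = FALSE))
    }
  }
  for (i in seq_along(reference)) {
    add(reference[[i]], ids[i], "+")
    add(revcomp_rna(reference[[i]]), ids[i], "-")
  }
  structure(list(postings = post, k = k, sequences = reference,
                 families = stats::setNames(families, ids)),
            class = "kmer_index")
}

#' Assign a candidate to a known sncRNA family by seeded local alignment
#'
#' Query k-mers are looked up in the index; the `top_n` subjects with the
#' most shared seeds (per strand) are aligned with [local_align()] and the
#' best hit passing the identity and query-coverage thresholds is
#' returned. Ties break by `(score, identity, subject_id)`.
#'
#' @param sequence candidate sequence.
#' @param index a `kmer_index` from [build_kmer_index()].
#' @param min_identity minimum alignment identity (default 0.8).
#' @param min_coverage minimum fraction of the query covered by the
#'   alignment (default 0.5).
#' @param top_n number of seeded subjects to align (default 5).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return one-row data frame (`subject_id`, `subject_family`, `identity`,
#'   `query_coverage`, `alignment_score`, `strand`) or `NULL` when nothing
#'   passes.
#' @export
assign_family <- function(sequence, index, min_identity = 0.8,
                          min_coverage = 0.5, top_n = 5,
                          match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  stopifnot(inherits(index, "kmer_index"))
  q <- as_rna(sequence)
  L <- nchar(q)
  k <- index$k
  if (L < k) return(NULL)
  seeds <- list()
  for (o in 0:(L - k)) {
    km <- substr(q, o + 1, o + k)
    p <- index$postings[[km]]
    if (!is.null(p)) seeds[[length(seeds) + 1]] <- p
  }
  if (length(seeds) == 0) return(NULL)
  seeds <- do.call(rbind, seeds)
  key <- paste(seeds$subject, seeds$strand)
  tab <- sort(table(key), decreasing = TRUE)
  take <- names(tab)[seq_len(min(top_n, length(tab)))]
  best <- NULL
  for (ks in sort(take)) {
    parts <- strsplit(ks, " ", fixed = TRUE)[[1]]
    sid <- parts[1]; strand <- parts[2]
    subj <- index$sequences[[sid]]
    if (strand == "-") subj <- revcomp_rna(subj)
    aln <- local_align(q, subj, match, mismatch, gap_open, gap_extend)
    coverage <- (aln$query_end - aln$query_start) / L
    if (aln$identity < min_identity || coverage < min_coverage) next
    cand <- data.frame(subject_id = sid,
                       subject_family = unname(index$families[sid]),
                       identity = aln$identity, query_coverage = coverage,
                       alignment_score = aln$score, strand = strand,
                       stringsAsFactors = FALSE)
    if (is.null(best) ||
        cand$alignment_score > best$alignment_score ||
        (cand$alignment_score == best$alignment_score &&
         cand$identity > best$identity) ||
        (cand$alignment_score == best$alignment_score &&
         cand$identity == best$identity &&
         cand$subject_id < best$subject_id)) {
      best <- cand
    }
  }
  best
}

#' Assign families for all candidates
#'
#' @param candidates candidate data frame with sequences.
#' @param index a `kmer_index`.
#' @param ... passed to [assign_family()].
#' @return `candidates` with `homology_subject`, `homology_family`,
#'   `homology_identity` columns (`NA` where no hit passes).
#' @export
assign_families <- function(candidates, index, ...) {
  candidates$homology_subject <- NA_character_
  candidates$homology_family <- NA_character_
  candidates$homology_identity <- NA_real_
  for (i in seq_len(nrow(candidates))) {
    hit <- assign_family(candidates$sequence[i], index, ...)
    if (!is.null(hit)) {
      candidates$homology_subject[i] <- hit$subject_id
      candidates$homology_family[i] <- hit$subject_family
      candidates$homology_identity[i] <- hit$identity
    }
  }
  candidates
}
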