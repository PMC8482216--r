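#' Link an intronic candidate to its host gene
#'
#' An intronic candidate is assigned to the gene whose intron fully
#' contains it; when introns of several genes contain it, the intron whose
#' boundaries are nearest (i.e. the smallest containing intron) wins, with
#' a deterministic lexicographic tie-break on gene id.
#'
#' @param candidate one-row candidate data frame (needs `contig`, `start`,
#'   `end`, `context`).
#' @param features feature data frame with `iR` records carrying
#'   `gene_id`.
#' @return the host `gene_id`, or `NA_character_` for intergenic
#'   candidates.
#' @export
link_host <- function(candidate, features) {
  if (!identical(candidate$context, "intronic")) return(NA_character_)
  introns <- features[features$feature_class == "iR" &
                        features$contig == candidate$contig &
                        features$start <= candidate$start &
                        candidate$end <= features$end, , drop = FALSE]
  if (nrow(introns) == 0)
    stop("intronic candidate ", candidate$candidate_id %||% "?",
         " is not inside any intron record (inconsistent upstream labeling)")
  genes <- unique(introns$gene_id)
  if (length(genes) > 1) {
    width <- introns$end - introns$start
    introns <- introns[order(width, introns$gene_id), , drop = FALSE]
    message("candidate ", candidate$candidate_id %||% "?",
            " lies in introns of several genes (",
            paste(genes, collapse = ", "), "); choosing ",
            introns$gene_id[1])
  }
  introns$gene_id[1]
}

#' Link every candidate to a host gene
#'
#' @param candidates candidate data frame.
#' @param features feature data frame.
#' @return `candidates` with a `host_gene_id` column.
#' @export
link_hosts <- function(candidates, features) {
  candidates$host_gene_id <- vapply(seq_len(nrow(candidates)), function(i) {
    link_host(candidates[i, , drop = FALSE], features)
  }, character(1))
  candidates
}

#' Pearson correlation of two expression vectors
#'
#' Counts are log(x+1)-transformed by default before the product-moment
#' correlation is computed.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param log_transform log(x+1)-transform before correlating (default
#'   `TRUE`).
#' @return the correlation `r`, or `NA` (with a warning) when either
#'   vector has zero variance.
#' @export
pearson <- function(x, y, log_transform = TRUE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 samples for a correlation")
  if (log_transform) { x <- log(x + 1); y <- log(y + 1) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Candidate/host expression correlation report
#'
#' @param pairs data frame with `candidate_id` and `host_gene_id`.
#' @param candidate_counts numeric matrix (rows = candidate ids, cols =
#'   samples).
#' @param host_counts numeric matrix (rows = gene ids, same sample
#'   columns).
#' @param log_transform passed to [pearson()].
#' @return list with `table` (one `CorrelationResult` row per pair:
#'   `candidate_id`, `host_gene_id`, `r`, `n_samples`, `defined`) and
#'   `mean_r` (mean over pairs with defined `r`; `NA` when none).
#' @export
correlation_report <- function(pairs, candidate_counts, host_counts,
                               log_transform = TRUE) {
  miss_s <- union(setdiff(colnames(candidate_counts), colnames(host_counts)),
                  setdiff(colnames(host_counts), colnames(candidate_counts)))
  if (length(miss_s) > 0)
    stop("sample columns missing from one matrix: ",
         paste(miss_s, collapse = ", "))
  miss_c <- setdiff(pairs$candidate_id, rownames(candidate_counts))
  miss_h <- setdiff(pairs$host_gene_id, rownames(host_counts))
  if (length(miss_c) > 0 || length(miss_h) > 0)
    stop("pairs missing from count matrices: ",
         paste(c(miss_c, miss_h), collapse = ", "))
  samples <- colnames(candidate_counts)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(pearson(candidate_counts[pairs$candidate_id[i], samples],
                             host_counts[pairs$host_gene_id[i], samples],
                             log_transform = log_transform))
  }, numeric(1))
  tab <- data.frame(candidate_id = pairs$candidate_id,
                    host_gene_id = pairs$host_gene_id,
                    r = r, n_samples = length(samples),
                    defined = !is.na(r), stringsAsFactors = FALSE)
  list(table = tab,
       mean_r = if (any(tab$defined)) mean(tab$r[tab$defined]) else NA_real_)
}
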