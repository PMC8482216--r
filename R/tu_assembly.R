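#' Extract splice junctions from spliced alignments
#'
#' Every gap between consecutive aligned blocks of a read is one junction
#' observation; observations are aggregated by
#' `(contig, donor, acceptor, strand)` and junctions supported by fewer
#' than `min_support` spliced reads are dropped.
#'
#' @param reads reads data frame.
#' @param min_support minimum spliced-read support (default 2).
#' @return data frame of junctions: `contig`, `donor` (0-based first
#'   intronic base), `acceptor` (exclusive end of the intron), `strand`,
#'   `support`.
#' @export
extract_junctions <- function(reads, min_support = 2) {
  validate_reads(reads)
  obs <- list()
  multi <- which(lengths(reads$starts) > 1)
  for (i in multi) {
    s <- reads$starts[[i]]; e <- reads$ends[[i]]
    nb <- length(s)
    obs[[length(obs) + 1]] <- data.frame(
      contig = reads$contig[i], donor = e[-nb], acceptor = s[-1],
      strand = reads$strand[i], stringsAsFactors = FALSE)
  }
  if (length(obs) == 0)
    return(data.frame(contig = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      support = integer(0), stringsAsFactors = FALSE))
  obs <- do.call(rbind, obs)
  key <- paste(obs$contig, obs$donor, obs$acceptor, obs$strand, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    contig = vapply(parts, `[[`, character(1), 1),
    donor = as.integer(vapply(parts, `[[`, character(1), 2)),
    acceptor = as.integer(vapply(parts, `[[`, character(1), 3)),
    strand = vapply(parts, `[[`, character(1), 4),
    support = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$contig, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

covered_runs <- function(reads, contig, from, to) {
  keep <- reads$contig == contig
  if (!any(keep))
    return(data.frame(start = integer(0), end = integer(0)))
  s <- unlist(reads$starts[keep], use.names = FALSE)
  e <- unlist(reads$ends[keep], use.names = FALSE)
  ok <- e > from & s < to
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  red <- IRanges::reduce(IRanges::IRanges(start = s[ok] + 1L, end = e[ok]))
  data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' Assemble a transcriptional unit around an intergenic candidate
#'
#' Searches junctions within `window` nt of the candidate for an intron
#' `[donor, acceptor)` strictly containing the candidate interval (best
#' junction by support, then smallest intron, then leftmost). Exons are
#' the maximal covered runs (depth >= 1 in the supplied total-RNA reads)
#' abutting the donor and acceptor, extended outward until coverage drops
#' to zero or a further compatible junction is met, in which case the exon
#' chain continues through it. Returns `NULL` when no containing intron is
#' evidenced (candidate autonomous or host undetected). Outer exon edges
#' are coverage-defined and flagged `soft_edge`.
#'
#' @param candidate one-row candidate data frame with
#'   `context == "intergenic"`.
#' @param junctions junction data frame from [extract_junctions()].
#' @param reads total-RNA reads used for exonic coverage.
#' @param window search window around the candidate in nt (default 10000).
#' @param max_exons chain-extension guard per side (default 10).
#' @return an object of class `transcriptional_unit` (list with `tu_id`,
#'   `contig`, `strand`, `exons` data frame, `hosted_candidate_id`,
#'   `hosting_intron_index` (0-based), `min_junction_support`), or `NULL`.
#' @export
assemble_tu <- function(candidate, junctions, reads, window = 10000,
                        max_exons = 10) {
  if (!identical(candidate$context, "intergenic"))
    stop("assemble_tu expects an intergenic candidate")
  j <- junctions[junctions$contig == candidate$contig &
                   junctions$donor < candidate$start &
                   junctions$acceptor > candidate$end &
                   junctions$donor >= candidate$start - window &
                   junctions$acceptor <= candidate$end + window, , drop = FALSE]
  if (nrow(j) == 0) return(NULL)
  j <- j[order(-j$support, j$acceptor - j$donor, j$donor), , drop = FALSE]
  host <- j[1, , drop = FALSE]
  from <- candidate$start - window; to <- candidate$end + window
  runs <- covered_runs(reads, candidate$contig, from, to)
  run_at <- function(pos) {
    # covered run containing base `pos` (0-based)
    hit <- which(runs$start <= pos & pos < runs$end)
    if (length(hit) == 0) NULL else runs[hit[1], , drop = FALSE]
  }
  jn <- junctions[junctions$contig == candidate$contig, , drop = FALSE]
  used_support <- host$support

  # walk left from a donor: exon ends at `donor`, starts at the covered
  # run boundary or at the acceptor of the next junction met
  left_exons <- list()
  donor <- host$donor
  for (step in seq_len(max_exons)) {
    run <- run_at(donor - 1L)
    if (is.null(run)) return(NULL) # donor flank not covered: no exon evidence
    inner <- jn[jn$acceptor >= run$start & jn$acceptor < donor &
                  jn$donor < jn$acceptor, , drop = FALSE]
    if (nrow(inner) > 0) {
      nxt <- inner[order(-inner$acceptor, -inner$support), , drop = FALSE][1, , drop = FALSE]
      left_exons[[length(left_exons) + 1]] <-
        data.frame(start = nxt$acceptor, end = donor, soft_edge = FALSE)
      used_support <- c(used_support, nxt$support)
      donor <- nxt$donor
    } else {
      left_exons[[length(left_exons) + 1]] <-
        data.frame(start = run$start, end = donor, soft_edge = TRUE)
      break
    }
  }
  right_exons <- list()
  acceptor <- host$acceptor
  for (step in seq_len(max_exons)) {
    run <- run_at(acceptor)
    if (is.null(run)) return(NULL)
    inner <- jn[jn$donor > acceptor & jn$donor <= run$end &
                  jn$acceptor > jn$donor, , drop = FALSE]
    if (nrow(inner) > 0) {
      nxt <- inner[order(inner$donor, -inner$support), , drop = FALSE][1, , drop = FALSE]
      right_exons[[length(right_exons) + 1]] <-
        data.frame(start = acceptor, end = nxt$donor, soft_edge = FALSE)
      used_support <- c(used_support, nxt$support)
      acceptor <- nxt$acceptor
    } else {
      right_exons[[length(right_exons) + 1]] <-
        data.frame(start = acceptor, end = run$end, soft_edge = TRUE)
      break
    }
  }
  exons <- rbind(do.call(rbind, rev(left_exons)), do.call(rbind, right_exons))
  exons <- exons[exons$end > exons$start, , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) < 2) return(NULL)
  structure(list(
    tu_id = paste0("tu_", candidate$candidate_id %||% "x"),
    contig = candidate$contig,
    strand = host$strand,
    exons = exons,
    hosted_candidate_id = candidate$candidate_id %||% NA_character_,
    hosting_intron_index = length(left_exons) - 1L,
    min_junction_support = min(used_support)
  ), class = "transcriptional_unit")
}

#' @export
print.transcriptional_unit <- function(x, ...) {
  cat(sprintf("TU %s on %s(%s): %d exons, hosts %s in intron %d (min junction support %d)\n",
              x$tu_id, x$contig, x$strand, nrow(x$exons),
              x$hosted_candidate_id, x$hosting_intron_index,
              x$min_junction_support))
  print(x$exons, row.names = FALSE)
  invisible(x)
}

#' Assemble TUs for all intergenic candidates
#'
#' @param candidates candidate data frame.
#' @param junctions junction data frame.
#' @param reads total-RNA reads.
#' @param ... passed to [assemble_tu()].
#' @return named list (by candidate_id) of `transcriptional_unit` objects
#'   or `NULL`s, covering exactly the intergenic candidates.
#' @export
assemble_tus <- function(candidates, junctions, reads, ...) {
  ig <- which(candidates$context == "intergenic")
  tus <- lapply(ig, function(i)
    assemble_tu(candidates[i, , drop = FALSE], junctions, reads, ...))
  names(tus) <- candidates$candidate_id[ig]
  tus
}

#' Reclassify intergenic candidates by TU evidence
#'
#' @param candidates candidate data frame.
#' @param tus list from [assemble_tus()].
#' @return data frame of `candidate_id` and `status`
#'   (`intron_hosted_novel_TU` when a TU was assembled around it,
#'   `autonomous_or_unknown` otherwise); one row per intergenic candidate.
#' @export
classify_intergenic <- function(candidates, tus) {
  ig <- candidates$candidate_id[candidates$context == "intergenic"]
  status <- vapply(ig, function(id) {
    if (!is.null(tus[[id]])) "intron_hosted_novel_TU" else "autonomous_or_unknown"
  }, character(1))
  data.frame(candidate_id = ig, status = unname(status),
             stringsAsFactors = FALSE)
}
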