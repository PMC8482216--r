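iupac_sets <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Scan a sequence for an IUPAC motif allowing mismatches
#'
#' Finds every offset inside `window` where the motif (IUPAC ambiguity
#' codes allowed, e.g. the C box `RUGAUGA` with `R = A or G`, or the H box
#' `ANANNA`) matches with at most `max_mismatch` mismatching positions.
#' The full motif must lie inside the window. Hits are sorted by
#' `(mismatches, position)`.
#'
#' @param seq RNA sequence (character scalar; `T` is read as `U`).
#' @param motif IUPAC motif string.
#' @param window 0-based half-open `[start, end)` window of `seq` to scan;
#'   default the whole sequence.
#' @param max_mismatch maximum mismatching positions (default 0).
#' @param box optional label stored in the `box` column (default the motif
#'   itself).
#' @return data frame of hits: `box`, `position` (0-based offset of the
#'   match start in `seq`), `matched`, `mismatches`.
#' @export
scan_motif <- function(seq, motif, window = NULL, max_mismatch = 0,
                       box = motif) {
  s <- strsplit(as_rna(seq), "", fixed = TRUE)[[1]]
  m <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(m, names(iupac_sets))
  if (length(bad) > 0)
    stop("invalid IUPAC code in motif: ", paste(bad, collapse = ", "))
  n <- length(s); k <- length(m)
  if (is.null(window)) window <- c(0L, n)
  if (window[1] < 0 || window[2] > n)
    stop("window outside sequence")
  empty <- data.frame(box = character(0), position = integer(0),
                      matched = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  offsets <- seq.int(window[1], window[2] - k)
  if (window[2] - window[1] < k) return(empty)
  # ok[p, ] : does motif position p match sequence position (offset + p)?
  mm <- vapply(offsets, function(o) {
    sum(vapply(seq_len(k), function(p) !(s[o + p] %in% iupac_sets[[m[p]]]),
               logical(1)))
  }, integer(1))
  hit <- which(mm <= max_mismatch)
  if (length(hit) == 0) return(empty)
  res <- data.frame(
    box = box,
    position = offsets[hit],
    matched = vapply(offsets[hit],
                     function(o) paste(s[(o + 1):(o + k)], collapse = ""),
                     character(1)),
    mismatches = mm[hit],
    stringsAsFactors = FALSE)
  res[order(res$mismatches, res$position), , drop = FALSE]
}
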