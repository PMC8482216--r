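#' Maximum nested base pairing of an RNA sequence
#'
#' Dynamic program over nested AU/GC/GU pairs with a minimum hairpin loop
#' of `min_loop` unpaired bases; returns the maximum pair count and one
#' optimal structure in dot-bracket notation. Used as transparent
#' secondary-structure evidence in the snoRNA class cascade.
#'
#' @param seq RNA sequence (character scalar; `T` is read as `U`).
#' @param min_loop minimum number of unpaired bases inside a hairpin loop
#'   (default 3).
#' @param forbid integer vector of 0-based positions forced to stay
#'   unpaired (used to test whether a motif can sit in a loop).
#' @return list with `pairs` (integer) and `structure` (dot-bracket
#'   string).
#' @export
fold_maxpairs <- function(seq, min_loop = 3, forbid = integer(0)) {
  s <- as_rna(seq)
  if (grepl("[^ACGU]", s))
    stop("invalid character in sequence (expected A/C/G/U)")
  .nussinov_cpp(s, as.integer(min_loop), as.integer(forbid))
}
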