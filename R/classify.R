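#' Parameters of the rule-based snoRNA class cascade
#'
#' Defaults encode the canonical class definitions: a C box (`RUGAUGA`)
#' near the 5' end plus a D box (`CUGA`) near the 3' end with a terminal
#' stem for C/D snoRNAs; an H box (`ANANNA`) in a single-stranded hinge
#' between two hairpins plus an `ACA` triplet a fixed offset from the 3'
#' end for H/ACA snoRNAs; and additionally a CAB box inside a hairpin loop
#' for scaRNAs. The CAB consensus is not fixed in the literature consulted
#' here and defaults to `UGAG`; every threshold is exposed.
#'
#' @param c_box,d_box,h_box,cab_box IUPAC motifs.
#' @param c_window,d_window nt windows at the 5'/3' ends that must contain
#'   the C and D boxes (defaults 16/16, allowing a few nt of slop in the
#'   called 5'/3' boundaries).
#' @param c_max_mismatch,d_max_mismatch,h_max_mismatch,cab_max_mismatch
#'   allowed mismatches per box (defaults 1, 0, 1, 0).
#' @param aca_offset the `ACA` triplet must end exactly this many nt
#'   before the 3' end (default 3).
#' @param aca_tol tolerance on `aca_offset` in nt (default 2), absorbing
#'   small uncertainty in the called 3' boundary; the most central
#'   matching offset is used.
#' @param terminal_arm nt taken from each terminus for the C/D terminal
#'   stem fold (default 15).
#' @param s_min minimum terminal-stem score, as fraction of 7 pairs
#'   (default 0.5).
#' @param hinge_window fraction of the sequence scanned for the H box
#'   (default central `c(0.3, 0.7)`).
#' @param min_arm_pairs minimum base pairs in each of the two H/ACA
#'   hairpin arms (default 4).
#' @param min_arm_stack each H/ACA arm must contain a helix of at least
#'   this many contiguous stacked pairs (default 6); random sequence
#'   rarely sustains long clean helices, so this carries most of the
#'   structural specificity.
#' @param max_h_hits at most this many minimal-mismatch H-box hits are
#'   evaluated as hinge splits (default 8).
#' @param cab_slack a CAB hit counts as loop-hosted if forcing it unpaired
#'   costs at most this many pairs relative to the optimum (default 1).
#' @param min_loop minimum hairpin loop size for folding (default 3).
#' @param min_length,max_length sequence length bounds; outside them the
#'   call is `unknown` (defaults 50/400).
#' @param weights named weights of box quality and structure score in the
#'   confidence (default 0.5/0.5).
#' @return a named list of parameters.
#' @export
sno_params <- function(c_box = "RUGAUGA", d_box = "CUGA", h_box = "ANANNA",
                       cab_box = "UGAG",
                       c_window = 16, d_window = 16,
                       c_max_mismatch = 1, d_max_mismatch = 0,
                       h_max_mismatch = 1, cab_max_mismatch = 0,
                       aca_offset = 3, aca_tol = 2,
                       terminal_arm = 15, s_min = 0.5,
                       hinge_window = c(0.3, 0.7), min_arm_pairs = 4,
                       min_arm_stack = 6,
                       max_h_hits = 8, cab_slack = 1, min_loop = 3,
                       min_length = 50, max_length = 400,
                       weights = c(box = 0.5, structure = 0.5)) {
  as.list(environment())
}

max_pairs_possible <- function(len, min_loop) {
  max(0L, (len - min_loop) %/% 2)
}

# pair table from dot-bracket: matrix of (open, close) 0-based positions
db_pairs <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  open <- integer(0); close <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i - 1L)
    else if (chars[i] == ")") {
      open <- c(open, stack[length(stack)]); close <- c(close, i - 1L)
      stack <- stack[-length(stack)]
    }
  }
  cbind(open = open, close = close)
}

# longest run of contiguous stacked pairs (i,j),(i+1,j-1),... in a
# dot-bracket structure
max_stack_run <- function(db) {
  pr <- db_pairs(db)
  if (nrow(pr) == 0) return(0L)
  key <- paste(pr[, "open"], pr[, "close"])
  is_start <- !(paste(pr[, "open"] - 1L, pr[, "close"] + 1L) %in% key)
  best <- 0L
  for (r in which(is_start)) {
    i <- pr[r, "open"]; j <- pr[r, "close"]; run <- 1L
    while (paste(i + 1L, j - 1L) %in% key) {
      i <- i + 1L; j <- j - 1L; run <- run + 1L
    }
    if (run > best) best <- run
  }
  best
}

# Can a CAB hit sit unpaired inside a loop? Mask its positions, refold,
# accept if the loss is within `cab_slack` pairs and the masked structure
# encloses the hit in at least one pair.
cab_in_loop <- function(seq, params) {
  n <- nchar(seq)
  hits <- scan_motif(seq, params$cab_box, max_mismatch = params$cab_max_mismatch,
                     box = "CAB")
  if (nrow(hits) == 0) return(NULL)
  full <- fold_maxpairs(seq, params$min_loop)
  k <- nchar(params$cab_box)
  for (r in seq_len(nrow(hits))) {
    p <- hits$position[r]
    masked <- fold_maxpairs(seq, params$min_loop, forbid = p:(p + k - 1))
    if (full$pairs - masked$pairs > params$cab_slack) next
    pr <- db_pairs(masked$structure)
    if (nrow(pr) > 0 && any(pr[, "open"] < p & pr[, "close"] > p + k - 1))
      return(hits[r, , drop = FALSE])
  }
  NULL
}

#' Classify one candidate sequence as C/D, H/ACA, scaRNA or unknown
#'
#' A transparent rule cascade over box motifs and maximum-base-pairing
#' structure (see [sno_params()] for every rule and threshold):
#' * `CD` — C box in the first `c_window` nt, D box in the last `d_window`
#'   nt, and a terminal stem between the 5'/3' termini scoring at least
#'   `s_min`.
#' * `HACA` — `ACA` ending `aca_offset` (+/- `aca_tol`) nt from the 3'
#'   end, an H box in the central hinge window, and a bipartite fold: both
#'   arms flanking the chosen H box form at least `min_arm_pairs` pairs
#'   and contain a helix of `min_arm_stack` stacked pairs. Among
#'   minimal-mismatch H hits the split maximising the weaker arm is used.
#' * `SCA_CD` / `SCA_HACA` — the class requirement plus a CAB box that can
#'   sit unpaired inside a hairpin loop.
#' * `SCA_TANDEM` — both CD and HACA requirements plus a loop-hosted CAB.
#' * otherwise `unknown`.
#'
#' When both single classes pass but no CAB box is found, the
#' higher-confidence class is reported and the conflict noted.
#'
#' @param seq candidate sequence (RNA alphabet; `T` read as `U`).
#' @param params parameter list from [sno_params()].
#' @return an object of class `sno_class_call`: list with `label`,
#'   `box_hits` (data frame), `structure_score`, `confidence`, `note`.
#' @export
classify_candidate <- function(seq, params = sno_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  call_out <- function(label, box_hits, structure_score, confidence,
                       note = NA_character_) {
    structure(list(label = label, box_hits = box_hits,
                   structure_score = structure_score,
                   confidence = confidence, note = note),
              class = "sno_class_call")
  }
  no_hits <- data.frame(box = character(0), position = integer(0),
                        matched = character(0), mismatches = integer(0),
                        stringsAsFactors = FALSE)
  if (n < params$min_length || n > params$max_length || grepl("[^ACGU]", seq))
    return(call_out("unknown", no_hits, NA_real_, 0))

  w <- params$weights / sum(params$weights)

  ## --- C/D branch -----------------------------------------------------
  c_hits <- scan_motif(seq, params$c_box,
                       window = c(0L, min(params$c_window, n)),
                       max_mismatch = params$c_max_mismatch, box = "C")
  d_hits <- scan_motif(seq, params$d_box,
                       window = c(max(0L, n - params$d_window), n),
                       max_mismatch = params$d_max_mismatch, box = "D")
  cd <- NULL
  if (nrow(c_hits) > 0 && nrow(d_hits) > 0) {
    arm <- min(params$terminal_arm, n %/% 2)
    stem <- fold_maxpairs(paste0(substr(seq, 1, arm),
                                 substr(seq, n - arm + 1, n)),
                          params$min_loop)
    ts <- stem$pairs / 7
    if (ts >= params$s_min) {
      # D-box hits lie near the 3' end; prefer the rightmost minimal-mm hit
      d_best <- d_hits[d_hits$mismatches == min(d_hits$mismatches), , drop = FALSE]
      d_best <- d_best[which.max(d_best$position), , drop = FALSE]
      q <- mean(c(1 - c_hits$mismatches[1] / (params$c_max_mismatch + 1),
                  1 - d_best$mismatches[1] / (params$d_max_mismatch + 1)))
      cd <- list(hits = rbind(c_hits[1, , drop = FALSE], d_best),
                 score = min(ts, 1),
                 confidence = unname(w["box"] * q + w["structure"] * min(ts, 1)))
    }
  }

  ## --- H/ACA branch ---------------------------------------------------
  haca <- NULL
  # most central matching ACA offset within the tolerance window
  offs <- params$aca_offset + c(0, -seq_len(params$aca_tol), seq_len(params$aca_tol))
  offs <- offs[params$aca_offset + params$aca_tol >= offs & offs >= 0]
  aca_start <- NA_integer_ # 1-based start of the ACA triplet
  for (o in offs) {
    st <- n - o - 2
    if (st >= 1 && substr(seq, st, st + 2) == "ACA") { aca_start <- st; break }
  }
  if (!is.na(aca_start)) {
    win <- c(floor(params$hinge_window[1] * n),
             ceiling(params$hinge_window[2] * n))
    win[2] <- min(win[2], n)
    h_hits <- scan_motif(seq, params$h_box, window = win,
                         max_mismatch = params$h_max_mismatch, box = "H")
    if (nrow(h_hits) > 0) {
      cand_hits <- h_hits[h_hits$mismatches == min(h_hits$mismatches), , drop = FALSE]
      cand_hits <- cand_hits[order(cand_hits$position), , drop = FALSE]
      if (nrow(cand_hits) > params$max_h_hits)
        cand_hits <- cand_hits[seq_len(params$max_h_hits), , drop = FALSE]
      hk <- nchar(params$h_box)
      best <- NULL
      for (r in seq_len(nrow(cand_hits))) {
        p <- cand_hits$position[r]
        l5 <- p
        l3 <- (aca_start - 1) - (p + hk)
        f5 <- if (l5 > params$min_loop + 1)
          fold_maxpairs(substr(seq, 1, l5), params$min_loop)
          else list(pairs = 0L, structure = "")
        f3 <- if (l3 > params$min_loop + 1)
          fold_maxpairs(substr(seq, p + hk + 1, aca_start - 1),
                        params$min_loop)
          else list(pairs = 0L, structure = "")
        p5 <- f5$pairs; p3 <- f3$pairs
        key <- c(min(p5, p3), p5 + p3, -p)
        if (is.null(best) ||
            key[1] > best$key[1] ||
            (key[1] == best$key[1] && key[2] > best$key[2]) ||
            (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3])) {
          best <- list(key = key, hit = cand_hits[r, , drop = FALSE],
                       p5 = p5, p3 = p3, l5 = l5, l3 = l3,
                       s5 = f5$structure, s3 = f3$structure)
        }
      }
      if (!is.null(best) && min(best$p5, best$p3) >= params$min_arm_pairs &&
          min(max_stack_run(best$s5), max_stack_run(best$s3)) >=
            params$min_arm_stack) {
        denom <- max_pairs_possible(best$l5, params$min_loop) +
          max_pairs_possible(best$l3, params$min_loop)
        sc <- if (denom > 0) (best$p5 + best$p3) / denom else 0
        aca_hit <- data.frame(box = "ACA", position = aca_start - 1L,
                              matched = "ACA", mismatches = 0L,
                              stringsAsFactors = FALSE)
        q <- mean(c(1 - best$hit$mismatches / (params$h_max_mismatch + 1), 1))
        haca <- list(hits = rbind(best$hit, aca_hit), score = min(sc, 1),
                     confidence = unname(w["box"] * q + w["structure"] * min(sc, 1)))
      }
    }
  }

  if (is.null(cd) && is.null(haca))
    return(call_out("unknown", no_hits, NA_real_, 0))

  cab <- cab_in_loop(seq, params)
  if (!is.null(cd) && !is.null(haca)) {
    hits <- rbind(cd$hits, haca$hits)
    if (!is.null(cab))
      return(call_out("SCA_TANDEM", rbind(hits, cab),
                      mean(c(cd$score, haca$score)),
                      mean(c(cd$confidence, haca$confidence))))
    pick_cd <- cd$confidence >= haca$confidence
    return(call_out(if (pick_cd) "CD" else "HACA",
                    if (pick_cd) cd$hits else haca$hits,
                    if (pick_cd) cd$score else haca$score,
                    if (pick_cd) cd$confidence else haca$confidence,
                    note = "both CD and HACA rules passed without a CAB box"))
  }
  one <- if (!is.null(cd)) cd else haca
  base <- if (!is.null(cd)) "CD" else "HACA"
  if (!is.null(cab))
    return(call_out(paste0("SCA_", base), rbind(one$hits, cab),
                    one$score, one$confidence))
  call_out(base, one$hits, one$score, one$confidence)
}

#' @export
print.sno_class_call <- function(x, ...) {
  cat("snoRNA class call:", x$label,
      sprintf("(confidence %.2f, structure score %s)\n", x$confidence,
              ifelse(is.na(x$structure_score), "NA",
                     sprintf("%.2f", x$structure_score))))
  if (nrow(x$box_hits) > 0) {
    cat("boxes:\n")
    print(x$box_hits, row.names = FALSE)
  }
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Classify all candidates in a table
#'
#' @param candidates candidate data frame with a `sequence` column (see
#'   [extract_sequences()]).
#' @param params parameter list from [sno_params()].
#' @return `candidates` with columns `sno_class`, `confidence`,
#'   `structure_score` and `boxes` (collapsed `box@pos:mism` string) added.
#' @export
classify_candidates <- function(candidates, params = sno_params()) {
  calls <- lapply(candidates$sequence, classify_candidate, params = params)
  candidates$sno_class <- vapply(calls, `[[`, character(1), "label")
  candidates$confidence <- vapply(calls, `[[`, numeric(1), "confidence")
  candidates$structure_score <- vapply(calls, `[[`, numeric(1), "structure_score")
  candidates$boxes <- vapply(calls, function(cl) {
    if (nrow(cl$box_hits) == 0) return("")
    paste(sprintf("%s@%d:%d", cl$box_hits$box, cl$box_hits$position,
                  cl$box_hits$mismatches), collapse = ";")
  }, character(1))
  candidates
}
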