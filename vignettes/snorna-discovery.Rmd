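---
title: "Discovering snoRNAs from size-selected RNA-seq: methods and design"
author: "snoscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering snoRNAs from size-selected RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoscout)
```

# The problem and the procedure

Human snoRNAs are mostly 50–200 nt RNAs processed from spliced introns.
That size range falls between the windows of small-RNA-seq and standard
total RNA-seq, so a size-selected ("medium") library is sequenced instead
and the discovery question becomes computational: which read pileups in
intronic or intergenic space are unannotated small ncRNAs, which of those
are snoRNAs of which class, and do the "intergenic" ones actually mark
introns of unannotated host transcripts?

`snoscout` implements that procedure as six composable stages (feature
filtering, ≥20-read cluster calling, rule-based class prediction, k-mer
seeded homology, host-gene correlation, junction-graph TU assembly) plus
a synthetic-data generator that stands in for a real deposited dataset.
This vignette records the models behind each stage, the parameters that
matter, and the design decisions taken where the procedure was genuinely
underdetermined.

All internal coordinates are 0-based half-open; conversion to GFF3's
1-based closed convention happens only at the I/O boundary. The library's
strandedness is not assumed: strand `.` matches both strands in overlap
tests, and strand-respecting mode is a flag (`stranded`).

# Feature filtering

Each read collects the set of distinct feature classes overlapped by any
of its aligned blocks (1 bp suffices; there is no minimum-overlap
fraction, the simplest rule, exposed as `min_overlap`). No overlap means
intergenic (IR); one class is kept; two or more make the read MF
("multiple feature") and exclude it. Overlap with an annotated small
ncRNA or a repeat dominates everything else — such reads are not novel by
definition. Two records of the *same* class (introns of two genes, say)
leave a read uniquely labelled by default, because same-type ambiguity is
resolved later by host assignment; `same_class_is_unique = FALSE`
switches to the stricter reading.

The promoter window is not fixed by any convention we could adopt, so
promoters are derived as 1000 nt (configurable) upstream of each
transcript start, strand-reflected.

# Cluster calling and the 20-read rule

Candidates are maximal covered runs of intronic/intergenic reads, with
runs separated by at most `merge_gap` uncovered positions merged
(default 0). "At least 20 reads" is interpreted as **20 distinct reads
overlapping the run**, not per-base depth ≥ 20; read counting is the
natural reading of the rule and the threshold behaves as a sharp boundary
(a 19-read locus is silent, a 20-read locus is called — this is a test).
Reads are pooled across samples by default. Candidates shorter than
`min_length` (50 nt, the library's lower size bound) are dropped.

**Boundary refinement.** Real 5′/3′ processing and library artefacts blur
read ends; the generator models this as uniform ±J jitter (J = 5 nt) on
both read boundaries. The raw min-start/max-end of member reads then
overshoots the mature termini by up to J, which matters because two of
the class rules below are positional (the C/D windows and the 3′-ACA
offset). Candidate boundaries are therefore trimmed to the outermost
positions whose depth is at least half the cluster's peak
(`refine_frac = 0.5`). Under symmetric jitter the half-peak crossing is
an unbiased estimator of the mature boundary; its sampling noise at
25–80 reads is about ±1–2 nt, which the classifier's end tolerances
absorb (below). The untrimmed bounds are kept as `raw_start`/`raw_end`,
and `refine_frac = 0` disables the refinement entirely.

Candidate strand is the majority strand of member reads, with ties
reported as `.`.

# The class cascade

Machine-learning class predictors are deliberately not reproduced here:
their training data and weights are not available, and their scores have
no defined mapping onto anything recomputable. What *is* reproducible is
the class definitions themselves, so the classifier is a rule cascade
over box motifs and secondary structure, with every threshold exposed in
`sno_params()`:

* **Motifs.** C box `RUGAUGA` (≤1 mismatch), D box `CUGA` (exact), H box
  `ANANNA` (≤1 mismatch), ACA exact. Degenerate C and H boxes are
  tolerated because canonical snoRNA architecture tolerates them; the D
  and ACA boxes are short enough that any mismatch destroys their
  information content. IUPAC codes are matched by set membership; the
  scanner is position-equivariant and tested against a regex-expansion
  oracle.
* **Structure.** Secondary-structure evidence is maximum nested base
  pairing (AU/GC/GU, minimum hairpin loop 3 nt) computed by an O(n³)
  dynamic program in C++ with a deterministic traceback that prefers the
  most distant pairing partner, which keeps designed stems intact in
  reported structures. Maximum pairing is a deliberately transparent
  stand-in for free-energy folding: it over-pairs random sequence, so
  raw pair counts discriminate poorly and the cascade instead uses
  (a) a terminal-stem score for C/D — pairs formed by the concatenated
  5′ and 3′ termini (15 nt each), normalised by 7, threshold 0.5 — and
  (b) for H/ACA, a requirement that each hairpin arm contain a helix of
  at least `min_arm_stack = 6` contiguous stacked pairs. Long clean
  helices are rare in random sequence, so the stack rule carries most of
  the structural specificity (the test suite checks that ≥95% of random
  140-mers come out `unknown`).
* **C/D rule.** C box inside the first `c_window = 16` nt, D box inside
  the last `d_window = 16` nt, terminal-stem score ≥ `s_min = 0.5`. The
  windows are the canonical ~12 nt box placement plus the ±2–3 nt
  boundary-estimator noise discussed above.
* **H/ACA rule.** An `ACA` ending `aca_offset = 3` nt from the 3′ end
  (± `aca_tol = 2` nt, most central match preferred), an H box in the
  central `hinge_window = c(0.3, 0.7)` fraction of the sequence, and a
  bipartite fold. A random 50-nt window is expected to contain about one
  spurious `ANANNA` match, so the hinge split is not taken from the
  first hit: among minimal-mismatch hits (capped at `max_h_hits = 8`)
  the classifier picks the split maximising the weaker arm's pair count
  (ties: total pairs, then leftmost), then requires both arms to reach
  `min_arm_pairs = 4` pairs and the stack rule.
* **CAB rule (scaRNAs).** The CAB consensus is not fixed in the
  literature this design draws on; the default `UGAG` is an explicit
  stand-in and is configurable everywhere (classifier and generator). "In
  a hairpin apical loop" is operationalised structurally rather than read
  off one traceback: a CAB hit counts as loop-hosted when forcing its
  positions to stay unpaired costs at most `cab_slack = 1` pair relative
  to the unconstrained optimum *and* the constrained structure encloses
  the hit in at least one pair. Masked refolding is deterministic and
  robust to ties among optimal structures, where any single traceback is
  arbitrary.
* **Cascade.** Both C/D and H/ACA passing plus a loop CAB is
  `SCA_TANDEM`; both passing without a CAB reports the higher-confidence
  single class and notes the conflict; a single class with a CAB is
  `SCA_CD`/`SCA_HACA`; nothing passing, a sequence outside 50–400 nt, or
  non-ACGU characters give `unknown`. Confidence is an equally weighted
  sum of box quality (1 − mismatches/budget) and the structure score,
  bounded in [0, 1].

# Homology

The homology stage is a self-contained seeded local aligner: an 11-mer
index over both strands of the reference, alignment of the `top_n = 5`
most-seeded subjects with affine-gap Smith–Waterman (+2/−3, gap open −5,
extend −2; a gap of length L costs open + L·extend), and acceptance at
`min_identity = 0.8` over `min_coverage = 0.5` of the query, ties broken
by score, identity, then subject id. The scoring defaults mirror common
nucleotide-BLAST practice; no E-value statistics are computed — score,
identity and coverage thresholds are the whole decision. The DP is
verified against an independent R implementation and cross-checked
against `Biostrings::pairwiseAlignment` in the test suite. Reference
family labels ride along as `family=<tag>` tokens on FASTA description
lines.

# Host linking and correlation

An intronic candidate is assigned to the gene whose intron fully contains
it; among several containing introns the smallest (nearest boundaries)
wins, with a lexicographic tie-break, and the ambiguity is logged. Counts
are log(x+1)-transformed before Pearson correlation — the standard
transform for expression correlation; a raw mode exists. Pairs with zero
variance in either vector are flagged and excluded from the mean rather
than contributing an undefined value.

# TU assembly around intergenic candidates

Full transcript assembly (phasing, flow decomposition) is out of scope:
the question the pipeline asks is only *whether a containing intron is
evidenced*. Junctions are aggregated from the inter-block gaps of spliced
total-RNA alignments and filtered at `min_support = 2` spliced reads
(an alignment-noise filter; the hosting question needs no more). Within
±10 kb of the candidate, the best junction whose intron strictly contains
it (support, then smallest intron, then leftmost) anchors the TU; exons
grow from the covered runs abutting donor and acceptor and extend through
compatible junctions. Junction-defined exon edges are exact; outer edges
are coverage-defined, hence approximate, and flagged `soft_edge`.
Candidates with a TU are reclassified `intron_hosted_novel_TU`, the rest
`autonomous_or_unknown`. Coverage thresholds are config-exposed because
nuclear-restricted, weakly expressed hosts may warrant laxer settings
than the defaults.

# The synthetic-data generator

The generator emulates the *structure* of a real size-selected dataset:
a single ~200 kb contig with twelve 3-exon genes; 30 planted snoRNAs
(10 C/D, 10 H/ACA, 10 scaRNA) split ~70/30 between intronic placements
(≥30 nt inside intron boundaries) and intergenic placements (≥1 kb from
any gene); 10 random-sequence decoy loci; and 4 intergenic snoRNAs seated
in the central intron of an unannotated two-exon transcriptional unit
whose exonic coverage and junction reads appear only in the simulated
total-RNA alignments. Planted sequences satisfy their class definitions
by construction (terminal stems and boxes for C/D; perfect-stem hairpins,
hinge H box and 3′ ACA for H/ACA; additionally a loop-hosted CAB for
scaRNAs), with rejection sampling that keeps plain classes free of
accidental CAB boxes, near-3′ ACA triplets, or C/D box pairs, so truth
labels are recoverable by an independent motif oracle at 100%.

Read depth per locus is negative binomial (mean 50, dispersion 0.3) —
the standard over-dispersed model for sequencing counts; no depth model
was prescribed, so this is the field's default. Planted loci are clamped
to ≥25 reads and decoys drawn uniformly from 5–19 reads, implementing
the stated construction that planted loci exceed and decoys fall below
the 20-read threshold (the clamp is skipped when the configured mean is
below 20, so degenerate zero-depth configurations still produce empty
alignments). Read ends jitter uniformly ±5 nt around locus boundaries
and lengths are clipped to the 50–200 nt insert window. Expression
matrices come from a bivariate log-normal: latent log-abundances with
correlation `r_target`, exponentiated and rounded; a host gene shared by
several candidates keeps one latent profile.

What the generator does **not** model — sequencing errors, quality
strings, PCR duplicates, multi-mapping, expression-dependent coverage
biases, overlapping genes, alternative splicing — bounds what passing
tests show: they demonstrate the pipeline's logic is correct under the
stated read model, not that the thresholds are optimal for any real
library.

# Numerical and degenerate-input conventions

* Candidate ordering (and hence IDs `cand_1…`) is by contig then start;
  all tie-breaks in homology, H-splits, hosting-junction choice and host
  assignment are total orders, so identical inputs and seeds give
  byte-identical outputs (tested via md5).
* Empty inputs return empty, well-typed tables; `size_statistics` on an
  empty candidate set and correlations on < 3 samples are errors, not
  silent NAs; zero-variance correlation vectors warn and return `NA`.
* CIGAR support is deliberately M/N/S/I/D only (S/I consume no
  reference, D consumes reference within a block, N splits blocks);
  anything else is a parse error naming the line, which is preferable to
  silently mis-walking exotic alignments.
* Reads on contigs missing from the annotation are IR with a warning.

# Problem sizes in the test suite

The suite exercises: the full pipeline on the 200 kb / 30-locus / 10-decoy
/ 4-TU conditions; cluster calling against an O(n²) brute-force oracle on
100 random read sets (20–60 reads each); motif scanning against the
regex-expansion oracle on 5000 random 200-mers; folding against
exhaustive structure enumeration for 200 sequences of ≤12 nt; seeded
homology against all-pairs Smith–Waterman on eight ≤30 nt references;
and correlation recovery at targets {−0.9, 0, 0.31, 0.9} with 12 samples
and 250–2000 Monte-Carlo replicates (the r = 0 case uses 2000 because a
single replicate's r has standard deviation ≈ 0.30 at n = 12). These
sizes make every oracle comparison exact or statistically sharp while
keeping the default run short.

# Known limitations

* Maximum base pairing is not thermodynamics; pseudo-knots, G-quadruplexes
  and modified bases are invisible to it.
* The CAB consensus default is a stand-in; real scaRNA calling should
  override it with a curated motif.
* Boundary refinement assumes roughly symmetric end raggedness; strongly
  asymmetric degradation would bias the recovered termini and with them
  the positional box checks.
* Homology has no significance model; a hit is whatever clears
  identity/coverage thresholds against the supplied reference.
* TU assembly reports a single best exon chain — sufficient for "is there
  a containing intron", not for isoform structure, and TU abundance is
  not quantified.
* No differential analysis between cell states is included; the pipeline
  stops at discovery, classification and host evidence.
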