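#' Write a complete synthetic dataset to disk
#'
#' Generates the toy genome, annotation, truth tables, size-selected
#' medium-RNA alignments, total-RNA alignments over the planted TUs, and a
#' small known-sncRNA reference; everything is deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with the generated objects and a `paths` list.
#' @export
simulate_dataset <- function(config, dir) {
  gen <- generate_genome(config, dir = dir)
  paths <- gen$paths
  paths$alignments <- file.path(dir, "alignments.tsv")
  paths$total_alignments <- file.path(dir, "total_alignments.tsv")
  paths$known <- file.path(dir, "known_sncRNAs.fa")
  gen$reads <- simulate_reads(gen$truth, config, features = gen$features,
                              path = paths$alignments)
  gen$tu_reads <- simulate_tu_reads(gen$tu_truth, config,
                                    path = paths$total_alignments)
  gen$reference <- generate_reference(config, path = paths$known)
  gen$paths <- paths
  gen
}

#' Pipeline configuration
#'
#' Bundles input paths, thresholds and modes for [run_all()]. Unknown
#' arguments are rejected. Thresholds default to the discovery settings
#' (20-read clusters, 50-nt minimum size, promoter window 1 kb).
#'
#' @param genome genome FASTA path.
#' @param alignments size-selected alignment file (SAM dialect or
#'   simplified TSV).
#' @param annotation_gff optional GFF3 annotation.
#' @param bed_paths named list of BED files per feature class (see
#'   [read_annotation()]).
#' @param total_alignments optional total-RNA alignment file for TU
#'   assembly.
#' @param known_fasta optional known-sncRNA reference FASTA for homology.
#' @param candidate_counts,host_counts optional count TSVs for the
#'   correlation stage (rows keyed by candidate / gene id).
#' @param min_mapq,min_reads,merge_gap,min_length,stranded,
#'   same_class_is_unique,promoter_width stage thresholds.
#' @param sno classifier parameters from [sno_params()].
#' @param min_identity,min_coverage homology thresholds.
#' @param junction_min_support,tu_window TU-assembly thresholds.
#' @param expression_r when no count files are given, simulate
#'   candidate/host counts at this latent correlation for the linked
#'   pairs (`NULL` disables the correlation stage).
#' @param expression_n_samples samples for simulated expression
#'   (default 12).
#' @param seed global seed echoed in the summary and used by any
#'   simulated stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome, alignments, annotation_gff = NULL,
                            bed_paths = list(), total_alignments = NULL,
                            known_fasta = NULL, candidate_counts = NULL,
                            host_counts = NULL, min_mapq = 0, min_reads = 20,
                            merge_gap = 0, min_length = 50, stranded = FALSE,
                            same_class_is_unique = TRUE,
                            promoter_width = 1000, sno = sno_params(),
                            min_identity = 0.8, min_coverage = 0.5,
                            junction_min_support = 2, tu_window = 10000,
                            expression_r = NULL, expression_n_samples = 12,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Executes feature assignment, cluster calling, classification, homology,
#' host linking, expression correlation and TU assembly, writing every
#' stage table plus a machine-readable `summary.json` and a `run_log.txt`
#' into `out_dir`. Any stage failure aborts with the stage name and leaves
#' a `FAILED` marker; an existing non-empty `out_dir` is refused unless
#' `force = TRUE`. Outputs are byte-identical across reruns with the same
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir result directory.
#' @param force overwrite an existing result directory (default `FALSE`).
#' @return invisibly, a list with `candidates`, `composition`,
#'   `correlations`, `tus`, `tu_classification`, `summary`, `paths`.
#' @export
run_all <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("result directory ", out_dir,
         " exists and is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("snoscout run", paste0("seed: ", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage: ", name),
                   conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  p <- function(f) file.path(out_dir, f)

  reads <- stage("read-alignments",
                 read_alignments(config$alignments, min_mapq = config$min_mapq))
  features <- stage("read-annotation",
                    read_annotation(config$annotation_gff, config$bed_paths,
                                    promoter_width = config$promoter_width))
  log_lines <- c(log_lines, sprintf("reads: %d", nrow(reads)),
                 sprintf("features: %d", nrow(features)))

  assignments <- stage("assign", {
    idx <- build_feature_index(features)
    assign_reads(reads, idx, stranded = config$stranded,
                 same_class_is_unique = config$same_class_is_unique)
  })
  comp <- composition_summary(assignments)
  utils::write.table(assignments, p("assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comp, p("composition.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  candidates <- stage("call-clusters", {
    keep <- assignments$label %in% c("iR", "IR")
    call_clusters(reads[keep, , drop = FALSE],
                  assignments[keep, , drop = FALSE], features,
                  min_reads = config$min_reads, merge_gap = config$merge_gap,
                  min_length = config$min_length)
  })
  log_lines <- c(log_lines, sprintf("candidates: %d", nrow(candidates)))

  genome <- stage("genome", read_genome(config$genome))
  if (nrow(candidates) > 0) {
    candidates <- stage("extract-sequences",
                        extract_sequences(candidates, genome))
    candidates <- stage("classify",
                        classify_candidates(candidates, config$sno))
    if (!is.null(config$known_fasta)) {
      candidates <- stage("homology", {
        kidx <- build_kmer_index(config$known_fasta)
        assign_families(candidates, kidx,
                        min_identity = config$min_identity,
                        min_coverage = config$min_coverage)
      })
    }
    candidates <- stage("link-hosts", link_hosts(candidates, features))
  }
  write_candidates(candidates, p("candidates.bed"))
  class_cols <- intersect(c("candidate_id", "context", "sno_class",
                            "confidence", "structure_score", "boxes",
                            "homology_subject", "homology_family",
                            "homology_identity", "host_gene_id"),
                          names(candidates))
  utils::write.table(candidates[, class_cols, drop = FALSE],
                     p("class_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  corr <- NULL
  pairs <- if (nrow(candidates) > 0)
    candidates[candidates$context == "intronic" &
                 !is.na(candidates$host_gene_id),
               c("candidate_id", "host_gene_id"), drop = FALSE]
  else data.frame(candidate_id = character(0), host_gene_id = character(0))
  corr <- stage("correlate", {
    if (nrow(pairs) > 0 &&
        (!is.null(config$candidate_counts) || !is.null(config$expression_r))) {
      if (!is.null(config$candidate_counts)) {
        cc <- read_counts(config$candidate_counts)
        hc <- read_counts(config$host_counts)
      } else {
        sim <- simulate_expression(pairs, config$expression_r,
                                   config$expression_n_samples,
                                   seed = config$seed + 4L)
        cc <- sim$candidate_counts; hc <- sim$host_counts
      }
      correlation_report(pairs, cc, hc)
    } else NULL
  })
  if (!is.null(corr)) {
    utils::write.table(corr$table, p("correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("mean r: %.6f", corr$mean_r))
  }

  tus <- NULL; tu_class <- NULL
  if (!is.null(config$total_alignments) && nrow(candidates) > 0) {
    tu_res <- stage("assemble-tu", {
      treads <- read_alignments(config$total_alignments)
      jx <- extract_junctions(treads,
                              min_support = config$junction_min_support)
      tus <- assemble_tus(candidates, jx, treads, window = config$tu_window)
      list(tus = tus, tu_class = classify_intergenic(candidates, tus))
    })
    tus <- tu_res$tus; tu_class <- tu_res$tu_class
    write_tu_gff3(Filter(Negate(is.null), tus), p("tus.gff3"))
    utils::write.table(tu_class, p("tu_classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_reads = nrow(reads),
    composition = comp,
    n_candidates = nrow(candidates),
    candidates_by_context = if (nrow(candidates) > 0)
      as.list(table(candidates$context)) else list(),
    candidates_by_class = if (nrow(candidates) > 0 &&
                              "sno_class" %in% names(candidates))
      as.list(table(candidates$sno_class)) else list(),
    size_statistics = if (nrow(candidates) > 0)
      size_statistics(candidates) else NULL,
    mean_r = if (!is.null(corr)) corr$mean_r else NULL,
    tu_status = if (!is.null(tu_class)) as.list(table(tu_class$status))
      else list()
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "status: OK"), p("run_log.txt"))
  invisible(list(candidates = candidates, composition = comp,
                 correlations = corr, tus = tus,
                 tu_classification = tu_class, summary = summary,
                 paths = out_dir))
}
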