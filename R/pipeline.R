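# End-to-end orchestration: simulate or load a cohort, detect elements,
# classify them, build the reference-element null, cluster, compute
# distance statistics and (when tracks are available) the enrichment
# analyses. All outputs are standard formats plus a JSON run manifest.

#' Pipeline configuration
#'
#' @param k,min_length,strand_mode detection parameters (see
#'   [detect_uces()]).
#' @param cluster_gap `"median"` (use the observed median inter-element
#'   gap, the rule behind the 18 kb threshold of the original analysis)
#'   or a fixed number of nt.
#' @param n_null distance-null replicate count.
#' @param flank gene-ranking flank in nt.
#' @param unique_reference require reference elements to map uniquely.
#' @param seed master seed; stage-level seeds are derived from it.
#' @export
pipeline_config <- function(k = 50L, min_length = 50L, strand_mode = "both",
                            cluster_gap = "median", n_null = 100L,
                            flank = 10000L, unique_reference = TRUE,
                            seed = 1L) {
  stopifnot(identical(cluster_gap, "median") || is.numeric(cluster_gap))
  structure(list(k = as.integer(k), min_length = as.integer(min_length),
                 strand_mode = strand_mode, cluster_gap = cluster_gap,
                 n_null = as.integer(n_null), flank = as.integer(flank),
                 unique_reference = unique_reference,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage_index) {
  (config$seed + 7919L * stage_index) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: detect, classify, reference-element
#' null, cluster, distances, and, when tracks are supplied, the factor
#' enrichment scan and multifunctionality analysis. Required inputs are
#' checked before any stage executes; every stage's output is written
#' even when empty, and the manifest records per-stage row counts,
#' seeds and input checksums. The manifest is written atomically at run
#' end.
#'
#' @param cohort a [genome_cohort()], or a list of FASTA paths
#'   `list(reference =, queries = c(...))`.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param annotations optional [annotation_set()] for classification.
#' @param peak_sets optional named list of per-factor peak `GRanges`
#'   (required if `run_enrichment = TRUE`).
#' @param editing optional `GRanges` of RNA-editing sites.
#' @param run_enrichment run the factor scan and multifunctionality
#'   stages (pre-flight fails if tracks are missing).
#' @return list with the stage results (`uces`, `classes`, `reference`,
#'   `clusters`, `distances`, `enrichment`, `multifun`, `manifest`),
#'   invisibly; files are written under `out_dir`.
#' @export
run_uce_pipeline <- function(cohort, out_dir, config = pipeline_config(),
                             annotations = NULL, peak_sets = NULL,
                             editing = NULL, run_enrichment = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  # pre-flight: resolve and validate all inputs before any stage runs
  if (is.list(cohort) && !inherits(cohort, "genome_cohort")) {
    paths <- c(cohort$reference, cohort$queries)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("missing input file: ", missing[1])
    cohort <- genome_cohort(
      read_genome_fasta(cohort$reference),
      stats::setNames(lapply(cohort$queries, read_genome_fasta),
                      basename(cohort$queries)))
  }
  stopifnot(inherits(cohort, "genome_cohort"))
  if (run_enrichment && (is.null(peak_sets) || length(peak_sets) == 0L)) {
    stop("enrichment stage requested but no peak sets supplied")
  }
  if (run_enrichment && is.null(annotations)) {
    stop("enrichment stage requested but no annotations supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  counts <- list()

  uces <- detect_uces(cohort, k = config$k, min_length = config$min_length,
                      strand_mode = config$strand_mode)
  results$uces <- uces
  counts$uces <- length(uces)
  write_bed(granges_with_score(uces), file.path(out_dir, "uces.bed"))
  if (length(uces)) {
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(uces$sequence), uces$name),
      file.path(out_dir, "uces.fa"), width = 60L)
  } else {
    file.create(file.path(out_dir, "uces.fa"))
  }

  if (!is.null(annotations)) {
    cls <- classify_elements(uces, annotations)
    uces$class <- as.character(cls)
    results$classes <- data.frame(name = uces$name, class = as.character(cls))
    counts$classes <- nrow(results$classes)
    write_tsv(results$classes, file.path(out_dir, "classes.tsv"))
  }

  ref_el <- generate_reference_elements(
    cohort$reference, lengths = if (length(uces)) GenomicRanges::width(uces)
                                else config$min_length,
    seed = stage_seed(config, 2L), unique_only = config$unique_reference)
  if (!is.null(annotations) && length(ref_el)) {
    ref_el$class <- as.character(classify_elements(ref_el, annotations))
  }
  results$reference <- ref_el
  counts$reference <- length(ref_el)
  write_bed(ref_el, file.path(out_dir, "reference_elements.bed"))

  gaps <- inter_element_gaps(uces)
  gap_threshold <- if (identical(config$cluster_gap, "median")) {
    if (length(gaps)) stats::median(gaps) else 0
  } else config$cluster_gap
  clusters <- cluster_elements(uces, gap_threshold)
  results$clusters <- clusters
  results$cluster_gap_threshold <- gap_threshold
  counts$clusters <- length(clusters)
  write_bed(clusters, file.path(out_dir, "clusters.bed"))

  dist <- distance_stats(uces, nchar(cohort$reference),
                         genome = if (config$unique_reference) cohort$reference,
                         n_null = config$n_null,
                         seed = stage_seed(config, 4L))
  results$distances <- dist
  counts$distances <- dist$n_observed_gaps
  write_tsv(data.frame(observed_median = dist$observed_median,
                       expected_median = dist$expected_median,
                       p_value = dist$p_value),
            file.path(out_dir, "distances.tsv"))

  if (run_enrichment) {
    keep <- uces$class != "ncRNA"  # ncRNA-overlapping elements excluded
    el <- uces[keep]
    el$class[el$class == "junction"] <- "exonic"
    re <- ref_el[ref_el$class != "ncRNA"]
    re$class[re$class == "junction"] <- "exonic"
    enr <- factor_scan(el, re, peak_sets)
    results$enrichment <- enr
    counts$enrichment <- nrow(enr)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

    mf <- multifunctionality(
      el, re,
      coding = annotations$exons,
      splice = splice_sites(annotations),
      editing = editing %||% GenomicRanges::GRanges(),
      peak_sets = peak_sets)
    results$multifun <- mf
    counts$multifun <- nrow(mf$profiles)
    write_tsv(mf$profiles, file.path(out_dir, "multifun.tsv"))
    write_tsv(combo_fold(mf$profiles, mf$reference_profiles),
              file.path(out_dir, "combo_folds.tsv"))
  }

  manifest <- list(
    tool = "ucekit",
    version = as.character(utils::packageVersion("ucekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    cluster_gap_threshold = gap_threshold,
    seeds = list(reference = stage_seed(config, 2L),
                 distances = stage_seed(config, 4L)),
    input_checksums = as.list(S4Vectors::metadata(uces)$manifest$genome_checksums),
    detection = S4Vectors::metadata(uces)$manifest[
      c("k", "min_length", "strand_mode", "n_seeds", "n_bisections")],
    row_counts = counts)
  tmp <- tempfile(tmpdir = out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

# BED score column = element length, as in the on-disk interface
granges_with_score <- function(uces) {
  if (length(uces) == 0L) return(GenomicRanges::granges(uces))
  out <- GenomicRanges::granges(uces)
  out$name <- uces$name
  out$score <- GenomicRanges::width(uces)
  out
}
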