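# Genomic context of detected elements: classification against gene
# models, the length-matched uniquely-mapping random-element null,
# single-linkage clustering, distance statistics and the gene ranking
# score used as input to GO-term analysis.

ELEMENT_CLASSES <- c("ncRNA", "exonic", "junction", "intronic", "intergenic")

#' Classify elements against gene models
#'
#' Each element receives exactly one class, by priority: overlapping any
#' annotated ncRNA makes it `ncRNA`; else overlapping at least one exon
#' and at least one intronic base of the same transcript makes it
#' `junction`; else any exon overlap makes it `exonic`; else lying inside
#' a gene span makes it `intronic`; everything else is `intergenic`. One
#' qualifying transcript suffices (any-gene, any-transcript rule).
#'
#' @param elements `GRanges` of elements in reference coordinates.
#' @param annotations an [annotation_set()].
#' @return factor of classes, one per element, levels
#'   `ncRNA, exonic, junction, intronic, intergenic`.
#' @export
classify_elements <- function(elements, annotations) {
  stopifnot(methods::is(elements, "GRanges"),
            inherits(annotations, "annotation_set"))
  n <- length(elements)
  cls <- rep("intergenic", n)
  ann_chroms <- unique(c(
    as.character(GenomicRanges::seqnames(annotations$genes)),
    as.character(GenomicRanges::seqnames(annotations$ncrna))))
  off <- !(as.character(GenomicRanges::seqnames(elements)) %in% ann_chroms)
  if (any(off)) {
    warning(sum(off), " element(s) on chromosomes absent from the ",
            "annotation; classified intergenic")
  }

  cls[IRanges::overlapsAny(elements, annotations$genes,
                           ignore.strand = TRUE)] <- "intronic"

  ex <- annotations$exons
  hit_ex <- GenomicRanges::findOverlaps(elements, ex, ignore.strand = TRUE)
  cls[unique(S4Vectors::queryHits(hit_ex))] <- "exonic"

  intr <- introns(annotations)
  hit_in <- GenomicRanges::findOverlaps(elements, intr, ignore.strand = TRUE)
  ex_pairs <- paste(S4Vectors::queryHits(hit_ex),
                    ex$transcript_id[S4Vectors::subjectHits(hit_ex)])
  in_pairs <- paste(S4Vectors::queryHits(hit_in),
                    intr$transcript_id[S4Vectors::subjectHits(hit_in)])
  junc <- unique(as.integer(sub(" .*", "", intersect(ex_pairs, in_pairs))))
  cls[junc] <- "junction"

  cls[IRanges::overlapsAny(elements, annotations$ncrna,
                           ignore.strand = TRUE)] <- "ncRNA"
  factor(cls, levels = ELEMENT_CLASSES)
}

#' Generate length-matched uniquely-mapping reference elements
#'
#' Tiles the genome left to right, chromosome by chromosome, drawing each
#' fragment length (with replacement, seeded) from the element length
#' multiset. Fragments containing N, or whose sequence is not unique in
#' the genome counting both strands, are discarded; the retained
#' fragments form the null cohort against which all enrichment statistics
#' are computed.
#'
#' @param genome reference genome (named character vector or
#'   `DNAStringSet`).
#' @param lengths integer vector: the element length multiset to match.
#' @param seed integer seed for the length draws.
#' @param unique_only require each fragment sequence to map uniquely
#'   (default `TRUE`).
#' @return `GRanges` of retained fragments with a `name` column.
#' @export
generate_reference_elements <- function(genome, lengths, seed = 1L,
                                        unique_only = TRUE) {
  genome <- as_genome(genome)
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) stop("length multiset must be non-empty")
  if (min(nchar(genome)) < min(lengths)) {
    if (max(nchar(genome)) < min(lengths)) {
      warning("genome shorter than the smallest fragment length")
      return(GenomicRanges::GRanges())
    }
  }
  dss <- Biostrings::DNAStringSet(genome)
  all_ch <- character(0); all_st <- integer(0); all_w <- integer(0)
  with_seed(seed, {
    for (ch in names(genome)) {
      L <- nchar(genome[[ch]])
      pos <- 0L
      repeat {
        len <- lengths[sample.int(length(lengths), 1L)]
        if (pos + len > L) break
        frag <- substr(genome[[ch]], pos + 1L, pos + len)
        ok <- !grepl("N", frag, fixed = TRUE)
        if (ok && unique_only) {
          ok <- count_genome_occurrences(frag, dss) == 1L
        }
        if (ok) {
          all_ch <- c(all_ch, ch); all_st <- c(all_st, pos + 1L)
          all_w <- c(all_w, len)
        }
        pos <- pos + len
      }
    }
  })
  if (length(all_st) == 0L) return(GenomicRanges::GRanges())
  gr <- sort(GenomicRanges::GRanges(all_ch,
                                    IRanges::IRanges(all_st, width = all_w)))
  gr$name <- sprintf("ref_%05d", seq_along(gr))
  gr
}

#' Single-linkage clustering of elements by genomic distance
#'
#' Chains consecutive same-chromosome elements whose gap (next start minus
#' previous end, half-open) is strictly below `gap_threshold`. A cluster
#' must have at least two members; chained singletons are not reported.
#'
#' @param elements `GRanges`, sorted or not (sorted internally).
#' @param gap_threshold gap threshold in nt (> 0); the original analysis
#'   used the observed median inter-element distance (18 kb).
#' @return `GRanges` of cluster spans with metadata columns `cluster_id`,
#'   `n_members` and `members` (comma-separated element names); per-class
#'   member counts are added when elements carry a `class` column.
#' @export
cluster_elements <- function(elements, gap_threshold) {
  stopifnot(methods::is(elements, "GRanges"), gap_threshold >= 0)
  if (length(elements) == 0L) return(GenomicRanges::GRanges())
  o <- order(as.character(GenomicRanges::seqnames(elements)),
             GenomicRanges::start(elements))
  el <- elements[o]
  chrom <- as.character(GenomicRanges::seqnames(el))
  gap <- GenomicRanges::start(el)[-1] - GenomicRanges::end(el)[-length(el)] - 1L
  same <- chrom[-1] == chrom[-length(chrom)]
  new_cluster <- c(TRUE, !(same & gap < gap_threshold))
  grp <- cumsum(new_cluster)
  keep <- as.integer(names(which(table(grp) >= 2L)))
  if (length(keep) == 0L) return(GenomicRanges::GRanges())
  rows <- lapply(seq_along(keep), function(i) {
    m <- el[grp == keep[i]]
    row <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(m))[1],
      start = min(GenomicRanges::start(m)),
      end = max(GenomicRanges::end(m)),
      cluster_id = sprintf("cluster_%03d", i),
      n_members = length(m),
      members = paste(m$name %||% seq_along(m), collapse = ","))
    if (!is.null(m$class)) {
      counts <- table(factor(as.character(m$class), levels = ELEMENT_CLASSES))
      for (cl in ELEMENT_CLASSES) row[[paste0("n_", cl)]] <- as.integer(counts[[cl]])
    }
    row
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- df[, -(1:3), drop = FALSE]
  gr
}

# gaps between consecutive same-chromosome elements (half-open convention:
# next start minus previous end)
inter_element_gaps <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr <- gr[o]
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr) < 2L) return(integer(0))
  gap <- GenomicRanges::start(gr)[-1] - GenomicRanges::end(gr)[-length(gr)] - 1L
  gap[chrom[-1] == chrom[-length(chrom)]]
}

#' Observed versus expected inter-element distances
#'
#' Distances are the gaps between consecutive same-chromosome elements.
#' The expected distribution is built by drawing, `n_null` times,
#' `length(elements)` random non-overlapping length-matched elements
#' (lengths resampled from the observed multiset; optionally required to
#' map uniquely when a genome is supplied), and pooling their gaps. The
#' expected median is the mean of the per-replicate medians; observed and
#' pooled null gaps are compared with a two-sided Mann-Whitney test
#' (normal approximation with tie correction for the large samples this
#' produces).
#'
#' @param elements `GRanges` of detected elements.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param genome optional genome for the unique-mapping filter on null
#'   draws.
#' @param n_null number of null replicates (default 100).
#' @param seed integer seed.
#' @return list with `observed_median`, `expected_median`, `p_value`,
#'   `n_observed_gaps`, `n_null_gaps`; medians are `NA` (flagged via
#'   `defined = FALSE`) with fewer than two elements.
#' @export
distance_stats <- function(elements, chrom_lengths, genome = NULL,
                           n_null = 100L, seed = 1L) {
  stopifnot(methods::is(elements, "GRanges"))
  if (length(elements) < 2L) {
    return(list(observed_median = NA_real_, expected_median = NA_real_,
                p_value = NA_real_, defined = FALSE,
                n_observed_gaps = 0L, n_null_gaps = 0L))
  }
  if (is.null(names(chrom_lengths))) {
    stop("chrom_lengths must be named by chromosome")
  }
  obs <- inter_element_gaps(elements)
  lens <- GenomicRanges::width(elements)
  dss <- if (!is.null(genome)) Biostrings::DNAStringSet(as_genome(genome)) else NULL
  gseq <- if (!is.null(genome)) as_genome(genome) else NULL

  null_gaps <- list(); null_medians <- numeric(0)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      draw_st <- integer(0); draw_w <- integer(0); draw_ch <- character(0)
      guard <- 0L
      while (length(draw_st) < length(elements) && guard < 50L * length(elements)) {
        guard <- guard + 1L
        w <- lens[sample.int(length(lens), 1L)]
        ch <- sample(names(chrom_lengths), 1L, prob = unlist(chrom_lengths))
        if (chrom_lengths[[ch]] < w) next
        st <- sample.int(chrom_lengths[[ch]] - w + 1L, 1L)
        clash <- any(draw_ch == ch & st <= draw_st + draw_w - 1L &
                       st + w - 1L >= draw_st)
        if (clash) next
        if (!is.null(dss)) {
          frag <- substr(gseq[[ch]], st, st + w - 1L)
          if (grepl("N", frag, fixed = TRUE)) next
          if (count_genome_occurrences(frag, dss) != 1L) next
        }
        draw_st <- c(draw_st, st); draw_w <- c(draw_w, w)
        draw_ch <- c(draw_ch, ch)
      }
      gr <- GenomicRanges::GRanges(draw_ch, IRanges::IRanges(draw_st, width = draw_w))
      g <- inter_element_gaps(gr)
      if (length(g)) {
        null_gaps[[r]] <- g
        null_medians <- c(null_medians, stats::median(g))
      }
    }
  })
  null_pool <- unlist(null_gaps)
  p <- if (length(null_pool)) {
    suppressWarnings(stats::wilcox.test(obs, null_pool)$p.value)
  } else NA_real_
  list(observed_median = stats::median(obs),
       expected_median = mean(null_medians),
       p_value = p, defined = TRUE,
       n_observed_gaps = length(obs), n_null_gaps = length(null_pool))
}

#' Rank genes by element density relative to the null cohort
#'
#' The score of a gene is the number of elements within the gene span
#' extended by `flank` nt on both sides, divided by the number of
#' reference elements in the same interval. Genes with zero reference
#' elements in their window are excluded (recorded in the `"excluded"`
#' attribute). This ranking is the input for downstream GO-term
#' enrichment tools.
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param elements,reference_elements `GRanges` cohorts to compare.
#' @param flank flank size in nt (default 10000).
#' @return data.frame (`gene_id`, `n_elements`, `n_reference`, `score`)
#'   sorted by descending score, ties broken by gene id.
#' @export
go_ranking_score <- function(genes, elements, reference_elements,
                             flank = 10000L) {
  stopifnot(methods::is(genes, "GRanges"), flank >= 0)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(genes) - flank),
                     GenomicRanges::end(genes) + flank))
  n_el <- GenomicRanges::countOverlaps(win, elements, ignore.strand = TRUE)
  n_ref <- GenomicRanges::countOverlaps(win, reference_elements,
                                        ignore.strand = TRUE)
  df <- data.frame(gene_id = genes$gene_id, n_elements = n_el,
                   n_reference = n_ref,
                   score = ifelse(n_ref > 0, n_el / n_ref, NA_real_))
  excluded <- df$gene_id[df$n_reference == 0L]
  df <- df[df$n_reference > 0L, , drop = FALSE]
  df <- df[order(-df$score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "excluded") <- excluded
  df
}
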