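# Overlap-based enrichment analyses: per-factor chi-square scans over
# element classes with joint BH correction, multifunctionality scoring,
# combination folds, the alternative-splicing overlap test and the
# exonic-splicing-enhancer motif scan.

direction_of <- function(testable, p_adj, fold, alpha) {
  ifelse(!testable, "untestable",
         ifelse(is.na(p_adj) | p_adj >= alpha, "ns",
                ifelse(fold > 1, "enriched", "depleted")))
}

#' Per-factor, per-class enrichment scan against the reference cohort
#'
#' For every combination of ChIP factor and element class, builds the 2x2
#' table of elements/reference elements overlapping (>= 1 shared base) at
#' least one peak of that factor and applies a chi-square test; BH
#' correction is applied jointly across the whole factor-by-class family.
#' Elements overlapping annotated ncRNAs are expected to have been
#' excluded upstream (they are not among the scanned classes).
#'
#' @param elements `GRanges` of detected elements with a `class` metadata
#'   column (from [classify_elements()]).
#' @param reference `GRanges` of reference elements with a `class` column.
#' @param peak_sets named list of `GRanges`, one per factor (optionally
#'   with a `stage` attribute).
#' @param classes element classes to scan (default intergenic, intronic,
#'   exonic; junction elements may be merged into `exonic` by the caller).
#' @param alpha adjusted-significance threshold for the reported
#'   direction (default 0.05).
#' @param yates apply Yates continuity correction (default `TRUE`).
#' @return data.frame with one row per factor x class: counts `a,b,c,d`,
#'   `fold`, `chi2`, `p`, `p_adj` and `direction`
#'   (`enriched`/`depleted`/`ns`/`untestable`).
#' @export
factor_scan <- function(elements, reference, peak_sets,
                        classes = c("intergenic", "intronic", "exonic"),
                        alpha = 0.05, yates = TRUE) {
  stopifnot(methods::is(elements, "GRanges"), methods::is(reference, "GRanges"))
  if (is.null(elements$class) || is.null(reference$class)) {
    stop("both cohorts need a `class` metadata column")
  }
  rows <- list()
  for (fac in names(peak_sets)) {
    pk <- peak_sets[[fac]]
    stage <- attr(pk, "stage") %||% NA_character_
    for (cl in classes) {
      el <- elements[as.character(elements$class) == cl]
      re <- reference[as.character(reference$class) == cl]
      if (length(pk) == 0L || length(el) == 0L || length(re) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = fac, stage = stage, class = cl,
          a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
          fold = NA_real_, chi2 = NA_real_, p = NA_real_,
          testable = FALSE)
        next
      }
      a <- sum(IRanges::overlapsAny(el, pk, ignore.strand = TRUE))
      b <- length(el) - a
      cc <- sum(IRanges::overlapsAny(re, pk, ignore.strand = TRUE))
      d <- length(re) - cc
      ht <- chi_square_2x2(a, b, cc, d, yates = yates)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fac, stage = stage, class = cl,
        a = a, b = b, c = cc, d = d,
        fold = ht$fold, chi2 = ht$statistic, p = ht$p,
        testable = ht$testable)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$direction <- direction_of(res$testable, res$p_adj, res$fold, alpha)
  res$testable <- NULL
  res
}

#' Per-element function flags and multifunctionality scores
#'
#' Flags each element for the four molecular functions: protein-coding
#' overlap, splice-site overlap (an exon terminal base adjacent to an
#' intron), presence of an RNA-editing site, and binding by at least one
#' factor (overlap with the union of all peak sets). All flags use the
#' >= 1 shared base rule. The score is the number of set flags (0-4);
#' tetrafunctional means all four.
#'
#' @param elements `GRanges` to profile.
#' @param coding `GRanges` of protein-coding intervals (e.g. coding
#'   exons).
#' @param splice `GRanges` of splice-site positions (see
#'   [splice_sites()]).
#' @param editing `GRanges` of RNA-editing sites.
#' @param peak_sets named list of per-factor peak `GRanges`.
#' @return data.frame with logical columns `coding`, `splice_site`,
#'   `editing`, `tf_bound` and integer `score`.
#' @export
function_profile <- function(elements, coding, splice, editing, peak_sets) {
  stopifnot(methods::is(elements, "GRanges"))
  all_peaks <- if (length(peak_sets)) {
    GenomicRanges::reduce(do.call(c, lapply(unname(peak_sets), function(g) {
      GenomicRanges::granges(g)
    })))
  } else GenomicRanges::GRanges()
  flag <- function(track) {
    if (length(track) == 0L) rep(FALSE, length(elements))
    else IRanges::overlapsAny(elements, track, ignore.strand = TRUE)
  }
  df <- data.frame(
    name = elements$name %||% sprintf("el_%05d", seq_along(elements)),
    coding = flag(coding),
    splice_site = flag(splice),
    editing = flag(editing),
    tf_bound = flag(all_peaks))
  df$score <- rowSums(df[, c("coding", "splice_site", "editing", "tf_bound")])
  df
}

#' Multifunctionality comparison between elements and the reference cohort
#'
#' Profiles both cohorts with [function_profile()] and compares the score
#' distributions with a two-sided Mann-Whitney test.
#'
#' @inheritParams function_profile
#' @param reference `GRanges` of reference elements.
#' @return list with `profiles`, `reference_profiles`, the score tables
#'   of both cohorts, and `p_value`.
#' @export
multifunctionality <- function(elements, reference, coding, splice, editing,
                               peak_sets) {
  pe <- function_profile(elements, coding, splice, editing, peak_sets)
  pr <- function_profile(reference, coding, splice, editing, peak_sets)
  mw <- mann_whitney(pe$score, pr$score)
  list(profiles = pe, reference_profiles = pr,
       score_table = table(factor(pe$score, levels = 0:4)),
       reference_score_table = table(factor(pr$score, levels = 0:4)),
       p_value = mw$p)
}

#' Fold enrichment of every function-flag combination
#'
#' Tabulates all 16 combinations of the four function flags in both
#' cohorts and reports, per combination, the proportion among elements,
#' among reference elements, and their ratio. A combination present in
#' the elements but absent from the reference has infinite fold (the
#' counts give the context); a combination absent from both is reported
#' with `NA` fold.
#'
#' @param profiles,reference_profiles data.frames from
#'   [function_profile()].
#' @return 16-row data.frame with flag columns, counts, proportions and
#'   `fold`.
#' @export
combo_fold <- function(profiles, reference_profiles) {
  stopifnot(nrow(profiles) > 0L, nrow(reference_profiles) > 0L)
  flags <- c("coding", "splice_site", "editing", "tf_bound")
  combos <- expand.grid(coding = c(FALSE, TRUE), splice_site = c(FALSE, TRUE),
                        editing = c(FALSE, TRUE), tf_bound = c(FALSE, TRUE))
  key <- function(df) apply(df[, flags, drop = FALSE], 1L, paste, collapse = "|")
  ck <- key(combos)
  n_e <- as.integer(table(factor(key(profiles), levels = ck)))
  n_r <- as.integer(table(factor(key(reference_profiles), levels = ck)))
  prop_e <- n_e / nrow(profiles)
  prop_r <- n_r / nrow(reference_profiles)
  # integer cross-ratio keeps round proportions exact (100/1000 vs 1/1000
  # gives fold 100, not 100 + floating-point noise)
  fold <- ifelse(n_e == 0L & n_r == 0L, NA_real_,
                 ifelse(n_r == 0L, Inf,
                        (as.numeric(n_e) * nrow(reference_profiles)) /
                          (as.numeric(n_r) * nrow(profiles))))
  out <- cbind(combos,
               data.frame(n_elements = n_e, n_reference = n_r,
                          prop_elements = prop_e, prop_reference = prop_r,
                          fold = fold))
  out$score <- rowSums(out[, flags])
  out[order(out$score, ck), c(flags, "score", "n_elements", "n_reference",
                              "prop_elements", "prop_reference", "fold")]
}

#' Overlap of exonic elements with alternatively spliced exons
#'
#' An element counts as alternatively-spliced-overlapping if it shares at
#' least one base with a non-constitutive exon. The element and reference
#' counts form a 2x2 chi-square test.
#'
#' @param elements `GRanges` of exonic elements.
#' @param exons `GRanges` of annotated exons carrying a logical
#'   `constitutive` column.
#' @param reference `GRanges` of exonic reference elements.
#' @param yates apply Yates correction.
#' @return one-row data.frame in the [factor_scan()] layout.
#' @export
alt_splicing_test <- function(elements, exons, reference, yates = TRUE) {
  stopifnot(methods::is(elements, "GRanges"), methods::is(reference, "GRanges"))
  if (length(exons) == 0L || is.null(exons$constitutive)) {
    return(data.frame(factor = "alt_splicing", stage = NA_character_,
                      class = "exonic", a = NA_integer_, b = NA_integer_,
                      c = NA_integer_, d = NA_integer_, fold = NA_real_,
                      chi2 = NA_real_, p = NA_real_, p_adj = NA_real_,
                      direction = "untestable"))
  }
  alt <- exons[!exons$constitutive]
  a <- sum(IRanges::overlapsAny(elements, alt, ignore.strand = TRUE))
  b <- length(elements) - a
  cc <- sum(IRanges::overlapsAny(reference, alt, ignore.strand = TRUE))
  d <- length(reference) - cc
  ht <- chi_square_2x2(a, b, cc, d, yates = yates)
  data.frame(factor = "alt_splicing", stage = NA_character_, class = "exonic",
             a = a, b = b, c = cc, d = d, fold = ht$fold,
             chi2 = ht$statistic, p = ht$p, p_adj = ht$p,
             direction = direction_of(ht$testable, ht$p, ht$fold, 0.05))
}

#' Scan element sequences for exonic-splicing-enhancer motifs
#'
#' An element matches a motif iff the motif is an exact substring of the
#' element's sense-strand sequence. Each motif gets a 2x2 chi-square test
#' of element versus reference match counts, with BH correction across
#' the motif family.
#'
#' @param element_seqs,reference_seqs character vectors of DNA sequences.
#' @param motifs character vector of motifs over ACGT (one test family;
#'   the original analysis used 99 putative enhancers).
#' @param alpha adjusted-significance threshold.
#' @param yates apply Yates correction.
#' @return data.frame with one row per motif: match counts, `fold`,
#'   `chi2`, `p`, `p_adj`, `direction`; empty for an empty motif list.
#' @export
ese_motif_scan <- function(element_seqs, reference_seqs, motifs,
                           alpha = 0.05, yates = TRUE) {
  if (length(motifs) == 0L) {
    return(data.frame(motif = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), fold = numeric(0),
                      chi2 = numeric(0), p = numeric(0), p_adj = numeric(0),
                      direction = character(0)))
  }
  motifs <- toupper(motifs)
  if (any(!grepl("^[ACGT]+$", motifs))) stop("motifs must be over ACGT")
  rows <- lapply(motifs, function(m) {
    a <- sum(grepl(m, element_seqs, fixed = TRUE))
    b <- length(element_seqs) - a
    cc <- sum(grepl(m, reference_seqs, fixed = TRUE))
    d <- length(reference_seqs) - cc
    ht <- chi_square_2x2(a, b, cc, d, yates = yates)
    data.frame(motif = m, a = a, b = b, c = cc, d = d, fold = ht$fold,
               chi2 = ht$statistic, p = ht$p, testable = ht$testable)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$direction <- direction_of(res$testable, res$p_adj, res$fold, alpha)
  res$testable <- NULL
  res
}

#' Merge several peak sets for one protein by interval union
#'
#' Used for Polycomb/Trithorax-group proteins where all available
#' datasets for a protein are pooled before testing.
#'
#' @param peak_sets list of `GRanges` for one protein.
#' @return a single reduced `GRanges`.
#' @export
merge_peak_sets <- function(peak_sets) {
  if (length(peak_sets) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(do.call(c, lapply(unname(peak_sets),
                                          GenomicRanges::granges)))
}
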