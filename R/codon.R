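# Synonymous-site census over in-frame codon alignments and the Fisher
# exact comparison that asks whether the absence of synonymous change in
# an exon can be explained by chance, given a baseline alignment evolving
# under ordinary synonymous turnover.

#' In-frame codon alignment
#'
#' @param seqs named character vector of aligned in-frame sequences, all
#'   the same length, length divisible by 3. Gapped or ambiguous columns
#'   are tolerated here and excluded (with a message) by [codon_census()].
#' @param reference name of the designated reference row (default: the
#'   first sequence). Substitutions are assessed pairwise against this
#'   row, not via ancestral reconstruction.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, reference = names(seqs)[1]) {
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by species")
  }
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  if (nchar(seqs[[1]]) %% 3L != 0L) {
    stop("alignment length must be divisible by 3")
  }
  if (!reference %in% names(seqs)) {
    stop("reference species not found: ", reference)
  }
  structure(list(seqs = seqs, species = names(seqs), reference = reference),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$seqs), "species,",
      nchar(x$seqs[[1]]) / 3, "codons (reference:", x$reference, ")\n")
  invisible(x)
}

split_codons <- function(seq) {
  n <- nchar(seq) / 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Synonymous capability of codons
#'
#' A codon is synonymous-capable iff at least one alternative nucleotide
#' at its third position encodes the same amino acid under the standard
#' genetic code. ATG (Met) and TGG (Trp) are the only incapable sense
#' codons.
#'
#' @param codons character vector of codons over ACGT.
#' @return logical vector (the capability mask); `sum()` gives the count
#'   of synonymous-capable sites.
#' @examples
#' synonymous_capable(c("ATG", "AAA", "TGG", "CTG"))
#' @export
synonymous_capable <- function(codons) {
  codons <- toupper(codons)
  stopifnot(all(grepl("^[ACGT]{3}$", codons)))
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    stop("stop codon in frame at codon position ", stop_at[1])
  }
  vapply(seq_along(codons), function(i) {
    third <- substr(codons[i], 3L, 3L)
    variants <- paste0(substr(codons[i], 1L, 2L),
                       setdiff(DNA_ALPHABET, third))
    any(code[variants] == aa[i])
  }, logical(1))
}

#' Census of third-position substitutions in a codon alignment
#'
#' For each codon column, records whether the site is synonymous-capable
#' and whether any non-reference species differs from the reference at
#' the third position with a codon encoding the same amino acid
#' (substituted synonymous) or a different one (substituted
#' nonsynonymous). First- and second-position differences are ignored;
#' columns containing gaps or non-ACGT characters in any species are
#' excluded with a message.
#'
#' @param alignment a [codon_alignment()].
#' @return object of class `site_census`: a data.frame with per-codon
#'   columns `codon`, `aa`, `synonymous_capable`,
#'   `substituted_synonymous`, `substituted_nonsynonymous`, plus a
#'   `totals` attribute (list with `n_codons`, `n_capable`,
#'   `n_synonymous_substituted`, `n_capable_unsubstituted`,
#'   `n_excluded`).
#' @export
codon_census <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  code <- Biostrings::GENETIC_CODE
  ref <- split_codons(alignment$seqs[[alignment$reference]])
  others <- alignment$seqs[setdiff(alignment$species, alignment$reference)]
  other_codons <- lapply(others, split_codons)

  clean <- grepl("^[ACGT]{3}$", ref)
  for (oc in other_codons) clean <- clean & grepl("^[ACGT]{3}$", oc)
  n_excluded <- sum(!clean)
  if (n_excluded > 0L) {
    message(n_excluded, " codon column(s) with gaps or ambiguity excluded")
  }

  capable <- rep(NA, length(ref))
  capable[clean] <- synonymous_capable(ref[clean])
  syn <- nonsyn <- rep(FALSE, length(ref))
  for (oc in other_codons) {
    differs <- clean & substr(oc, 3L, 3L) != substr(ref, 3L, 3L)
    if (!any(differs)) next
    same_aa <- differs
    same_aa[differs] <- code[oc[differs]] == code[ref[differs]] &
      code[oc[differs]] != "*"
    syn <- syn | same_aa
    nonsyn <- nonsyn | (differs & !same_aa)
  }
  df <- data.frame(codon = ref, aa = ifelse(clean, code[ref], NA_character_),
                   synonymous_capable = capable,
                   substituted_synonymous = syn,
                   substituted_nonsynonymous = nonsyn)
  df$synonymous_capable[!clean] <- NA
  df$substituted_synonymous[!clean] <- NA
  df$substituted_nonsynonymous[!clean] <- NA
  n_capable <- sum(df$synonymous_capable, na.rm = TRUE)
  n_syn <- sum(df$substituted_synonymous, na.rm = TRUE)
  attr(df, "totals") <- list(
    n_codons = length(ref),
    n_capable = n_capable,
    n_synonymous_substituted = n_syn,
    n_capable_unsubstituted = n_capable - n_syn,
    n_excluded = n_excluded)
  class(df) <- c("site_census", "data.frame")
  df
}

#' @export
print.site_census <- function(x, ...) {
  t <- attr(x, "totals")
  cat(sprintf(paste0("site_census: %d codons, %d synonymous-capable, ",
                     "%d with synonymous substitutions (%d excluded)\n"),
              t$n_codons, t$n_capable, t$n_synonymous_substituted,
              t$n_excluded))
  invisible(x)
}

#' Test whether an exon's synonymous conservation is explicable by chance
#'
#' Builds the 2x2 table (rows: exon, baseline; columns:
#' synonymous-substituted sites, synonymous-capable unsubstituted sites)
#' from the censuses of the two alignments and applies the two-sided
#' Fisher exact test. A baseline with ordinary synonymous turnover (such
#' as a deeply conserved protein domain identical at the amino-acid
#' level) calibrates how many synonymous changes the divergence times
#' allow.
#'
#' @param exon_alignment,baseline_alignment [codon_alignment()] objects
#'   over the same species set.
#' @return list with `table`, `p_value`, `testable`, and the two
#'   censuses. Zero synonymous-capable sites in either alignment make the
#'   comparison untestable (`p_value = NA`).
#' @export
constraint_test <- function(exon_alignment, baseline_alignment) {
  stopifnot(inherits(exon_alignment, "codon_alignment"),
            inherits(baseline_alignment, "codon_alignment"))
  if (!setequal(exon_alignment$species, baseline_alignment$species)) {
    stop("the two alignments must share the same species set")
  }
  ce <- codon_census(exon_alignment)
  cb <- codon_census(baseline_alignment)
  te <- attr(ce, "totals"); tb <- attr(cb, "totals")
  tab <- matrix(c(te$n_synonymous_substituted, te$n_capable_unsubstituted,
                  tb$n_synonymous_substituted, tb$n_capable_unsubstituted),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("exon", "baseline"),
                                c("substituted", "unsubstituted")))
  if (te$n_capable == 0L || tb$n_capable == 0L) {
    return(list(table = tab, p_value = NA_real_, testable = FALSE,
                exon_census = ce, baseline_census = cb))
  }
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p_value = ft$p, testable = TRUE,
       exon_census = ce, baseline_census = cb)
}
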