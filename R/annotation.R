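#' Gene-model annotation set
#'
#' Bundles protein-coding gene models (gene spans, transcript exons with a
#' per-exon constitutive flag) and non-coding RNA intervals, validating
#' that every exon lies inside its gene span.
#'
#' @param genes `GRanges` with metadata column `gene_id`.
#' @param exons `GRanges` with metadata columns `gene_id`,
#'   `transcript_id`, `exon_id` and logical `constitutive`.
#' @param ncrna `GRanges` of non-coding RNA intervals (may be empty).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genes, exons, ncrna = GenomicRanges::GRanges()) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRanges"),
            methods::is(ncrna, "GRanges"))
  if (is.null(genes$gene_id)) stop("genes must carry a gene_id column")
  for (col in c("gene_id", "transcript_id")) {
    if (is.null(S4Vectors::mcols(exons)[[col]])) {
      stop("exons must carry a ", col, " column")
    }
  }
  if (is.null(exons$exon_id)) {
    exons$exon_id <- sprintf("exon_%04d", seq_along(exons))
  }
  if (is.null(exons$constitutive)) exons$constitutive <- TRUE
  idx <- match(exons$gene_id, genes$gene_id)
  if (anyNA(idx)) {
    stop("exon refers to unknown gene: ",
         exons$exon_id[which(is.na(idx))[1]])
  }
  bad <- which(GenomicRanges::start(exons) < GenomicRanges::start(genes)[idx] |
                 GenomicRanges::end(exons) > GenomicRanges::end(genes)[idx] |
                 as.character(GenomicRanges::seqnames(exons)) !=
                 as.character(GenomicRanges::seqnames(genes))[idx])
  if (length(bad)) {
    stop(sprintf("exon outside its gene span: %s (gene %s)",
                 exons$exon_id[bad[1]], exons$gene_id[bad[1]]))
  }
  structure(list(genes = genes, exons = exons, ncrna = ncrna),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$genes), "genes,", length(x$exons),
      "exons,", length(x$ncrna), "ncRNAs\n")
  invisible(x)
}

#' Intron intervals of an annotation set
#'
#' Introns are the per-transcript gaps between consecutive exons.
#'
#' @param annotations an [annotation_set()].
#' @return `GRanges` with metadata columns `gene_id` and `transcript_id`.
#' @export
introns <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  ex <- annotations$exons
  rows <- lapply(unique(ex$transcript_id), function(tx) {
    e <- sort(ex[ex$transcript_id == tx])
    if (length(e) < 2L) return(NULL)
    st <- GenomicRanges::end(e)[-length(e)] + 1L
    en <- GenomicRanges::start(e)[-1] - 1L
    keep <- st <= en
    if (!any(keep)) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(e))[1],
               start = st[keep], end = en[keep],
               gene_id = e$gene_id[1], transcript_id = tx)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    gr <- GenomicRanges::GRanges()
    gr$gene_id <- character(0); gr$transcript_id <- character(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               gene_id = df$gene_id,
                               transcript_id = df$transcript_id)
  sort(gr)
}

#' Splice-site positions of an annotation set
#'
#' A splice site is operationalised as the terminal exon base adjacent to
#' an intron: the last base of every exon followed by an intron and the
#' first base of every exon preceded by one.
#'
#' @param annotations an [annotation_set()].
#' @return `GRanges` of width-1 positions.
#' @export
splice_sites <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  ex <- annotations$exons
  rows <- lapply(unique(ex$transcript_id), function(tx) {
    e <- sort(ex[ex$transcript_id == tx])
    if (length(e) < 2L) return(NULL)
    donor <- GenomicRanges::end(e)[-length(e)]       # exon end before intron
    acceptor <- GenomicRanges::start(e)[-1]          # exon start after intron
    data.frame(chrom = as.character(GenomicRanges::seqnames(e))[1],
               pos = sort(c(donor, acceptor)))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(GenomicRanges::GRanges())
  sort(unique(GenomicRanges::GRanges(df$chrom,
                                     IRanges::IRanges(df$pos, width = 1L))))
}
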