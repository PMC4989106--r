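# Standard-format I/O. FASTA via Biostrings (60-column wrapped), BED and
# GFF3 via rtracklayer (0-based half-open on disk, 1-based GRanges in
# memory), plain TSV with header rows for all tables.

#' Read a genome FASTA
#'
#' @param path FASTA file, one record per chromosome/scaffold.
#' @return named uppercase character vector; the `"had_lowercase"`
#'   attribute records whether soft-masked bases were present.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- Biostrings::readBStringSet(path)  # preserves case for mask detection
  raw <- as.character(dss)
  had_lower <- any(grepl("[acgtn]", raw))
  out <- as_genome(raw)
  names(out) <- sub("\\s.*$", "", names(dss))
  attr(out, "had_lowercase") <- had_lower
  out
}

#' Write a genome FASTA, wrapped at 60 columns
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 60L)
  invisible(path)
}

#' Read a BED file as GRanges
#'
#' On-disk BED intervals are 0-based half-open; the returned `GRanges`
#' follows the in-memory 1-based convention.
#' @param path BED3/BED6 file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write GRanges as BED
#'
#' @param gr `GRanges`; `name` and `score` metadata columns are written
#'   when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write an annotation set as GFF3
#'
#' Genes, one mRNA per transcript, and exons (with the constitutive flag
#' as an attribute) are written as a three-level feature hierarchy.
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @export
write_annotation_gff3 <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  g <- annotations$genes
  g$type <- "gene"; g$ID <- g$gene_id
  tx_ids <- unique(annotations$exons$transcript_id)
  tx_gene <- annotations$exons$gene_id[match(tx_ids, annotations$exons$transcript_id)]
  tx_df <- do.call(rbind, lapply(seq_along(tx_ids), function(i) {
    e <- annotations$exons[annotations$exons$transcript_id == tx_ids[i]]
    data.frame(chrom = as.character(GenomicRanges::seqnames(e))[1],
               start = min(GenomicRanges::start(e)),
               end = max(GenomicRanges::end(e)),
               strand = as.character(GenomicRanges::strand(e))[1])
  }))
  tx <- GenomicRanges::GRanges(tx_df$chrom,
                               IRanges::IRanges(tx_df$start, tx_df$end),
                               strand = tx_df$strand)
  tx$type <- "mRNA"; tx$ID <- tx_ids; tx$Parent <- tx_gene
  e <- annotations$exons
  e2 <- GenomicRanges::granges(e)
  e2$type <- "exon"; e2$ID <- e$exon_id; e2$Parent <- e$transcript_id
  e2$constitutive <- ifelse(e$constitutive, "1", "0")
  feats <- list(g, tx, e2)
  if (length(annotations$ncrna)) {
    nc <- GenomicRanges::granges(annotations$ncrna)
    nc$type <- "ncRNA"
    nc$ID <- annotations$ncrna$name %||%
      sprintf("ncrna_%02d", seq_along(annotations$ncrna))
    feats <- c(feats, list(nc))
  }
  all <- do.call(c, lapply(feats, function(x) {
    S4Vectors::mcols(x) <- S4Vectors::mcols(x)[intersect(
      c("type", "ID", "Parent", "constitutive"), names(S4Vectors::mcols(x)))]
    x
  }))
  rtracklayer::export(all, path, format = "GFF3")
  invisible(path)
}

#' Read a GFF3 gene model file into an annotation set
#'
#' Expects the hierarchy written by [write_annotation_gff3()] (gene,
#' mRNA, exon with Parent links; optional ncRNA features). An exon
#' falling outside its gene span raises a validation error naming the
#' feature.
#' @param path GFF3 file.
#' @export
read_annotation_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "GFF3")
  first_chr <- function(x) vapply(x, function(v) {
    if (length(v)) as.character(v[[1]]) else NA_character_
  }, character(1))
  genes <- gr[gr$type == "gene"]
  genes$gene_id <- as.character(genes$ID)
  tx <- gr[gr$type == "mRNA"]
  tx_gene <- stats::setNames(first_chr(tx$Parent), as.character(tx$ID))
  ex <- gr[gr$type == "exon"]
  exons <- GenomicRanges::granges(ex)
  exons$transcript_id <- first_chr(ex$Parent)
  exons$gene_id <- unname(tx_gene[exons$transcript_id])
  exons$exon_id <- as.character(ex$ID)
  exons$constitutive <- if (!is.null(ex$constitutive)) {
    ex$constitutive == "1"
  } else rep(TRUE, length(ex))
  nc <- gr[gr$type == "ncRNA"]
  ncrna <- GenomicRanges::granges(nc)
  if (length(nc)) ncrna$name <- as.character(nc$ID)
  annotation_set(genes[, "gene_id"], exons, ncrna)
}

#' Write a data.frame as TSV with a header row
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#' @param path input path.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a plain-text motif list (one motif per line)
#' @param path text file; blank lines and lines starting with `#` are
#'   skipped.
#' @export
read_motif_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path))
  toupper(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read an in-frame FASTA codon alignment
#' @param path FASTA with one record per species.
#' @param reference reference species name (default: first record).
#' @export
read_codon_alignment <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  codon_alignment(seqs, reference = reference %||% names(seqs)[1])
}
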