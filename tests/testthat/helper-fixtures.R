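# Small fixture builders shared across test files. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

# standard small cohort: three plants, one centred-mismatch decoy
small_cohort_spec <- function(seed = 7, divergence = 0.2, n_species = 4,
                              chrom_lengths = c(1200, 800)) {
  cohort_spec(
    n_species = n_species, chrom_lengths = chrom_lengths,
    background_divergence = divergence,
    plants = list(plant_spec(50, 1, 100), plant_spec(75, 1, 400),
                  plant_spec(120, 2, 200)),
    decoys = list(decoy_spec(60, 2, 500, n_mismatches = 1,
                             target_species = 1)),
    seed = seed)
}

# minimal annotation: one gene with two exons and an intron between,
# plus one ncRNA. Coordinates chosen to mirror the exon [100,200) /
# intron [200,300) classification examples (1-based closed in memory).
toy_annotation <- function() {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400),
                                  strand = "+", gene_id = "gene_001")
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 301), c(200, 400)), strand = "+",
    gene_id = "gene_001", transcript_id = "gene_001.t1",
    exon_id = c("exon_0001", "exon_0002"), constitutive = c(TRUE, FALSE))
  ncrna <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1080),
                                  name = "ncrna_01")
  annotation_set(genes, exons, ncrna)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

gr1 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

# n non-overlapping elements of width w evenly spaced `spacing` nt apart
spaced_elements <- function(n, w = 50, spacing = 10000, chrom = "chr1") {
  st <- (seq_len(n) - 1L) * spacing + 1L
  g <- gr1(chrom, st, st + w - 1L)
  g$name <- sprintf("el_%03d", seq_len(n))
  g
}
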