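# Simulators: determinism, ground-truth contracts, bias calibration.

test_that("cohort simulation is byte-deterministic given a seed", {
  a <- simulate_cohort(small_cohort_spec(seed = 42))
  b <- simulate_cohort(small_cohort_spec(seed = 42))
  expect_identical(a$cohort$reference, b$cohort$reference)
  expect_identical(a$cohort$queries, b$cohort$queries)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(a$cohort$reference, f1)
  write_genome_fasta(b$cohort$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  c_ <- simulate_cohort(small_cohort_spec(seed = 43))
  expect_false(identical(a$cohort$reference, c_$cohort$reference))
})

test_that("zero divergence yields identical genomes and complete truth", {
  spec <- cohort_spec(n_species = 3, chrom_lengths = 300,
                      background_divergence = 0,
                      plants = list(plant_spec(60, 1, 100)), seed = 5)
  sim <- simulate_cohort(spec)
  for (q in sim$cohort$queries) {
    expect_identical(unname(q), unname(sim$cohort$reference))
  }
  expect_equal(GenomicRanges::start(sim$truth), 101L)
  expect_equal(GenomicRanges::width(sim$truth), 60L)
})

test_that("planted regions are identical across genomes at any divergence", {
  sim <- simulate_cohort(small_cohort_spec(seed = 13, divergence = 0.3))
  plants <- sim$truth[sim$truth$type == "planted"]
  for (i in seq_along(plants)) {
    ch <- as.character(GenomicRanges::seqnames(plants)[i])
    s <- substr(sim$cohort$reference[[ch]], GenomicRanges::start(plants)[i],
                GenomicRanges::end(plants)[i])
    for (q in sim$cohort$queries) {
      expect_identical(substr(q[[ch]], GenomicRanges::start(plants)[i],
                              GenomicRanges::end(plants)[i]), s)
    }
  }
})

test_that("decoys differ by exactly n_mismatches in target species only", {
  spec <- cohort_spec(n_species = 4, chrom_lengths = 600,
                      background_divergence = 0,
                      decoys = list(decoy_spec(80, 1, 200, n_mismatches = 3,
                                               target_species = c(1, 3))),
                      seed = 8)
  sim <- simulate_cohort(spec)
  d <- sim$truth[sim$truth$type == "decoy"]
  ref_copy <- substr(sim$cohort$reference[["chr1"]],
                     GenomicRanges::start(d), GenomicRanges::end(d))
  mism <- function(q) {
    qc <- substr(q[["chr1"]], GenomicRanges::start(d), GenomicRanges::end(d))
    sum(strsplit(qc, "")[[1]] != strsplit(ref_copy, "")[[1]])
  }
  expect_equal(mism(sim$cohort$queries[[1]]), 3L)
  expect_equal(mism(sim$cohort$queries[[2]]), 0L)
  expect_equal(mism(sim$cohort$queries[[3]]), 3L)
})

test_that("overlapping or too-close plants are rejected naming the pair", {
  expect_error(
    cohort_spec(n_species = 3, chrom_lengths = 1000,
                plants = list(plant_spec(60, 1, 100), plant_spec(60, 1, 140))),
    "plant 1 and plant 2")
  expect_error(
    cohort_spec(n_species = 3, chrom_lengths = 1000,
                plants = list(plant_spec(60, 1, 100)),
                decoys = list(decoy_spec(60, 1, 180))),
    "closer than 50 nt")
})

test_that("injected N-runs are excluded from seed extraction", {
  spec <- cohort_spec(n_species = 3, chrom_lengths = 400,
                      background_divergence = 0,
                      n_runs = list(c(1, 200, 10)), seed = 4)
  sim <- simulate_cohort(spec)
  expect_true(grepl("N{10}", sim$cohort$reference[["chr1"]]))
  uniq <- extract_unique_kmers(sim$cohort$reference, k = 50)
  # no seed window may intersect the N run at 0-based [200, 210)
  expect_false(any(uniq$pos > 200 - 50 & uniq$pos < 210))
})

test_that("unbiased peak placement hits plants at the background rate", {
  n_plants <- 40L
  truth <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 2000, length.out = n_plants), width = 100),
    type = "planted")
  G <- 90000L
  tr <- simulate_tracks(c(chr1 = G),
    track_spec(n_genes = 5, peaks = list(
      TF1 = list(n_peaks = 5000, width = c(1, 1), uce_bias = 1)), seed = 31),
    truth = truth)
  hits <- sum(IRanges::overlapsAny(tr$peaks$TF1, truth))
  p_expected <- n_plants * 100 / G  # width-1 peaks: pure position fraction
  bt <- binom.test(hits, length(tr$peaks$TF1), p = p_expected)
  expect_gt(bt$p.value, 0.01)
})

test_that("peak placement bias is monotone in uce_bias", {
  truth <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 2000, length.out = 40), width = 100),
    type = "planted")
  frac <- vapply(c(1, 5, 20), function(b) {
    tr <- simulate_tracks(c(chr1 = 90000),
      track_spec(peaks = list(TF1 = list(n_peaks = 2000, width = c(1, 1),
                                         uce_bias = b)), seed = 55),
      truth = truth)
    mean(IRanges::overlapsAny(tr$peaks$TF1, truth))
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("simulated features stay within chromosome bounds", {
  tr <- simulate_tracks(c(chr1 = 20000, chr2 = 15000),
    track_spec(n_genes = 15, n_ncrna = 4,
               peaks = list(TF1 = list(n_peaks = 50, width = c(100, 300))),
               editing_density = 0.01, seed = 9))
  lens <- c(chr1 = 20000, chr2 = 15000)
  check <- function(gr) {
    if (length(gr) == 0L) return()
    ch <- as.character(GenomicRanges::seqnames(gr))
    expect_true(all(GenomicRanges::start(gr) >= 1L))
    expect_true(all(GenomicRanges::end(gr) <= lens[ch]))
  }
  check(tr$annotations$genes); check(tr$annotations$exons)
  check(tr$annotations$ncrna); check(tr$peaks$TF1); check(tr$editing)
  expect_s3_class(tr$annotations, "annotation_set")
})

test_that("codon simulation respects its constraint modes", {
  inv <- simulate_codon_alignment(codon_aln_spec(50, n_species = 5, rate = 0.5,
                                                 constraint_mode = "invariant",
                                                 seed = 2))
  expect_true(all(!inv$truth$substituted_synonymous))
  expect_identical(unname(inv$alignment$seqs[1]), unname(inv$alignment$seqs[2]))

  syn <- simulate_codon_alignment(codon_aln_spec(100, n_species = 12,
                                                 rate = 0.5,
                                                 constraint_mode = "synonymous_only",
                                                 seed = 3))
  expect_true(all(!syn$truth$substituted_nonsynonymous))
  cen <- codon_census(syn$alignment)
  expect_equal(cen$substituted_synonymous, syn$truth$substituted_synonymous)
  expect_equal(sum(cen$substituted_synonymous),
               sum(syn$truth$substituted_synonymous))
  # amino-acid identity across all rows under synonymous_only
  aa <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_true(all(vapply(syn$alignment$seqs, aa, character(1)) ==
                    aa(syn$alignment$seqs[[1]])))
  # Trp codons can never receive a synonymous substitution
  expect_true(all(!syn$truth$substituted_synonymous[syn$truth$codon == "TGG"]))
  expect_true(all(!syn$truth$synonymous_capable[syn$truth$codon %in%
                                                  c("ATG", "TGG")]))
})
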