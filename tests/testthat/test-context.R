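# Classification, reference-element null, clustering, distances, ranking.

test_that("classification follows the ncRNA > junction > exonic > intronic order", {
  ann <- toy_annotation()  # exon 101-200, intron 201-300, exon 301-400
  els <- c(gr1("chr1", 151, 250),   # spans exon/intron boundary
           gr1("chr1", 121, 180),   # inside first exon
           gr1("chr1", 211, 290),   # purely intronic
           gr1("chr1", 601, 650),   # outside the gene
           gr1("chr1", 1001, 1010)) # inside the ncRNA
  cls <- classify_elements(els, ann)
  expect_equal(as.character(cls),
               c("junction", "exonic", "intronic", "intergenic", "ncRNA"))
})

test_that("ncRNA overlap wins over exon overlap", {
  genes <- gr1("chr1", 101, 400); genes$gene_id <- "g1"
  exons <- gr1("chr1", 101, 200)
  exons$gene_id <- "g1"; exons$transcript_id <- "g1.t1"
  exons$exon_id <- "e1"; exons$constitutive <- TRUE
  ncrna <- gr1("chr1", 150, 250); ncrna$name <- "tRNA-1"
  ann <- annotation_set(genes, exons, ncrna)
  expect_equal(as.character(classify_elements(gr1("chr1", 140, 260), ann)),
               "ncRNA")
})

test_that("classification is total: class counts sum to the element count", {
  ann <- toy_annotation()
  els <- withr::with_seed(17, {
    st <- sample.int(1500, 60)
    gr1("chr1", st, st + sample(30:80, 60, TRUE))
  })
  mixed <- suppressWarnings(c(els, gr1("chrX", 1, 50)))
  expect_warning(cls <- classify_elements(mixed, ann), "absent")
  expect_equal(sum(table(cls)), 61L)
})

test_that("reference elements tile deterministically with matched lengths", {
  genome <- withr::with_seed(29, c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")))
  re <- generate_reference_elements(genome, lengths = 50L, seed = 1)
  expect_lte(length(re), 20L)
  expect_true(all(GenomicRanges::width(re) == 50L))
  expect_true(all(diff(GenomicRanges::start(re)) %% 50 == 0))
  expect_equal(GenomicRanges::start(re)[1], 1L)
  re2 <- generate_reference_elements(genome, lengths = 50L, seed = 1)
  expect_identical(GenomicRanges::start(re), GenomicRanges::start(re2))
})

test_that("duplicated fragments are discarded by the unique-mapping rule", {
  dup <- withr::with_seed(31, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                                    collapse = ""))
  fill <- withr::with_seed(32, paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                     collapse = ""))
  tail <- withr::with_seed(33, paste(sample(c("A", "C", "G", "T"), 140, TRUE),
                                     collapse = ""))
  genome <- c(chr1 = paste0(dup, fill, dup, tail))  # dup at tiling slots 0 and 100
  re <- generate_reference_elements(genome, lengths = c(60L, 40L), seed = 2)
  seqs <- substring(genome, GenomicRanges::start(re), GenomicRanges::end(re))
  expect_false(dup %in% seqs)
  # every retained fragment really is unique (naive both-strand count)
  for (s in seqs) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    n <- length(gregexpr(s, genome, fixed = TRUE)[[1]])
    expect_equal(n + sum(gregexpr(rc, genome,
                                  fixed = TRUE)[[1]] > 0), 1L)
  }
})

test_that("retained length mix matches the sampling multiset", {
  genome <- withr::with_seed(41, c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")))
  lens <- c(rep(50L, 9), 80L)
  re <- generate_reference_elements(genome, lengths = lens, seed = 3)
  frac80 <- mean(GenomicRanges::width(re) == 80L)
  n <- length(re)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac80 - 0.1), 3 * se)
})

test_that("single-linkage clustering honours the strict gap threshold", {
  els <- c(gr1("chr1", 1, 50), gr1("chr1", 10001, 10050),
           gr1("chr1", 40051, 40100))
  els$name <- c("a", "b", "c")
  cl <- cluster_elements(els, 18000)
  expect_equal(length(cl), 1L)
  expect_equal(cl$n_members, 2L)
  expect_equal(cl$members, "a,b")
  expect_equal(length(cluster_elements(els, 0)), 0L)
  # gap exactly at threshold does not join (strict inequality)
  two <- c(gr1("chr1", 1, 50), gr1("chr1", 151, 200))
  expect_equal(length(cluster_elements(two, 100)), 0L)
  expect_equal(length(cluster_elements(two, 101)), 1L)
})

test_that("clustering is idempotent and order-independent", {
  els <- withr::with_seed(5, {
    st <- sort(sample.int(100000, 30))
    g <- gr1("chr1", st, st + 49)
    g$name <- sprintf("e%02d", 1:30)
    g
  })
  cl1 <- cluster_elements(els, 5000)
  cl2 <- cluster_elements(els[sample(30)], 5000)
  expect_identical(as.data.frame(cl1), as.data.frame(cl2))
  # threshold -> infinity: one cluster per chromosome holding everything
  cl_inf <- cluster_elements(els, 1e9)
  expect_equal(length(cl_inf), 1L)
  expect_equal(cl_inf$n_members, 30L)
})

test_that("observed distances are half-open gaps between neighbours", {
  els <- spaced_elements(5, w = 50, spacing = 10000)
  d <- distance_stats(els, c(chr1 = 100000), n_null = 10, seed = 1)
  expect_equal(d$observed_median, 9950)
  expect_true(d$defined)
  one <- distance_stats(els[1], c(chr1 = 100000))
  expect_false(one$defined)
})

test_that("the distance null is calibrated: no false positional signal", {
  # elements drawn from the null's own process must not register as
  # non-randomly spaced. Same-chromosome gaps are negatively correlated
  # (they sum to ~the genome length), which makes the rank-sum test
  # conservative rather than exactly uniform; the operative calibration
  # property is type-I control.
  chrlen <- c(chr1 = 100000L)
  ps <- vapply(1:100, function(s) {
    els <- withr::with_seed(1000 + s, {
      st <- sort(sample.int(99950, 12))
      gr1("chr1", st, st + 49)
    })
    distance_stats(els, chrlen, n_null = 20, seed = 2000 + s)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
  expect_lte(mean(ps < 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / 100))
  # and a genuinely clustered layout is flagged against the same null
  clustered <- c(gr1("chr1", seq(1000, by = 300, length.out = 6),
                     seq(1049, by = 300, length.out = 6)),
                 gr1("chr1", seq(60000, by = 300, length.out = 6),
                     seq(60049, by = 300, length.out = 6)))
  d <- distance_stats(clustered, chrlen, n_null = 20, seed = 5)
  expect_lt(d$p_value, 0.01)
  expect_lt(d$observed_median, d$expected_median)
})

test_that("gene ranking divides element counts by reference counts", {
  genes <- gr1("chr1", c(20001, 60001, 100001), c(30000, 70000, 110000))
  genes$gene_id <- c("gA", "gB", "gC")
  els <- c(gr1("chr1", c(21000, 22000), c(21050, 22050)),  # 2 in gA
           gr1("chr1", 61000, 61050))                      # 1 in gB
  ref_st <- seq(20100, by = 2000, length.out = 4)
  refs <- c(gr1("chr1", ref_st, ref_st + 49), gr1("chr1", 61500, 61549))
  rk <- go_ranking_score(genes, els, refs, flank = 10000)
  expect_equal(rk$score[rk$gene_id == "gA"], 0.5)
  expect_equal(rk$score[rk$gene_id == "gB"], 1)
  expect_false("gC" %in% rk$gene_id)          # zero reference elements
  expect_equal(attr(rk, "excluded"), "gC")
  expect_equal(rk$gene_id[1], "gB")           # densest gene ranks first
})
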