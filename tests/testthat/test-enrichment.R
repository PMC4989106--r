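# Enrichment analyses: factor scan, multifunctionality, combination
# folds, alternative splicing, motif scan.

make_classed <- function(gr, cls) { gr$class <- cls; gr }

test_that("factor scan flags a biased factor and not an unbiased one", {
  n <- 500L
  truth <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(500, by = 400, length.out = n), width = 50),
    type = "planted")
  els <- make_classed(GenomicRanges::granges(truth), "intergenic")
  refs <- withr::with_seed(81, {
    st <- sort(sample.int(200000, n))
    make_classed(gr1("chr1", st, st + 49), "intergenic")
  })
  tr <- simulate_tracks(c(chr1 = 201000),
    track_spec(n_genes = 2, peaks = list(
      biased = list(n_peaks = 120, width = c(100, 200), uce_bias = 10),
      flat = list(n_peaks = 120, width = c(100, 200), uce_bias = 1)),
      seed = 82),
    truth = truth)
  res <- factor_scan(els, refs, tr$peaks, classes = "intergenic")
  biased <- res[res$factor == "biased", ]
  flat <- res[res$factor == "flat", ]
  expect_equal(biased$direction, "enriched")
  expect_gt(biased$fold, 1)
  expect_equal(flat$direction, "ns")
})

test_that("empty classes and empty peak sets are untestable rows", {
  els <- make_classed(spaced_elements(10), "intergenic")
  refs <- make_classed(spaced_elements(10, spacing = 7000), "intergenic")
  peaks <- list(empty = GenomicRanges::GRanges(),
                some = gr1("chr1", 1, 100))
  res <- factor_scan(els, refs, peaks,
                     classes = c("intergenic", "exonic"))
  expect_equal(nrow(res), 4L)
  expect_true(all(res$direction[res$factor == "empty"] == "untestable"))
  expect_true(all(res$direction[res$class == "exonic"] == "untestable"))
})

test_that("function flags follow the >=1 base overlap rule", {
  ann <- toy_annotation()
  el <- gr1("chr1", 195, 210)  # covers exon end 200 (splice site) + coding
  el$name <- "e1"
  prof <- function_profile(el, coding = ann$exons,
                          splice = splice_sites(ann),
                          editing = GenomicRanges::GRanges(),
                          peak_sets = list(TF = gr1("chr1", 205, 260)))
  expect_true(prof$coding); expect_true(prof$splice_site)
  expect_false(prof$editing); expect_true(prof$tf_bound)
  expect_equal(prof$score, 3)
})

test_that("splice sites are the exon terminal bases flanking introns", {
  ss <- splice_sites(toy_annotation())  # exons 101-200, 301-400
  expect_equal(GenomicRanges::start(ss), c(200L, 301L))
  expect_true(all(GenomicRanges::width(ss) == 1L))
})

test_that("combination folds reproduce constructed proportions", {
  flags <- c("coding", "splice_site", "editing", "tf_bound")
  mk <- function(n_tetra, n_total) {
    df <- data.frame(coding = rep(FALSE, n_total), splice_site = FALSE,
                     editing = FALSE, tf_bound = FALSE)
    if (n_tetra > 0) df[seq_len(n_tetra), flags] <- TRUE
    df$score <- rowSums(df[, flags])
    df
  }
  cf <- combo_fold(mk(100, 1000), mk(1, 1000))
  tetra <- cf[cf$coding & cf$splice_site & cf$editing & cf$tf_bound, ]
  expect_equal(tetra$fold, 100)
  expect_equal(tetra$prop_elements, 0.1)
  expect_equal(sum(cf$prop_elements), 1)
  expect_equal(sum(cf$prop_reference), 1)

  # identical multisets: every observed combination has fold 1
  same <- combo_fold(mk(5, 50), mk(5, 50))
  obs <- same[same$n_elements + same$n_reference > 0, ]
  expect_true(all(obs$fold == 1))
  expect_true(all(is.na(same$fold[same$n_elements + same$n_reference == 0])))

  # all-zero flags: the null combination alone carries fold 1
  zero <- combo_fold(mk(0, 20), mk(0, 20))
  expect_equal(sum(zero$fold == 1, na.rm = TRUE), 1L)

  # a combination seen only in elements is reported as infinite
  inf_case <- combo_fold(mk(3, 10), mk(0, 10))
  expect_true(any(is.infinite(inf_case$fold)))
})

test_that("alternative-splicing overlap uses the >=1 non-constitutive rule", {
  ex <- gr1("chr1", c(101, 301, 601), c(200, 400, 700))
  ex$constitutive <- c(TRUE, FALSE, FALSE)
  els <- gr1("chr1", seq(301, by = 1, length.out = 100),
             seq(350, by = 1, length.out = 100))
  refs_alt <- gr1("chr1", rep(310, 50), rep(360, 50))
  refs_const <- gr1("chr1", rep(110, 50), rep(160, 50))
  refs <- c(refs_alt, refs_const)
  res <- alt_splicing_test(els, ex, refs)
  expect_equal(res$a, 100L)
  expect_equal(res$c, 50L)
  expect_equal(res$fold, 2)
  expect_lt(res$p, 0.05)
  expect_equal(res$direction, "enriched")

  # overlapping both a constitutive and a non-constitutive exon counts
  both <- gr1("chr1", 195, 305)
  expect_equal(alt_splicing_test(both, ex, refs_const)$a, 1L)

  # empty exon table is untestable
  expect_equal(alt_splicing_test(els, GenomicRanges::GRanges(), refs)$direction,
               "untestable")
})

test_that("motif scan detects a planted enhancer and tolerates absences", {
  withr::with_seed(91, {
    el <- vapply(1:200, function(i) {
      paste0(random_dna_str(20), "GAAGAA", random_dna_str(20))
    }, character(1))
    rf <- vapply(1:200, function(i) random_dna_str(46), character(1))
  })
  rf <- gsub("GAAGAA", "GAAGTA", rf, fixed = TRUE)  # scrub chance hits
  res <- ese_motif_scan(el, rf, c("GAAGAA", "CCCCCCCCCC"))
  hit <- res[res$motif == "GAAGAA", ]
  expect_equal(hit$a, 200L)
  expect_lt(hit$p_adj, 0.05)
  expect_equal(hit$direction, "enriched")
  # a motif absent from both cohorts is untestable
  expect_equal(res$direction[res$motif == "CCCCCCCCCC"], "untestable")
  # an element equal to the motif itself matches (substring incl. identity)
  self <- ese_motif_scan("GAAGAA", "TTTTTT", "GAAGAA")
  expect_equal(self$a, 1L)
  expect_equal(nrow(ese_motif_scan(el, rf, character(0))), 0L)
  expect_error(ese_motif_scan(el, rf, "GAXGAA"), "ACGT")
})

test_that("multifunctionality shifts are detected by the rank-sum test", {
  ann <- toy_annotation()
  # elements piled on the splice site with a peak and editing site on top;
  # reference elements in naked intergenic space
  els <- gr1("chr1", seq(191, 200), seq(240, 249))
  els$name <- paste0("e", 1:10)
  refs <- gr1("chr1", seq(2001, by = 100, length.out = 10),
              seq(2050, by = 100, length.out = 10))
  refs$name <- paste0("r", 1:10)
  mf <- multifunctionality(
    els, refs, coding = ann$exons, splice = splice_sites(ann),
    editing = gr1("chr1", 200, 200),
    peak_sets = list(TF = gr1("chr1", 150, 260)))
  expect_true(all(mf$profiles$score == 4))
  expect_true(all(mf$reference_profiles$score == 0))
  expect_lt(mf$p_value, 0.01)
})
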