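---
title: "Alignment-free ultraconserved element discovery and its downstream statistics"
author: "ucekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free ultraconserved element discovery and its downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ultraconserved elements (UCEs) are genomic segments — here, at least 50 nt —
whose sequence is *identical* across every assembly in a cohort of related
species. Whole-genome alignments under-report them: an ambiguously placed gap,
a block split, or an assembly artifact can hide a perfectly conserved segment.
`ucekit` therefore finds UCEs without any alignment, by exact string matching,
and then supplies the statistics used to characterise them: a length-matched
random-element null, genomic classification, clustering, ChIP-peak enrichment,
multifunctionality scoring, and a synonymous-site test that asks whether the
total conservation of a coding exon can be explained by protein-level
constraint alone.

## Detection: seed, verify, fuse, re-verify

Detection composes four operations, each exposed separately:

1. **`extract_unique_kmers()`** — every k-mer (default k = 50) occurring
   exactly once in the reference assembly. Uniqueness counts both strands: an
   occurrence of the reverse complement anywhere counts against a k-mer, so a
   palindromic k-mer always counts at least twice and is excluded. Windows
   containing N are skipped. Positions are 0-based, matching BED on disk.
2. **`is_universal()`** — a seed survives if an exact copy (either strand
   under the default `strand_mode = "both"`) exists in *every* query genome.
   Multiple copies in a query are allowed: uniqueness is a reference-side
   property only. (The length-matched null below re-imposes unique mapping,
   because the published null construction does.)
3. **`fuse_seeds()`** — surviving seeds whose windows share at least one
   reference base (start difference ≤ k − 1) are merged transitively into
   maximal candidate intervals. Abutting, non-overlapping windows are not
   merged.
4. **`verify_and_emit()`** — each candidate's full reference sequence is
   re-checked for universality. This matters: two seed clusters can fuse on
   the reference while matching *different* loci in some query, in which case
   the reconstituted sequence exists nowhere. A failing candidate is bisected
   at its median seed, each half re-fused and re-verified recursively, and
   verified sub-elements of at least `min_length` are emitted; unverifiable
   remainders are logged and dropped, never raised as errors.

One geometric consequence is worth stating plainly: consecutive fused seeds
overlap by construction, so the two verified halves of a bisected candidate
share the boundary seed's bases. Bisection is thus the single code path that
can produce overlapping output elements; directly verified output is always
disjoint and sorted. The run manifest records how many bisections occurred.

`scan_universal_substrings()` implements the same question by brute force —
extend a window base by base with a full substring search at every step,
keeping maximal universal substrings — with no k-mer index, no fusion and no
uniqueness filter. It is quadratic-ish and only usable on desk-scale genomes,
which is exactly what makes it a credible independent cross-check: the test
suite demands exact agreement between the two routes on hundreds of simulated
cohorts.

Soft-masked (lowercase) bases are uppercased before indexing and any
non-ACGT code becomes N; all sequences of an assembly, however small, are
processed. Case-insensitive exact matching is the biologically right reading
of identity, and masking state is an annotation, not sequence.

## The simulators: what they emulate, and what they do not

`simulate_cohort()` generates a random reference genome, writes planted
elements (zero substitutions in every species) and decoys into it, and derives
each query genome by i.i.d. per-site substitutions at a configurable
background divergence — a star phylogeny. This is deliberate: the detector is
tree-agnostic (it only asks "is this string present everywhere"), so shared
internal branches would add realism without exercising any additional code
path. Indels, rate heterogeneity and GC skew are likewise out of scope; the
simulator's job is ground truth for exact-matching machinery, not
evolutionary realism. Assembly gaps can be emulated by injecting N-runs.

A **decoy** models the known false-positive mode of alignment-based audits: a
sequence exactly conserved in most species but carrying a fixed number of
mismatches in designated target species. Mismatch positions are evenly spaced
quantiles of the decoy, so a short decoy (about 60 nt with a centred
mismatch) leaves no clean ≥ 50 nt sub-run — important, because a long decoy
with one off-centre mismatch *genuinely contains* a conserved element in its
clean part, and the detector is right to report it.

Two properties of the generator matter for interpreting tests. First, a
planted element can be extended by flanking bases that stay identical in all
queries by chance (per-site probability (1 − d)^q), so the detector
legitimately reports a slightly wider interval than the plant; recovery is
therefore asserted as coverage, and exactness is asserted against the
brute-force scanner, which extends identically. Second, at divergence 0 the
whole chromosome is one universal element, so counts of "chance" elements are
not monotone through zero divergence — fewer, larger elements — while from
0.02 upward the expected count decreases monotonically, which is what the
property test checks.

`simulate_tracks()` lays gene models left-to-right with exponential gaps
(one transcript per gene; exons and introns alternate), places ncRNAs,
RNA-editing sites (Poisson over exonic bases), flags a configurable fraction
of exons non-constitutive, and draws ChIP-like peaks from a two-component
mixture: with probability bA/(bA + G − A) a peak centre falls uniformly
inside a planted element, otherwise uniformly outside (A = total planted
length, G = genome length, b = `uce_bias`). At b = 1 this reduces exactly to
genome-wide uniform placement, and the expected overlap fold at planted
elements is a closed-form, monotone function of b — which is how the
enrichment tests can state their expected outcome *before* any run.

`simulate_codon_alignment()` draws a reference row from the 61 sense codons
and substitutes third positions per species at a configurable rate, under
three constraint modes (`free`, `synonymous_only`, `invariant`), recording
per-site truth flags as it goes.

## Classification and the length-matched null

`classify_elements()` assigns exactly one class by fixed priority:
ncRNA overlap → intron–exon **junction** (≥ 1 exonic and ≥ 1 intronic base of
the *same* transcript) → **exonic** (any exon) → **intronic** (inside a gene
span) → **intergenic**. One qualifying transcript of one gene suffices.
Junction is deliberately tested before exonic so boundary-spanning elements
form their own category; the class counts always sum to the element count.

`generate_reference_elements()` builds the null cohort: the genome is tiled
left to right with fragment lengths drawn (seeded, with replacement) from the
observed element-length multiset, and fragments containing N or mapping
non-uniquely (both strands, overlapping occurrences counted) are discarded.
Tiling rather than random placement reproduces the published construction;
the discard step means the retained count can be below the arithmetic
maximum, but the retained length *mix* converges to the source multiset.

## Clustering, distances, gene ranking

`cluster_elements()` chains consecutive same-chromosome elements whose gap
(next start − previous end, half-open) is strictly below the threshold;
a cluster needs at least two members, so singletons are never counted as
clusters. The pipeline's `cluster_gap = "median"` mode sets the threshold to
the observed median inter-element gap — the rule that yields the published
18 kb threshold at assembly scale.

`distance_stats()` compares observed gaps against gaps of `n_null` seeded
draws of equally many random, non-overlapping, length-matched (optionally
uniquely mapping) elements, with a two-sided Mann–Whitney test and the
expected median averaged over replicate medians. A caveat we measured rather
than assumed: gaps on one chromosome are negatively correlated (they sum to
roughly the chromosome length), so the rank-sum p-value under the null is
*conservative* — its distribution piles up toward 1 rather than being
uniform. The calibration test therefore asserts what matters operationally:
no type-I inflation, and strong sensitivity to genuinely clustered layouts.
For the huge shifts this analysis targets (observed median several-fold below
expected) the conservatism is immaterial.

`go_ranking_score()` ranks genes by elements within the gene span ± 10 kb
divided by reference elements in the same window; zero-reference windows are
excluded and recorded. The ranking is the input contract for external
GO-enrichment tools, which are out of scope.

## Enrichment statistics

All 2×2 tests run through `chi_square_2x2()`: Pearson χ² with the Yates
continuity correction on by default. The correction is R's default for 2×2
tables and errs conservative at the modest per-class counts typical here; it
is configurable off. Any zero row/column margin yields an `untestable`
result — empty peak sets, empty classes and all-absent motifs are reported,
never thrown.

`factor_scan()` performs one test per factor × element class (elements
overlapping ncRNAs are excluded upstream; junction elements are merged into
exonic by the pipeline), with Benjamini–Hochberg correction applied jointly
across the whole family — one family per analysis, never pooled across
analyses. The two published family sizes (117 factor-by-class tests, 99
splicing-enhancer motifs) are reproduced by that rule. Directions
(`enriched`/`depleted`) are reported at adjusted p < 0.05 and are consistent
with the fold by construction. Datasets for one Polycomb/Trithorax protein
are merged by interval union (`merge_peak_sets()`) before testing.

`function_profile()` flags each element for protein-coding overlap,
splice-site overlap (operationalised as the terminal exon base adjacent to an
intron — "overlap with a splice site" needs a point definition), RNA-editing
overlap, and binding by at least one factor (union of all peak sets), all at
the ≥ 1 shared base rule; the score is the flag count, 0–4.
`multifunctionality()` compares score distributions with a two-sided
Mann–Whitney test, and `combo_fold()` reports, for each of the 16 flag
combinations, the proportion among elements, among reference elements, and
their ratio, computed as an integer cross-ratio so that round constructed
proportions give exact folds. A combination absent from the reference but
present among elements is reported as infinite with its counts; a combination
absent from both is `NA`.

The desk-scale study conditions for the calibration and recovery checks were
fixed from the placement algebra, not by trial: 500 elements on a 200 kb
genome with 300 peaks per factor gives an analytic overlap fold ≈ 3.5 at
`uce_bias = 10`, comfortably detectable at n = 500, while `uce_bias = 1`
families stay at the nominal false-positive level under BH.

## The synonymous-site census and the constraint test

`synonymous_capable()` marks codons whose third position admits at least one
same-amino-acid alternative under the standard genetic code; ATG and TGG are
the only incapable sense codons, a fact the tests verify exhaustively over
all 61. `codon_census()` compares every non-reference row against the
designated reference row (no ancestral reconstruction — substitutions are
defined relative to the reference sequence), counts a capable site as
synonymous-substituted when *any* species differs at the third position with
the same amino acid, ignores first/second-position differences, and excludes
gapped or ambiguous columns with a log message. In-frame stop codons are an
error naming the position.

`constraint_test()` builds the 2×2 table — synonymous-substituted versus
capable-but-unsubstituted sites, exon versus baseline — and applies the
two-sided Fisher exact test (minimum-likelihood convention, relative
tolerance 1 + 10⁻⁷). Two-sided is the deliberate choice: on the motivating
census structure (0 of 15 exon sites substituted versus 29 of 57 baseline
sites) it yields p ≈ 1.9 × 10⁻⁴, which prints as 0.0002, where a one-sided
test would print 0.0001. A baseline with zero capable sites makes the
comparison untestable. dN/dS estimation is intentionally out of scope; the
census concerns third positions only.

## Numerical and degenerate-input conventions

* Coordinates are 1-based closed inside R (`GRanges`), 0-based half-open on
  disk (BED via `rtracklayer`); the k-mer position functions speak 0-based.
* Ties in the gene ranking break by gene id; cluster ids follow genomic
  order; all outputs are deterministically sorted.
* Every stochastic stage takes an explicit integer seed, and the pipeline
  derives per-stage seeds from one master seed, so a fixed configuration
  gives byte-identical FASTA/BED/TSV output across runs.
* Degenerate inputs (empty candidate sets, empty tracks, zero margins,
  single-element distance inputs, all-zero tables) produce flagged results or
  warnings, not exceptions; verification failures are logged events.
* Fragments and features that would cross a chromosome end are clipped with
  a warning (tracks) or terminate the tiling (reference elements).

## Problem sizes used by the test suite

The suite runs entirely on simulated data: detection is checked against the
brute-force scanner on 200 cohorts of 0.7–1 kb references with 3–6 species
and divergence 0–0.3; enrichment calibration uses 100 unbiased six-factor
families and 60 biased runs at the conditions above; Fisher agreement with
enumeration is exhaustive for small table totals plus randomized larger
tables. These sizes were chosen so the whole suite is a desk-scale exercise
of every code path; assembly-scale runs (twelve fly genomes, ~10⁸ seeds) use
the identical code but need the public assemblies on disk and are not part of
the tests.

## Known limitations

* No synteny checking: an element present everywhere but translocated in one
  species is still a UCE by this definition (decoys show the near-miss case).
* The k-mer index is held in memory; full insect-genome cohorts fit on a
  workstation, but the brute-force scanner does not scale past desk size.
* The distance null's rank-sum test is conservative (see above).
* Bisection can emit overlapping verified halves of a chimeric candidate by
  design; downstream counting treats them as separate elements.
* The simulators do not model indels, shared phylogeny, or base composition;
  conclusions from passing tests are about the machinery, not about any real
  genome cohort.
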