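# Seeded simulators: genome cohorts with planted ultraconserved elements
# and near-identical decoys, annotation/peak/editing tracks with a
# controllable placement bias, and codon alignments with per-site truth
# flags. Every pipeline stage can be exercised against known ground truth.

#' Specify a planted ultraconserved element
#'
#' A planted element receives zero substitutions in every simulated
#' species, so by construction it is identical across the cohort.
#'
#' @param length element length in nt (>= 50 by default; shorter plants
#'   are allowed for small-k experiments).
#' @param chrom 1-based chromosome index.
#' @param position 0-based reference start coordinate.
#' @param sequence optional explicit DNA string (length must match);
#'   `NULL` draws a random ACGT sequence.
#' @export
plant_spec <- function(length, chrom = 1L, position, sequence = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    stopifnot(nchar(sequence) == length, grepl("^[ACGT]+$", sequence))
  }
  structure(list(length = as.integer(length), chrom = as.integer(chrom),
                 position = as.integer(position), sequence = sequence),
            class = "plant_spec")
}

#' Specify a decoy (near-ultraconserved) element
#'
#' A decoy emulates the false-positive mode of alignment-based UCE audits:
#' a sequence that is exactly conserved in most species but carries a
#' small number of mismatches in the `target_species`, so it must never be
#' reported as ultraconserved. Mismatch positions are evenly spaced
#' quantiles of the element, which keeps the longest clean sub-run below
#' the detection threshold for short decoys (a long decoy with one
#' off-centre mismatch genuinely contains a real UCE in its clean part).
#'
#' @param length decoy length in nt.
#' @param chrom 1-based chromosome index.
#' @param position 0-based reference start coordinate.
#' @param n_mismatches number of mismatched positions (>= 1) carried by
#'   each target species.
#' @param target_species integer indices (into the query species) that
#'   carry the mismatched copy; all other species carry an exact copy.
#' @export
decoy_spec <- function(length, chrom = 1L, position, n_mismatches = 1L,
                       target_species = 1L) {
  stopifnot(n_mismatches >= 1L, n_mismatches < length)
  structure(list(length = as.integer(length), chrom = as.integer(chrom),
                 position = as.integer(position),
                 n_mismatches = as.integer(n_mismatches),
                 target_species = as.integer(target_species)),
            class = "decoy_spec")
}

#' Specify a simulated genome cohort
#'
#' @param n_species total species count (reference + queries), >= 2.
#' @param chrom_lengths integer vector of chromosome lengths (each >= 100).
#' @param background_divergence per-site substitution probability per
#'   query genome, in [0, 1), applied i.i.d. outside planted/decoy
#'   regions. A star phylogeny: no substitutions are shared between
#'   queries.
#' @param plants list of [plant_spec()] objects.
#' @param decoys list of [decoy_spec()] objects.
#' @param n_runs optional list of `c(chrom, position, length)` triples of
#'   N-runs injected into the reference (emulating assembly gaps).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @export
cohort_spec <- function(n_species = 3L, chrom_lengths = 1000L,
                        background_divergence = 0.1, plants = list(),
                        decoys = list(), n_runs = list(), seed = 1L) {
  n_species <- as.integer(n_species)
  chrom_lengths <- as.integer(chrom_lengths)
  if (n_species < 2L) stop("n_species must be >= 2")
  if (any(chrom_lengths < 100L)) stop("chrom_lengths must all be >= 100")
  if (background_divergence < 0 || background_divergence >= 1) {
    stop("background_divergence must be in [0, 1)")
  }
  spec <- structure(
    list(n_species = n_species, chrom_lengths = chrom_lengths,
         background_divergence = background_divergence,
         plants = plants, decoys = decoys, n_runs = n_runs,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  feats <- c(spec$plants, spec$decoys)
  if (length(feats) == 0L) return(invisible(spec))
  chrom <- vapply(feats, `[[`, 1L, "chrom")
  start <- vapply(feats, `[[`, 1L, "position")
  len <- vapply(feats, `[[`, 1L, "length")
  lab <- c(if (length(spec$plants)) paste0("plant ", seq_along(spec$plants)),
           if (length(spec$decoys)) paste0("decoy ", seq_along(spec$decoys)))
  if (any(chrom < 1L | chrom > length(spec$chrom_lengths))) {
    stop("planted feature chromosome index out of range")
  }
  if (any(start < 0L | start + len > spec$chrom_lengths[chrom])) {
    stop("planted feature exceeds chromosome bounds")
  }
  # pairwise non-overlap with >= 50 nt separation between planted features
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(start[i])]
    if (length(o) > 1L) {
      gap <- start[o][-1] - (start[o] + len[o])[-length(o)]
      bad <- which(gap < 50L)
      if (length(bad)) {
        if (gap[bad[1]] < 0L) {
          stop(sprintf("planted features overlap: %s and %s",
                       lab[o[bad[1]]], lab[o[bad[1] + 1L]]))
        }
        stop(sprintf("planted features closer than 50 nt: %s and %s",
                     lab[o[bad[1]]], lab[o[bad[1] + 1L]]))
      }
    }
  }
  invisible(spec)
}

# evenly spaced 0-based mismatch offsets within a decoy of given length
decoy_mismatch_offsets <- function(length, n) {
  off <- unique(pmin(length - 1L, floor(length * seq_len(n) / (n + 1))))
  while (length(off) < n) off <- unique(c(off, sample.int(length, 1L) - 1L))
  sort(off)
}

# replace each base by a uniformly chosen different base
substitute_base <- function(base) {
  pick <- sample.int(3L, length(base), replace = TRUE)
  vapply(seq_along(base), function(i) {
    setdiff(DNA_ALPHABET, base[i])[pick[i]]
  }, character(1))
}

#' Simulate a genome cohort with planted elements and decoys
#'
#' The reference is an i.i.d. random ACGT genome with plant and decoy
#' sequences written at their specified coordinates. Each query genome is
#' the reference with independent substitutions at rate
#' `background_divergence` outside planted/decoy regions; planted regions
#' are copied exactly into every query, and each decoy's copy carries
#' exactly `n_mismatches` substitutions in every target species (and an
#' exact copy elsewhere).
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (a [genome_cohort()]) and `truth`, a
#'   `GRanges` of planted features with metadata columns `type`
#'   (`"planted"`/`"decoy"`) and `name`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    chroms <- paste0("chr", seq_along(spec$chrom_lengths))
    ref_chars <- lapply(spec$chrom_lengths, function(L) {
      sample(DNA_ALPHABET, L, replace = TRUE)
    })
    names(ref_chars) <- chroms

    put <- function(chars, feat, seqstr) {
      chars[[feat$chrom]][feat$position + seq_len(feat$length)] <-
        strsplit(seqstr, "")[[1]]
      chars
    }
    plant_seqs <- lapply(spec$plants, function(p) p$sequence %||% random_dna(p$length))
    decoy_seqs <- lapply(spec$decoys, function(d) random_dna(d$length))
    for (i in seq_along(spec$plants)) {
      ref_chars <- put(ref_chars, spec$plants[[i]], plant_seqs[[i]])
    }
    for (i in seq_along(spec$decoys)) {
      ref_chars <- put(ref_chars, spec$decoys[[i]], decoy_seqs[[i]])
    }
    for (nr in spec$n_runs) {
      ref_chars[[nr[1]]][nr[2] + seq_len(nr[3])] <- "N"
    }

    protected <- lapply(seq_along(chroms), function(ci) {
      keep <- rep(FALSE, spec$chrom_lengths[ci])
      for (f in c(spec$plants, spec$decoys)) {
        if (f$chrom == ci) keep[f$position + seq_len(f$length)] <- TRUE
      }
      keep
    })

    n_queries <- spec$n_species - 1L
    queries <- vector("list", n_queries)
    names(queries) <- sprintf("query_%02d", seq_len(n_queries))
    for (q in seq_len(n_queries)) {
      qchars <- ref_chars
      for (ci in seq_along(chroms)) {
        hit <- which(stats::runif(spec$chrom_lengths[ci]) <
                       spec$background_divergence & !protected[[ci]] &
                       qchars[[ci]] != "N")
        if (length(hit)) {
          qchars[[ci]][hit] <- substitute_base(qchars[[ci]][hit])
        }
      }
      for (d in spec$decoys) {
        if (q %in% d$target_species) {
          off <- decoy_mismatch_offsets(d$length, d$n_mismatches)
          pos <- d$position + off + 1L
          qchars[[d$chrom]][pos] <- substitute_base(qchars[[d$chrom]][pos])
        }
      }
      queries[[q]] <- vapply(qchars, paste, character(1), collapse = "")
    }
    reference <- vapply(ref_chars, paste, character(1), collapse = "")

    feats <- c(spec$plants, spec$decoys)
    truth <- GenomicRanges::GRanges(
      seqnames = if (length(feats)) chroms[vapply(feats, `[[`, 1L, "chrom")] else character(0),
      ranges = IRanges::IRanges(
        start = vapply(feats, `[[`, 1L, "position") + 1L,
        width = vapply(feats, `[[`, 1L, "length")),
      type = rep(c("planted", "decoy"),
                 c(length(spec$plants), length(spec$decoys))),
      name = c(if (length(spec$plants)) sprintf("plant_%02d", seq_along(spec$plants)),
               if (length(spec$decoys)) sprintf("decoy_%02d", seq_along(spec$decoys)))
    )
    list(cohort = genome_cohort(reference, queries), truth = sort(truth))
  })
}

#' Specify simulated annotation and functional tracks
#'
#' @param n_genes number of protein-coding gene models.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param mean_exon_len,mean_intron_len,mean_intergenic mean feature
#'   lengths in nt (exponential draws, floored).
#' @param n_ncrna number of non-coding RNA intervals.
#' @param peaks named list, one entry per factor:
#'   `list(n_peaks =, width = c(min, max), uce_bias =, stage =)`. With
#'   `uce_bias = 1` peak placement is uniform over the genome; with bias
#'   `b` the per-nt density of peak centres inside planted elements is `b`
#'   times the density outside.
#' @param editing_density expected RNA-editing sites per exonic nt.
#' @param frac_nonconstitutive fraction of exons flagged non-constitutive
#'   (alternatively spliced).
#' @param seed integer seed.
#' @export
track_spec <- function(n_genes = 20L, exons_per_gene = c(2L, 6L),
                       mean_exon_len = 150, mean_intron_len = 300,
                       mean_intergenic = 500, n_ncrna = 3L,
                       peaks = list(), editing_density = 0.005,
                       frac_nonconstitutive = 0.4, seed = 1L) {
  stopifnot(length(exons_per_gene) == 2L, exons_per_gene[1] >= 1L,
            editing_density >= 0, frac_nonconstitutive >= 0,
            frac_nonconstitutive <= 1)
  for (p in peaks) {
    stopifnot(p$n_peaks >= 0L, length(p$width) == 2L,
              (p$uce_bias %||% 1) >= 0)
  }
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 mean_exon_len = mean_exon_len,
                 mean_intron_len = mean_intron_len,
                 mean_intergenic = mean_intergenic,
                 n_ncrna = as.integer(n_ncrna), peaks = peaks,
                 editing_density = editing_density,
                 frac_nonconstitutive = frac_nonconstitutive,
                 seed = as.integer(seed)),
            class = "track_spec")
}

rlen <- function(n, mean) pmax(10L, as.integer(round(stats::rexp(n, 1 / mean))))

#' Simulate annotation, ChIP-peak, RNA-editing and exon tracks
#'
#' Gene models are laid left-to-right along each chromosome with
#' exponential intergenic gaps; each gene has one transcript whose exons
#' and introns alternate. Peaks are placed by a two-component mixture:
#' with probability `b*A / (b*A + (G - A))` (where `A` is the total
#' planted-element length, `G` the genome length and `b` the factor's
#' `uce_bias`) the peak centre falls uniformly inside a planted element,
#' otherwise uniformly outside, so `b = 1` reduces to genome-wide uniform
#' placement. Features running past a chromosome end are clipped with a
#' warning.
#'
#' @param chrom_lengths named integer vector of reference chromosome
#'   lengths, or a [genome_cohort()] (its reference lengths are used).
#' @param spec a [track_spec()].
#' @param truth optional `GRanges` of planted elements (from
#'   [simulate_cohort()]); required when any factor has `uce_bias != 1`.
#' @return list with `annotations` (an [annotation_set()]), `peaks`
#'   (named list of `GRanges`, one per factor, with a `stage` attribute),
#'   `editing` (`GRanges` of single-nt sites) and `exons` (the annotated
#'   exon `GRanges` carrying the `constitutive` flag).
#' @export
simulate_tracks <- function(chrom_lengths, spec, truth = NULL) {
  stopifnot(inherits(spec, "track_spec"))
  if (inherits(chrom_lengths, "genome_cohort")) {
    chrom_lengths <- nchar(chrom_lengths$reference)
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  with_seed(spec$seed, {
    genes <- list(); exons <- list(); gid <- 0L
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      pos <- rlen(1L, spec$mean_intergenic)
      repeat {
        gid_local <- gid + 1L
        n_ex <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]), 1L)
        ex_len <- rlen(n_ex, spec$mean_exon_len)
        in_len <- if (n_ex > 1L) rlen(n_ex - 1L, spec$mean_intron_len) else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (pos + span > L) break
        starts <- pos + c(0L, cumsum(ex_len[-n_ex] + in_len))
        gene_id <- sprintf("gene_%03d", gid_local)
        strand <- sample(c("+", "-"), 1L)
        genes[[gene_id]] <- data.frame(
          chrom = ch, start = pos + 1L, end = pos + span,
          gene_id = gene_id, strand = strand)
        exons[[gene_id]] <- data.frame(
          chrom = ch, start = starts + 1L, end = starts + ex_len,
          gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
          strand = strand)
        gid <- gid_local
        pos <- pos + span + rlen(1L, spec$mean_intergenic)
        if (gid >= spec$n_genes) break
      }
      if (gid >= spec$n_genes) break
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    if (is.null(genes)) stop("no gene fits the chromosome lengths; enlarge the genome")

    genes_gr <- GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(genes$start, genes$end), strand = genes$strand,
      gene_id = genes$gene_id)
    exons_gr <- GenomicRanges::GRanges(exons$chrom,
      IRanges::IRanges(exons$start, exons$end), strand = exons$strand,
      gene_id = exons$gene_id, transcript_id = exons$transcript_id,
      exon_id = sprintf("exon_%04d", seq_len(nrow(exons))),
      constitutive = stats::runif(nrow(exons)) >= spec$frac_nonconstitutive)

    # ncRNAs in intergenic space
    nc <- list()
    if (spec$n_ncrna > 0L) {
      for (i in seq_len(spec$n_ncrna)) {
        ch <- sample(names(chrom_lengths), 1L)
        len <- rlen(1L, 80)
        st <- sample.int(max(1L, chrom_lengths[[ch]] - len), 1L)
        nc[[i]] <- data.frame(chrom = ch, start = st, end = st + len - 1L)
      }
      nc <- do.call(rbind, nc)
      nc_gr <- GenomicRanges::GRanges(nc$chrom, IRanges::IRanges(nc$start, nc$end),
                                      name = sprintf("ncrna_%02d", seq_len(nrow(nc))))
    } else {
      nc_gr <- GenomicRanges::GRanges()
    }

    ann <- annotation_set(genes_gr, exons_gr, nc_gr)

    # peak placement mixture
    G <- sum(chrom_lengths)
    plants <- if (!is.null(truth)) truth[truth$type == "planted"] else
      GenomicRanges::GRanges()
    A <- sum(GenomicRanges::width(plants))
    peak_sets <- list()
    for (fac in names(spec$peaks)) {
      p <- spec$peaks[[fac]]
      b <- p$uce_bias %||% 1
      if (b != 1 && A == 0) {
        stop("uce_bias != 1 requires planted-element truth intervals")
      }
      w_bias <- if (A > 0) b * A / (b * A + (G - A)) else 0
      n <- p$n_peaks
      if (n == 0L) {
        peak_sets[[fac]] <- GenomicRanges::GRanges()
        attr(peak_sets[[fac]], "stage") <- p$stage %||% "embryo"
        next
      }
      widths <- sample(seq(p$width[1], p$width[2]), n, replace = TRUE)
      n_biased <- sum(stats::runif(n) < w_bias)
      centers_ch <- character(0); centers <- integer(0)
      if (n_biased > 0L) {
        j <- sample.int(length(plants), n_biased, replace = TRUE,
                        prob = GenomicRanges::width(plants))
        off <- floor(stats::runif(n_biased) * GenomicRanges::width(plants)[j])
        centers_ch <- as.character(GenomicRanges::seqnames(plants))[j]
        centers <- GenomicRanges::start(plants)[j] + as.integer(off)
      }
      need <- n - n_biased
      while (need > 0L) {  # vectorised rejection of draws inside plants
        ch <- sample(names(chrom_lengths), need, replace = TRUE,
                     prob = unlist(chrom_lengths))
        pos <- floor(stats::runif(need) * unlist(chrom_lengths)[ch]) + 1L
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos))
        keep <- if (length(plants)) {
          !suppressWarnings(IRanges::overlapsAny(cand, plants,
                                                 ignore.strand = TRUE))
        } else rep(TRUE, need)
        centers_ch <- c(centers_ch, ch[keep])
        centers <- c(centers, as.integer(pos[keep]))
        need <- need - sum(keep)
      }
      st <- pmax(1L, centers - widths %/% 2L)
      en <- pmin(unlist(chrom_lengths)[centers_ch], st + widths - 1L)
      clipped <- sum(en - st + 1L < widths)
      if (clipped > 0L) {
        warning(sprintf("%d peak(s) of factor %s clipped at chromosome ends",
                        clipped, fac))
      }
      gr <- GenomicRanges::GRanges(centers_ch, IRanges::IRanges(st, en))
      gr <- sort(gr)
      attr(gr, "stage") <- p$stage %||% "embryo"
      peak_sets[[fac]] <- gr
    }

    # RNA-editing sites: Poisson over exonic nucleotides
    ex_red <- GenomicRanges::reduce(exons_gr, ignore.strand = TRUE)
    tot_ex <- sum(GenomicRanges::width(ex_red))
    n_ed <- stats::rpois(1L, spec$editing_density * tot_ex)
    if (n_ed > 0L && tot_ex > 0L) {
      off <- sample.int(tot_ex, n_ed, replace = TRUE)
      cum <- cumsum(GenomicRanges::width(ex_red))
      idx <- findInterval(off - 0.5, c(0L, cum))  # exon holding the off-th exonic nt
      within <- off - c(0L, cum)[idx]             # 1-based offset inside that exon
      ed_gr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(ex_red)[idx],
        IRanges::IRanges(GenomicRanges::start(ex_red)[idx] + within - 1L,
                         width = 1L))
      ed_gr <- sort(unique(ed_gr))
    } else {
      ed_gr <- GenomicRanges::GRanges()
    }

    list(annotations = ann, peaks = peak_sets, editing = ed_gr,
         exons = exons_gr)
  })
}

#' Specify a simulated codon alignment
#'
#' @param n_codons number of codons (>= 1).
#' @param n_species total species count including the reference.
#' @param rate per-codon third-position substitution probability per
#'   non-reference species.
#' @param constraint_mode `"free"` (any third-position base),
#'   `"synonymous_only"` (substitutions never change the amino acid) or
#'   `"invariant"` (no substitutions at all).
#' @param seed integer seed.
#' @export
codon_aln_spec <- function(n_codons, n_species = 12L, rate = 0.3,
                           constraint_mode = c("free", "synonymous_only",
                                               "invariant"),
                           seed = 1L) {
  constraint_mode <- match.arg(constraint_mode)
  stopifnot(n_codons >= 1L, n_species >= 2L, rate >= 0, rate <= 1)
  structure(list(n_codons = as.integer(n_codons),
                 n_species = as.integer(n_species), rate = rate,
                 constraint_mode = constraint_mode, seed = as.integer(seed)),
            class = "codon_aln_spec")
}

#' Simulate an in-frame codon alignment with per-site truth flags
#'
#' The reference row is drawn from the 61 sense codons; each non-reference
#' species substitutes the third position of each codon independently with
#' probability `rate`, under the spec's constraint mode. Truth flags
#' record, per codon, whether any species carries a synonymous (or
#' nonsynonymous) third-position substitution relative to the reference.
#'
#' @param spec a [codon_aln_spec()].
#' @return list with `alignment` (a [codon_alignment()]) and `truth`, a
#'   data.frame with per-codon columns `codon`, `synonymous_capable`,
#'   `substituted_synonymous`, `substituted_nonsynonymous`.
#' @export
simulate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "codon_aln_spec"))
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  with_seed(spec$seed, {
    ref_codons <- sample(sense, spec$n_codons, replace = TRUE)
    n_q <- spec$n_species - 1L
    rows <- matrix(rep(ref_codons, each = n_q), nrow = n_q)
    syn_truth <- rep(FALSE, spec$n_codons)
    nonsyn_truth <- rep(FALSE, spec$n_codons)
    if (spec$constraint_mode != "invariant") {
      for (s in seq_len(n_q)) {
        hit <- which(stats::runif(spec$n_codons) < spec$rate)
        for (i in hit) {
          cod <- ref_codons[i]
          third <- substr(cod, 3L, 3L)
          alts <- setdiff(DNA_ALPHABET, third)
          variants <- paste0(substr(cod, 1L, 2L), alts)
          if (spec$constraint_mode == "synonymous_only") {
            variants <- variants[code[variants] == code[cod]]
            if (length(variants) == 0L) next  # Met/Trp: no synonymous move
          } else {
            variants <- variants[code[variants] != "*"]
            if (length(variants) == 0L) next
          }
          new <- variants[sample.int(length(variants), 1L)]
          rows[s, i] <- new
          if (code[new] == code[cod]) syn_truth[i] <- TRUE else nonsyn_truth[i] <- TRUE
        }
      }
    }
    species <- c("reference", sprintf("species_%02d", seq_len(n_q)))
    seqs <- c(paste(ref_codons, collapse = ""),
              apply(rows, 1L, paste, collapse = ""))
    names(seqs) <- species
    aln <- codon_alignment(seqs, reference = "reference")
    capable <- synonymous_capable(ref_codons)
    list(alignment = aln,
         truth = data.frame(codon = ref_codons,
                            synonymous_capable = as.logical(capable),
                            substituted_synonymous = syn_truth,
                            substituted_nonsynonymous = nonsyn_truth))
  })
}
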