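# Alignment-free detection of ultraconserved elements (UCEs):
# reference-unique k-mer seeds -> universality across all query genomes ->
# fusion of genomically overlapping seeds -> verification of the
# reconstituted elements.

#' Positions of reference-unique k-mers
#'
#' Scans a reference genome and returns the start positions of every k-mer
#' that occurs exactly once. Under `strand_mode = "both"` an occurrence of
#' the reverse complement anywhere in the genome counts against uniqueness,
#' so a palindromic k-mer (its own reverse complement) always counts at
#' least twice and is excluded. Windows containing N are excluded when
#' `exclude_n` is `TRUE`.
#'
#' Positions are 0-based, matching the on-disk BED convention used for all
#' interval output; the k-mer at position `p` covers `[p, p + k)`.
#'
#' @param reference a genome (named character vector or `DNAStringSet`).
#' @param k seed length in nucleotides (default 50, minimum 8).
#' @param strand_mode `"both"` (count forward occurrences plus occurrences
#'   of the reverse complement) or `"forward"`.
#' @param exclude_n drop windows containing N (default `TRUE`).
#' @return data.frame with columns `chrom` and `pos` (0-based start),
#'   sorted by chromosome then position.
#' @export
extract_unique_kmers <- function(reference, k = 50L,
                                 strand_mode = c("both", "forward"),
                                 exclude_n = TRUE) {
  strand_mode <- match.arg(strand_mode)
  reference <- as_genome(reference)
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  if (k > max(nchar(reference))) {
    warning("k exceeds the longest reference sequence; no k-mers to extract")
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  win <- lapply(reference, seq_windows, k = k)
  kmer <- unlist(lapply(win, `[[`, "kmer"), use.names = FALSE)
  pos <- unlist(lapply(win, `[[`, "pos"), use.names = FALSE)
  chrom <- rep(names(reference), vapply(win, function(w) length(w$pos), 1L))

  valid <- if (exclude_n) !grepl("N", kmer, fixed = TRUE) else rep(TRUE, length(kmer))
  uk <- unique(kmer[valid])
  fwd_count <- tabulate(match(kmer[valid], uk), nbins = length(uk))

  total <- rep(NA_integer_, length(kmer))
  idx <- match(kmer, uk)
  total[valid] <- fwd_count[idx[valid]]
  if (strand_mode == "both") {
    rc_idx <- match(rev_comp(kmer[valid]), uk)
    extra <- ifelse(is.na(rc_idx), 0L, fwd_count[rc_idx])
    total[valid] <- total[valid] + extra
  }
  keep <- valid & !is.na(total) & total == 1L
  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Test whether a sequence occurs exactly in every query genome
#'
#' A sequence is universal if an exact match (on the forward strand, or on
#' either strand under `strand_mode = "both"`) exists in every query
#' genome. Multiple occurrences within a query are permitted: uniqueness
#' is a property of the reference only.
#'
#' @param sequence a DNA string over ACGT.
#' @param queries list of query genomes (named character vectors or
#'   `DNAStringSet`s), or a `genome_cohort` (its queries are used).
#' @param strand_mode `"both"` or `"forward"`.
#' @return `TRUE` iff the sequence (or, under `"both"`, its reverse
#'   complement) has an exact occurrence in every query genome.
#' @export
is_universal <- function(sequence, queries, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(queries, "genome_cohort")) queries <- queries$queries
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  rc <- if (strand_mode == "both") rev_comp(sequence) else NULL
  for (q in queries) {
    if (!is.character(q)) q <- as_genome(q)  # cohort queries are pre-normalised
    hit <- any(grepl(sequence, q, fixed = TRUE))
    if (!hit && !is.null(rc)) hit <- any(grepl(rc, q, fixed = TRUE))
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Fuse genomically overlapping seed windows into candidate intervals
#'
#' Two seed windows `[p, p+k)` and `[q, q+k)` with `p < q` overlap (share
#' at least one base) iff `q - p <= k - 1`; candidates are the maximal
#' unions of transitively overlapping seeds. Windows that merely abut
#' (`q - p == k`) are not fused.
#'
#' @param positions integer vector of 0-based seed start positions on one
#'   chromosome (sorted ascending; unsorted input is sorted).
#' @param k seed length.
#' @return data.frame with 0-based half-open columns `start`, `end` and the
#'   seed count `n_seeds` per candidate.
#' @export
fuse_seeds <- function(positions, k) {
  positions <- sort(unique(as.integer(positions)))
  k <- as.integer(k)
  if (length(positions) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), n_seeds = integer(0)))
  }
  gap_break <- c(FALSE, diff(positions) > k - 1L)
  grp <- cumsum(gap_break)
  start <- tapply(positions, grp, min)
  last <- tapply(positions, grp, max)
  data.frame(start = as.integer(start),
             end = as.integer(last) + k,
             n_seeds = as.integer(table(grp)),
             row.names = NULL)
}

# Recursive verification of one fused candidate. `seeds` are the 0-based
# start positions of its member k-mers. A candidate whose full sequence is
# not universal is bisected at the median seed, each half re-fused and
# re-verified; verified sub-elements >= min_length are emitted. Returns a
# data.frame of emitted intervals plus a log of dropped remainders.
verify_candidate <- function(seeds, chromseq, queries, k, min_length, strand_mode, log_env) {
  if (length(seeds) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- min(seeds)
  end <- max(seeds) + k
  s <- substr(chromseq, start + 1L, end)
  if (is_universal(s, queries, strand_mode)) {
    if (nchar(s) >= min_length) {
      return(data.frame(start = start, end = end))
    }
    log_env$log <- rbind(log_env$log, data.frame(
      start = start, end = end, reason = "verified_below_min_length"))
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (length(seeds) == 1L) {
    # a single seed is a reference-unique universal k-mer by construction;
    # reaching this branch means the seed itself failed, which only happens
    # when candidates were supplied from outside the seed pipeline
    log_env$log <- rbind(log_env$log, data.frame(
      start = start, end = end, reason = "unverifiable_single_seed"))
    return(data.frame(start = integer(0), end = integer(0)))
  }
  log_env$bisections <- log_env$bisections + 1L
  h <- floor(length(seeds) / 2)
  halves <- list(seeds[seq_len(h)], seeds[(h + 1L):length(seeds)])
  out <- lapply(halves, function(hs) {
    refused <- fuse_seeds(hs, k)
    do.call(rbind, lapply(seq_len(nrow(refused)), function(i) {
      sub <- hs[hs >= refused$start[i] & hs <= refused$end[i] - k]
      verify_candidate(sub, chromseq, queries, k, min_length, strand_mode, log_env)
    }))
  })
  do.call(rbind, out)
}

#' Verify fused candidates and emit ultraconserved elements
#'
#' Each candidate whose full reference sequence is universal across the
#' query genomes is emitted. A failing candidate (its seeds are
#' individually universal but match different loci in some query) is
#' recursively bisected at the median seed; verified sub-elements of at
#' least `min_length` are emitted and unverifiable remainders are logged
#' and dropped, never raised as errors. Note that the two verified halves
#' of a bisected candidate share the reference bases of the boundary seed
#' overlap, so bisection is the one code path that can yield overlapping
#' output elements.
#'
#' @param candidates data.frame from [fuse_seeds()] (`start`, `end`,
#'   0-based half-open) for one chromosome, or a per-chromosome list.
#' @param seeds data.frame of seed positions (as from
#'   [extract_unique_kmers()]) restricted to universal seeds.
#' @param cohort a [genome_cohort()].
#' @param k,min_length,strand_mode detection parameters (see
#'   [detect_uces()]).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `sequence`; attribute `"log"` holds dropped intervals
#'   and `"bisections"` the number of bisection events.
#' @export
verify_and_emit <- function(candidates, seeds, cohort, k = 50L,
                            min_length = 50L,
                            strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(cohort, "genome_cohort"))
  log_env <- new.env()
  log_env$log <- data.frame(start = integer(0), end = integer(0),
                            reason = character(0))
  log_env$bisections <- 0L
  out <- list()
  for (chrom in unique(candidates$chrom %||% names(cohort$reference)[1])) {
    cand <- if (!is.null(candidates$chrom)) {
      candidates[candidates$chrom == chrom, , drop = FALSE]
    } else candidates
    sd <- if (!is.null(seeds$chrom)) {
      seeds$pos[seeds$chrom == chrom]
    } else seeds$pos
    chromseq <- cohort$reference[[chrom]]
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      member <- sd[sd >= cand$start[i] & sd <= cand$end[i] - k]
      verify_candidate(member, chromseq, cohort$queries, k, min_length,
                       strand_mode, log_env)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows) > 0L) {
      rows$chrom <- chrom
      rows$sequence <- substring(chromseq, rows$start + 1L, rows$end)
      out[[chrom]] <- rows[, c("chrom", "start", "end", "sequence")]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               sequence = character(0))
  rownames(res) <- NULL
  attr(res, "log") <- log_env$log
  attr(res, "bisections") <- log_env$bisections
  res
}

#' Detect ultraconserved elements across a genome cohort
#'
#' Composes the four detection stages: extract reference-unique k-mers,
#' keep those with an exact match in every query genome, fuse genomically
#' overlapping universal seeds into candidates, and verify that each
#' reconstituted candidate sequence itself occurs in every query genome.
#'
#' @param cohort a [genome_cohort()].
#' @param k seed length (default 50 nt).
#' @param min_length minimal reported element length (default 50 nt; must
#'   be >= `k`).
#' @param strand_mode `"both"` (default): uniqueness and universality count
#'   both strands; `"forward"` restricts matching to the forward strand.
#' @param exclude_n drop seed windows containing N.
#' @return a [GenomicRanges::GRanges] in reference coordinates (1-based in
#'   memory; written 0-based half-open as BED), sorted by chromosome and
#'   start, with metadata columns `name`, `length` and `sequence`. The
#'   run manifest (parameters, genome checksums, seed/bisection counts)
#'   is stored in `S4Vectors::metadata(x)$manifest`.
#' @examples
#' ref <- c(chr1 = paste(rep("ACGT", 60), collapse = ""))
#' # an identity cohort: the whole chromosome is ultraconserved, but no
#' # k-mer is unique in this repetitive toy sequence, so nothing is found
#' detect_uces(genome_cohort(ref, list(q1 = ref)), k = 8, min_length = 8)
#' @export
detect_uces <- function(cohort, k = 50L, min_length = 50L,
                        strand_mode = c("both", "forward"),
                        exclude_n = TRUE) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(cohort, "genome_cohort"))
  k <- as.integer(k)
  min_length <- as.integer(min_length)
  if (min_length < k) stop("min_length must be >= k")

  uniq <- extract_unique_kmers(cohort$reference, k = k,
                               strand_mode = strand_mode,
                               exclude_n = exclude_n)

  # universality of seeds via per-query k-mer membership sets
  if (nrow(uniq) > 0L) {
    kmers <- unlist(lapply(unique(uniq$chrom), function(ch) {
      w <- seq_windows(cohort$reference[[ch]], k)
      w$kmer[match(uniq$pos[uniq$chrom == ch], w$pos)]
    }), use.names = FALSE)
    rc <- if (strand_mode == "both") rev_comp(kmers) else NULL
    universal <- rep(TRUE, length(kmers))
    for (q in cohort$queries) {
      qset <- unique(unlist(lapply(q, function(s) seq_windows(s, k)$kmer),
                            use.names = FALSE))
      hit <- kmers %in% qset
      if (!is.null(rc)) hit <- hit | (rc %in% qset)
      universal <- universal & hit
      if (!any(universal)) break
    }
    uniq <- uniq[universal, , drop = FALSE]
  }

  per_chrom <- lapply(unique(uniq$chrom), function(ch) {
    cand <- fuse_seeds(uniq$pos[uniq$chrom == ch], k)
    if (nrow(cand) == 0L) return(NULL)
    cand$chrom <- ch
    cand
  })
  cand_all <- do.call(rbind, per_chrom)
  if (is.null(cand_all) || nrow(cand_all) == 0L) {
    emitted <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), sequence = character(0))
    attr(emitted, "log") <- data.frame()
    attr(emitted, "bisections") <- 0L
  } else {
    emitted <- verify_and_emit(cand_all, uniq, cohort, k = k,
                               min_length = min_length,
                               strand_mode = strand_mode)
  }

  emitted <- emitted[order(emitted$chrom, emitted$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = emitted$chrom,
    ranges = IRanges::IRanges(start = emitted$start + 1L, end = emitted$end),
    name = if (nrow(emitted)) sprintf("uce_%04d", seq_len(nrow(emitted))) else character(0),
    length = emitted$end - emitted$start,
    sequence = emitted$sequence
  )
  S4Vectors::metadata(gr)$manifest <- list(
    k = k, min_length = min_length, strand_mode = strand_mode,
    exclude_n = exclude_n,
    n_queries = length(cohort$queries),
    n_seeds = nrow(uniq),
    n_bisections = attr(emitted, "bisections"),
    dropped = attr(emitted, "log"),
    genome_checksums = c(
      reference = genome_checksum(cohort$reference),
      vapply(cohort$queries, genome_checksum, character(1))
    )
  )
  gr
}

#' Direct scan for maximal universal substrings
#'
#' Reference scanner for small cohorts: finds every maximal substring of
#' the reference, of at least `min_length` nt, whose sequence occurs
#' exactly in every query genome. It extends a window base by base with a
#' full substring search at every step and never looks at k-mer
#' uniqueness, so it is quadratic-ish and only suitable for desk-scale
#' genomes, but it is independent of the seed-and-fuse machinery in
#' [detect_uces()] and serves as its cross-check.
#'
#' @inheritParams detect_uces
#' @param min_length minimal reported substring length.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `sequence`.
#' @export
scan_universal_substrings <- function(cohort, min_length = 50L,
                                      strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(cohort, "genome_cohort"))
  out <- list()
  for (chrom in names(cohort$reference)) {
    seqc <- cohort$reference[[chrom]]
    L <- nchar(seqc)
    e <- 0L
    prev_u <- 0L
    starts <- integer(0); ends <- integer(0)
    for (s in 0:(L - 1L)) {
      if (e < s) e <- s
      while (e < L) {
        cand <- substr(seqc, s + 1L, e + 1L)
        if (grepl("N", cand, fixed = TRUE)) break
        if (!is_universal(cand, cohort$queries, strand_mode)) break
        e <- e + 1L
      }
      if (e - s >= min_length && (s == 0L || e > prev_u)) {
        starts <- c(starts, s); ends <- c(ends, e)
      }
      prev_u <- e
    }
    if (length(starts)) {
      out[[chrom]] <- data.frame(
        chrom = chrom, start = starts, end = ends,
        sequence = substring(seqc, starts + 1L, ends))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               sequence = character(0))
  rownames(res) <- NULL
  res
}
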