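# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of character DNA sequences (vectorised).
#'
#' Character-level (chartr + byte reversal): called in tight inner loops
#' where per-call XStringSet construction would dominate the runtime.
#' @noRd
rev_comp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(chartr("ACGTN", "TGCAN", x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA string of length n (uses current RNG stream)
#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Normalise a genome to a named uppercase character vector.
#'
#' Accepts a `Biostrings::DNAStringSet` or a (named) character vector.
#' Lowercase (soft-masked) bases are uppercased; any IUPAC ambiguity code
#' other than A/C/G/T is mapped to N so that exact matching treats it as
#' unresolvable.
#' @noRd
as_genome <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L) {
    stop("a genome must be a non-empty character vector or DNAStringSet")
  }
  if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
  x <- toupper(x)
  x <- gsub("[^ACGTN]", "N", x)
  x
}

#' All k-length windows of a sequence, with their 0-based start positions
#' @noRd
seq_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list(kmer = character(0), pos = integer(0)))
  n <- L - k + 1L
  list(kmer = substring(seq, seq_len(n), seq_len(n) + k - 1L),
       pos = seq_len(n) - 1L)
}

#' Count occurrences of `pattern` in a genome, both strands, overlapping
#' matches included. Used for unique-mapping checks.
#' @noRd
count_genome_occurrences <- function(pattern, genome_dss, both_strands = TRUE) {
  n <- sum(Biostrings::vcountPattern(pattern, genome_dss))
  if (both_strands) {
    n <- n + sum(Biostrings::vcountPattern(rev_comp(pattern), genome_dss))
  }
  n
}

#' md5 checksum of a genome's sequences (for run manifests)
#' @noRd
genome_checksum <- function(genome) {
  genome <- as_genome(genome)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(names(genome), genome), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
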