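#' Assemble a genome cohort
#'
#' A genome cohort bundles one reference assembly with one or more query
#' assemblies. Ultraconserved elements are reported in reference
#' coordinates; the queries are only searched for exact sequence matches,
#' so their coordinate systems never enter the analysis.
#'
#' Sequences may be given as named character vectors or
#' [Biostrings::DNAStringSet] objects; they are uppercased and any
#' ambiguity code other than A/C/G/T is mapped to N.
#'
#' @param reference named character vector or `DNAStringSet`: the reference
#'   assembly, one element per chromosome/scaffold.
#' @param queries named list of genomes (same representation as
#'   `reference`), one per query species.
#' @return an object of class `genome_cohort` with elements `reference`,
#'   `queries` and `species` (the query names).
#' @examples
#' cohort <- genome_cohort(
#'   reference = c(chr1 = "ACGTACGTACGT"),
#'   queries = list(spA = c(chr1 = "ACGTACGTACGT"))
#' )
#' @export
genome_cohort <- function(reference, queries) {
  reference <- as_genome(reference)
  if (!is.list(queries) || length(queries) == 0L) {
    stop("`queries` must be a non-empty list of genomes (at least one query species)")
  }
  queries <- lapply(queries, as_genome)
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- paste0("query_", seq_along(queries))
  }
  structure(
    list(reference = reference, queries = queries, species = names(queries)),
    class = "genome_cohort"
  )
}

#' @export
print.genome_cohort <- function(x, ...) {
  cat("genome_cohort:", length(x$queries) + 1L, "species\n")
  cat("  reference:", length(x$reference), "sequence(s),",
      sum(nchar(x$reference)), "nt\n")
  for (sp in names(x$queries)) {
    cat("  query", sp, ":", sum(nchar(x$queries[[sp]])), "nt\n")
  }
  invisible(x)
}
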