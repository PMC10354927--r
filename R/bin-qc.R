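#' Assembly statistics for a set of contigs
#'
#' Computes the standard MAG report card: total size, G+C content, contig
#' count, N50 and largest contig.  G+C is `100 * (G + C) / (A + C + G + T)`;
#' ambiguity codes are excluded from both numerator and denominator so runs
#' of N do not deflate the estimate.  N50 is the largest length `L` such that
#' contigs of length >= `L` sum to at least half the total assembly size
#' (descending cumulative sum).
#'
#' @param contigs named character vector of DNA sequences or a
#'   [Biostrings::DNAStringSet].
#' @return a list with elements `total_size`, `gc_percent` (two decimals),
#'   `n_contigs`, `n50`, `largest`.
#' @examples
#' assembly_stats(c(a = strrep("G", 40), b = strrep("AT", 15),
#'                  c = strrep("C", 20), d = strrep("A", 10)))
#' @export
assembly_stats <- function(contigs) {
  x <- as_dna_stringset(contigs)
  if (length(x) == 0L) stop("empty contig set")
  lens <- Biostrings::width(x)
  total <- sum(lens)
  freq <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- round(100 * (acgt[["G"]] + acgt[["C"]]) / sum(acgt), 2)
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(as.numeric(sl)) >= total / 2)[1L]]
  list(total_size = as.numeric(total), gc_percent = gc,
       n_contigs = length(x), n50 = as.numeric(n50),
       largest = as.numeric(sl[1L]))
}
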