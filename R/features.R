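#' Tile contigs into fixed-length fragments
#'
#' Large contigs are cut left-to-right into `fragment_len` pieces; contigs
#' shorter than `min_contig` are excluded altogether.  A trailing remainder
#' shorter than `min_contig` is merged into the preceding fragment (so no
#' fragment used for composition estimation falls below the `min_contig`
#' floor); a remainder of at least `min_contig` stands as its own fragment.
#'
#' @param contigs a named character vector of DNA sequences, or a
#'   [Biostrings::DNAStringSet]; names are the contig ids and must be unique.
#' @param fragment_len target fragment length in bp (default 10000).
#' @param min_contig minimum contig (and fragment) length in bp (default 1000).
#' @return a data.frame with columns `fragment_id`, `contig_id`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `length`.  Fragments of
#'   one contig tile it exactly.
#' @examples
#' fragment_contigs(c(c1 = paste(rep("ACGT", 3000), collapse = "")))
#' @export
fragment_contigs <- function(contigs, fragment_len = 10000L, min_contig = 1000L) {
  if (!(fragment_len > min_contig) || min_contig <= 0)
    stop("need fragment_len > min_contig > 0")
  lens <- contig_lengths(contigs)
  ids <- names(lens)
  if (is.null(ids) || any(ids == ""))
    stop("contigs must be named")
  if (anyDuplicated(ids))
    stop("duplicate contig ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(lens) == 0L) {
    warning("empty contig set: returning empty fragment table")
    return(empty_fragment_table())
  }
  keep <- lens >= min_contig
  rows <- lapply(which(keep), function(i) {
    L <- lens[[i]]
    starts <- seq.int(0L, L - 1L, by = fragment_len)
    ends <- pmin(starts + fragment_len, L)
    n <- length(starts)
    if (n > 1L && (ends[n] - starts[n]) < min_contig) {
      # merge short remainder into the preceding fragment
      ends[n - 1L] <- ends[n]
      starts <- starts[-n]; ends <- ends[-n]; n <- n - 1L
    }
    data.frame(
      fragment_id = sprintf("%s|%d", ids[[i]], seq_len(n)),
      contig_id = ids[[i]],
      start = as.integer(starts), end = as.integer(ends),
      length = as.integer(ends - starts),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) return(empty_fragment_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_fragment_table <- function() {
  data.frame(fragment_id = character(), contig_id = character(),
             start = integer(), end = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

contig_lengths <- function(contigs) {
  if (methods::is(contigs, "DNAStringSet")) {
    setNames(Biostrings::width(contigs), names(contigs))
  } else {
    setNames(nchar(contigs), names(contigs))
  }
}

as_dna_stringset <- function(contigs) {
  if (methods::is(contigs, "DNAStringSet")) contigs
  else Biostrings::DNAStringSet(toupper(unlist(contigs)))
}

#' Tetranucleotide frequencies of a sequence
#'
#' Counts every overlapping 4-mer window on the given strand whose four bases
#' are all unambiguous (A/C/G/T, case-insensitive); windows containing any
#' other code (N, IUPAC ambiguity, gap) are skipped, shrinking the
#' denominator rather than biasing the counts.  Frequencies are returned in
#' fixed lexicographic order AAAA..TTTT and sum to 1.
#'
#' @param sequence a single DNA string (or a `DNAString`); length >= 4.
#' @return a named numeric vector of length 256.
#' @examples
#' f <- tetramer_frequencies("ACGTACGT")
#' f[f > 0]
#' @export
tetramer_frequencies <- function(sequence) {
  m <- tetramer_counts(sequence)
  n <- sum(m)
  if (n == 0L)
    stop("no valid 4-mer window (every window contains an ambiguous base) in: ",
         substr(as.character(sequence), 1, 40))
  m / n
}

tetramer_counts <- function(sequence) {
  x <- if (methods::is(sequence, "DNAString")) sequence
       else Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(x) < 4L) stop("sequence shorter than 4 bp")
  Biostrings::oligonucleotideFrequency(x, width = 4L)
}

#' Mean read depth per fragment
#'
#' Two depth dialects are supported.  *Per-base*: a samtools-depth-style
#' table with columns `contig_id`, `pos` (1-based), `depth`; the fragment
#' mean is taken over all its coordinates, with positions absent from the
#' table counted as depth 0.  *Per-contig*: a table with columns `contig_id`,
#' `mean_depth`; the contig mean is assigned to every fragment of the contig.
#'
#' @param depth a data.frame in one of the two dialects above (detected by
#'   column count/names), or a path to a TSV file of either dialect.
#' @param fragments a fragment table from [fragment_contigs()].
#' @return a named numeric vector: fragment_id -> mean depth.
#' @export
fragment_coverage <- function(depth, fragments) {
  if (is.character(depth) && length(depth) == 1L) depth <- read_depth(depth)
  stopifnot(is.data.frame(depth))
  per_base <- ncol(depth) >= 3L
  contigs_needed <- unique(fragments$contig_id)
  have <- unique(as.character(depth[[1L]]))
  missing <- setdiff(contigs_needed, have)
  if (length(missing) > 0L)
    stop("contigs absent from depth input: ", paste(missing, collapse = ", "))
  if (nrow(fragments) == 0L) return(setNames(numeric(0), character(0)))
  if (per_base) {
    names(depth)[1:3] <- c("contig_id", "pos", "depth")
    by_contig <- split(depth[, c("pos", "depth")], as.character(depth$contig_id))
    vapply(seq_len(nrow(fragments)), function(i) {
      d <- by_contig[[fragments$contig_id[i]]]
      lo <- fragments$start[i] + 1L  # depth positions are 1-based
      hi <- fragments$end[i]
      sel <- d$pos >= lo & d$pos <= hi
      sum(d$depth[sel]) / fragments$length[i]  # absent positions count as 0
    }, numeric(1), USE.NAMES = FALSE) |> setNames(fragments$fragment_id)
  } else {
    names(depth)[1:2] <- c("contig_id", "mean_depth")
    means <- setNames(depth$mean_depth, as.character(depth$contig_id))
    setNames(as.numeric(means[fragments$contig_id]), fragments$fragment_id)
  }
}

#' Assemble the 257-dimensional per-fragment feature matrix
#'
#' Column order is the 256 tetramer frequencies (AAAA..TTTT) followed by one
#' coverage column.  With the default scaling, coverage is first transformed
#' to `log10(1 + x)` — raw depth is unbounded and would otherwise dominate
#' frequencies (all <= 1) in embedding distances — and then every column is
#' z-scored; zero-variance columns are left at 0.  The scaling applied is
#' recorded in the `"scaling"` attribute.
#'
#' @param tetramers numeric matrix (fragments x 256), rows named by fragment.
#' @param coverages named numeric vector of per-fragment mean depth.
#' @param scaling `"log10_zscore"` (default) or `"none"` (raw frequencies and
#'   depth, no standardisation).
#' @return numeric matrix (fragments x 257) with attribute `"scaling"`.
#' @export
build_feature_matrix <- function(tetramers, coverages,
                                 scaling = c("log10_zscore", "none")) {
  scaling <- match.arg(scaling)
  a <- rownames(tetramers); b <- names(coverages)
  if (!setequal(a, b) || is.null(a) || is.null(b)) {
    stop("fragment sets differ; only in tetramers: ",
         paste(setdiff(a, b), collapse = ", "),
         "; only in coverages: ", paste(setdiff(b, a), collapse = ", "))
  }
  if (any(coverages < 0)) stop("negative coverage")
  x <- cbind(tetramers, coverage = as.numeric(coverages[a]))
  if (scaling == "log10_zscore") {
    x[, "coverage"] <- log10(1 + x[, "coverage"])
    x <- apply(x, 2L, function(col) {
      s <- sd(col)
      if (s == 0 || !is.finite(s)) rep(0, length(col)) else (col - mean(col)) / s
    })
    rownames(x) <- a
  }
  stopifnot(ncol(x) == 257L)
  attr(x, "scaling") <- scaling
  x
}
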