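#' Read and write contig FASTA
#'
#' Thin wrappers over [Biostrings] keeping ids unique and sequences upper-case.
#'
#' @param path FASTA file path.
#' @param contigs named character vector or `DNAStringSet`.
#' @return `read_contigs` returns a `DNAStringSet`; writers return `path`
#'   invisibly.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))  # keep the id token only
  if (anyDuplicated(names(x))) stop("duplicate contig ids in ", path)
  x
}

#' @rdname read_contigs
#' @export
write_contigs <- function(contigs, path) {
  Biostrings::writeXStringSet(as_dna_stringset(contigs), path)
  invisible(path)
}

#' Read / write depth tables
#'
#' Auto-detects the dialect: three columns means samtools-depth style
#' (`contig_id`, `pos` 1-based, `depth`); two columns means per-contig means
#' (`contig_id`, `mean_depth`).  Files are headerless TSV in the per-base
#' dialect (samtools convention) and headered in the per-contig dialect.
#'
#' @param path TSV file path.
#' @param depth a per-contig depth data.frame (`contig_id`, `mean_depth`).
#' @export
read_depth <- function(path) {
  first <- readLines(path, n = 1L)
  nfields <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (nfields >= 3L) {
    d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    names(d)[1:3] <- c("contig_id", "pos", "depth")
  } else {
    d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    names(d)[1:2] <- c("contig_id", "mean_depth")
  }
  d
}

#' @rdname read_depth
#' @export
write_depth <- function(depth, path) {
  write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = ncol(depth) < 3L)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' The gene-content reconstruction requires a rooted tree.  An unrooted
#' Newick input is an error unless a rooting strategy is supplied:
#' `outgroup = "leafname"` roots on that leaf's branch, `midpoint = TRUE`
#' midpoint-roots.
#'
#' @param path Newick file path (or an [ape::phylo] object).
#' @param outgroup optional leaf name to root on.
#' @param midpoint set `TRUE` to midpoint-root an unrooted input.
#' @return a rooted `phylo` with branch lengths.
#' @export
read_phylogeny <- function(path, outgroup = NULL, midpoint = FALSE) {
  tree <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick from ", path)
  if (!is.null(outgroup)) tree <- ape::root(tree, outgroup = outgroup,
                                            resolve.root = TRUE)
  else if (midpoint) tree <- phangorn::midpoint(tree)
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it first (outgroup= or midpoint=TRUE)")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names")
  tree
}

# Stable node names: leaf labels for tips, existing internal labels when
# present, otherwise "node<k>" with ape's internal numbering.
node_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  inner <- if (!is.null(tree$node.label) &&
               all(nzchar(tree$node.label))) tree$node.label
           else paste0("node", seq_len(n_node) + n_tip)
  c(tree$tip.label, inner)
}
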