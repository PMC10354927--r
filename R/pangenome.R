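#' Build a phyletic profile from a cluster-membership table
#'
#' Normalises external ortholog-clustering output (get_homologues/Roary
#' style, reduced to three columns) into a dense family x genome matrix of
#' copy counts.  Genomes absent from a family get 0; duplicate
#' (family, genome) rows are summed.
#'
#' @param membership a data.frame (or TSV path) with columns `family_id`,
#'   `genome_id`, `count` (a non-negative integer; omitted column means one
#'   member per row).
#' @param genomes optional character vector fixing the column set/order
#'   (e.g. the tree's leaf names); defaults to the genomes seen in the table.
#' @return integer matrix, rows = families (in first-appearance order),
#'   columns = genomes.
#' @export
build_profile <- function(membership, genomes = NULL) {
  if (is.character(membership) && length(membership) == 1L)
    membership <- read.table(membership, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  stopifnot(is.data.frame(membership))
  if (nrow(membership) == 0L) {
    warning("empty membership table: returning empty profile")
    return(matrix(0L, 0L, length(genomes),
                  dimnames = list(NULL, genomes)))
  }
  if (ncol(membership) == 2L) membership$count <- 1L
  names(membership)[1:3] <- c("family_id", "genome_id", "count")
  bad <- which(is.na(membership$count) | membership$count < 0 |
                 membership$count != floor(membership$count))
  if (length(bad) > 0L)
    stop("malformed membership rows (non-integer or negative count) at lines: ",
         paste(head(bad, 10L), collapse = ", "))
  fams <- unique(as.character(membership$family_id))
  gs <- if (is.null(genomes)) unique(as.character(membership$genome_id)) else genomes
  if (anyDuplicated(gs)) stop("genome names must be unique")
  unknown <- setdiff(unique(as.character(membership$genome_id)), gs)
  if (length(unknown) > 0L)
    stop("genomes in table but not in `genomes`: ", paste(unknown, collapse = ", "))
  prof <- matrix(0L, length(fams), length(gs), dimnames = list(fams, gs))
  for (i in seq_len(nrow(membership))) {
    prof[as.character(membership$family_id[i]),
         as.character(membership$genome_id[i])] <-
      prof[as.character(membership$family_id[i]),
           as.character(membership$genome_id[i])] + as.integer(membership$count[i])
  }
  prof
}

#' Core gene families of a profile
#'
#' The core genome is the set of families present (count >= 1) in every
#' genome of the profile; no soft-core threshold is applied.
#'
#' @param profile integer matrix, families x genomes.
#' @return character vector of core family ids, in profile row order.
#' @examples
#' p <- rbind(f1 = c(1, 2, 1), f2 = c(0, 5, 5), f3 = c(3, 3, 0))
#' colnames(p) <- c("g1", "g2", "g3")
#' core_families(p)
#' @export
core_families <- function(profile) {
  stopifnot(ncol(profile) >= 1L)
  rownames(profile)[apply(profile >= 1L, 1L, all)]
}

#' Read / write a phyletic profile TSV
#'
#' Rows are families, columns genomes, integer copy counts; the first column
#' (`family_id`) carries the row names.
#'
#' @param path file path.
#' @param profile integer matrix as returned by [build_profile()].
#' @return `read_profile` returns the integer matrix; `write_profile` is
#'   called for its side effect and returns `path` invisibly.
#' @export
read_profile <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(d[[1L]])
  m
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  d <- data.frame(family_id = rownames(profile), profile,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
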