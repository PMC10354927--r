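#' Embed the feature matrix in two dimensions with t-SNE
#'
#' Runs Barnes-Hut t-SNE on the 257-dimensional fragment features, with PCA
#' initialisation (first two principal-component scores scaled to sd 1e-4)
#' so that runs are reproducible for a fixed seed and input.  Perplexity,
#' seed and t-SNE settings are recorded as attributes of the result.
#'
#' @param features numeric matrix from [build_feature_matrix()].
#' @param perplexity t-SNE perplexity (default 30); needs at least
#'   `3 * perplexity + 1` fragments.
#' @param seed RNG seed (default 42).
#' @param max_iter t-SNE iterations (default 1000).
#' @return matrix (fragments x 2) of embedding coordinates, row names kept,
#'   with attributes `perplexity` and `seed`.
#' @export
embed_fragments <- function(features, perplexity = 30, seed = 42L,
                            max_iter = 1000L) {
  n <- nrow(features)
  if (n < 3 * perplexity + 1)
    stop("too few fragments (", n, ") for perplexity ", perplexity,
         "; use perplexity <= ", floor((n - 1) / 3))
  set.seed(seed)
  pc <- stats::prcomp(features, rank. = 2L, center = TRUE, scale. = FALSE)$x
  init <- 1e-4 * scale(pc, center = TRUE, scale = apply(pc, 2L, sd))
  fit <- Rtsne::Rtsne(features, dims = 2L, perplexity = perplexity,
                      Y_init = init, pca = FALSE, max_iter = max_iter,
                      check_duplicates = FALSE, verbose = FALSE)
  y <- fit$Y
  rownames(y) <- rownames(features)
  colnames(y) <- c("x", "y")
  attr(y, "perplexity") <- perplexity
  attr(y, "seed") <- seed
  y
}

#' Density-cluster the 2-D embedding
#'
#' HDBSCAN over the embedding coordinates; points in no sufficiently dense
#' region get the noise label 0.  The default minimum cluster size,
#' `max(15, 0.5%)` of the fragments, scales with community size.
#'
#' @param embedding matrix from [embed_fragments()].
#' @param min_cluster_size minimum fragments per cluster.
#' @return named integer vector of labels (0 = noise).
#' @export
cluster_fragments <- function(embedding,
                              min_cluster_size = max(15L, ceiling(0.005 * nrow(embedding)))) {
  if (nrow(embedding) < min_cluster_size)
    return(setNames(rep(0L, nrow(embedding)), rownames(embedding)))
  labels <- hdbscan_clusters(embedding[, 1:2, drop = FALSE], min_cluster_size)
  setNames(labels, rownames(embedding))
}

#' Merge fragment clusters back into contig bins
#'
#' Each contig is assigned by a length-weighted majority vote over the
#' non-noise labels of its fragments.  Contigs whose fragments are all noise,
#' or whose top vote is tied, stay unbinned (`NA`) — conservative bins in
#' place of downstream manual curation.  Contigs excluded from fragmentation
#' (shorter than the minimum) are unbinned by construction.
#'
#' @param labels named integer vector from [cluster_fragments()].
#' @param fragments fragment table from [fragment_contigs()].
#' @return data.frame `contig_id`, `bin` (integer or `NA` for unbinned).
#' @export
assemble_bins <- function(labels, fragments) {
  unknown <- setdiff(names(labels), fragments$fragment_id)
  if (length(unknown) > 0L)
    stop("labels for unknown fragments: ", paste(head(unknown, 5L), collapse = ", "))
  if (!all(fragments$fragment_id %in% names(labels)))
    stop("labels must cover every fragment")
  lab <- labels[fragments$fragment_id]
  contigs <- unique(fragments$contig_id)
  bin <- rep(NA_integer_, length(contigs))
  for (i in seq_along(contigs)) {
    sel <- fragments$contig_id == contigs[i] & lab != 0L
    if (!any(sel)) next
    votes <- tapply(fragments$length[sel], lab[sel], sum)
    top <- votes == max(votes)
    if (sum(top) == 1L) bin[i] <- as.integer(names(votes)[top])
  }
  data.frame(contig_id = contigs, bin = bin, stringsAsFactors = FALSE)
}

#' Score a binning against known truth
#'
#' Base-pair-weighted scores: a bin's *precision* is the fraction of its
#' base pairs that come from its majority source genome; a genome's *recall*
#' is the fraction of its (binnable, i.e. retained-contig) base pairs
#' recovered in its best bin, and F1 combines the two.  The adjusted Rand
#' index is computed over binned contigs, weighting each contig by its
#' length; unbinned contigs are excluded from the ARI, mirroring standard
#' binning benchmarks.
#'
#' @param bins data.frame from [assemble_bins()].
#' @param truth data.frame with `contig_id`, `genome` (from
#'   [simulate_community()]).
#' @param contig_len named lengths of the contigs (bp).
#' @return list with `per_bin` (bin, size_bp, majority_genome, precision),
#'   `per_genome` (genome, recall, precision of its best bin, f1),
#'   `ari`, `unbinned_bp`.
#' @export
score_binning <- function(bins, truth, contig_len) {
  if (!all(bins$contig_id %in% truth$contig_id))
    stop("truth does not cover all binned contigs")
  genome <- setNames(truth$genome, truth$contig_id)[bins$contig_id]
  len <- as.numeric(contig_len[bins$contig_id])
  if (any(is.na(len))) stop("contig lengths missing for some contigs")
  keep <- !is.na(bins$bin)
  if (!any(keep)) {
    genomes <- sort(unique(genome))
    return(list(per_bin = data.frame(),
                per_genome = data.frame(genome = genomes, best_bin = NA_integer_,
                                        recall = 0, precision = NA_real_, f1 = 0,
                                        stringsAsFactors = FALSE),
                ari = NA_real_, unbinned_bp = sum(len)))
  }
  tab <- tapply(len[keep], list(bin = bins$bin[keep], genome = genome[keep]), sum)
  tab[is.na(tab)] <- 0
  per_bin <- data.frame(
    bin = as.integer(rownames(tab)),
    size_bp = rowSums(tab),
    majority_genome = colnames(tab)[max.col(tab, ties.method = "first")],
    precision = apply(tab, 1L, max) / rowSums(tab),
    stringsAsFactors = FALSE)
  genomes <- sort(unique(genome))
  total_bp <- tapply(len, genome, sum)[genomes]
  per_genome <- do.call(rbind, lapply(genomes, function(g) {
    col <- if (g %in% colnames(tab)) tab[, g] else numeric(0)
    if (length(col) == 0L || max(col) == 0)
      return(data.frame(genome = g, best_bin = NA_integer_, recall = 0,
                        precision = NA_real_, f1 = 0, stringsAsFactors = FALSE))
    b <- which.max(col)
    rec <- col[b] / total_bp[[g]]
    prec <- per_bin$precision[b]
    data.frame(genome = g, best_bin = per_bin$bin[b], recall = rec,
               precision = prec, f1 = 2 * prec * rec / (prec + rec),
               stringsAsFactors = FALSE)
  }))
  list(per_bin = per_bin, per_genome = per_genome,
       ari = weighted_ari(bins$bin[keep], genome[keep], len[keep]),
       unbinned_bp = sum(len[!keep]))
}

# pair-counting adjusted Rand index from a weighted contingency table
weighted_ari <- function(a, b, w) {
  tab <- tapply(w, list(a, b), sum)
  tab[is.na(tab)] <- 0
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
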