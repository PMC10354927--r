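#' Configuration for the binning pipeline
#'
#' Collects every stage parameter with the workflow's defaults: 10 kb
#' fragments, 1 kb minimum contig, 257-dimensional features with
#' log10(1+x)/z-score scaling, t-SNE perplexity 30 at seed 42, HDBSCAN
#' minimum cluster size `max(15, 0.5%)` of fragments.  Fully serialisable
#' into the run manifest.
#'
#' @param fragment_len,min_contig fragmentation parameters (bp).
#' @param scaling feature scaling, see [build_feature_matrix()].
#' @param perplexity,seed,max_iter t-SNE settings.
#' @param min_cluster_size HDBSCAN minimum cluster size; `NULL` means
#'   `max(15, ceiling(0.005 * n_fragments))`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(fragment_len = 10000L, min_contig = 1000L,
                            scaling = "log10_zscore", perplexity = 30,
                            seed = 42L, max_iter = 1000L,
                            min_cluster_size = NULL) {
  if (!(fragment_len > min_contig))
    stop("invalid config: fragment_len must exceed min_contig")
  structure(list(fragment_len = as.integer(fragment_len),
                 min_contig = as.integer(min_contig), scaling = scaling,
                 perplexity = perplexity, seed = as.integer(seed),
                 max_iter = as.integer(max_iter),
                 min_cluster_size = min_cluster_size),
            class = "pipeline_config")
}

#' Run the binning workflow end to end
#'
#' Fragment -> tetramer+coverage features -> t-SNE -> HDBSCAN -> bins, with
#' optional scoring against truth.  When `out_dir` is given, writes per-bin
#' FASTA files, `fragments.tsv` (fragment table with labels and embedding
#' coordinates), `bins.tsv`, `metrics.json` (when truth is supplied) and a
#' `run.json` manifest carrying all parameters and seeds.  Inputs are never
#' mutated; rerunning with the same config and inputs reproduces identical
#' outputs.
#'
#' @param contigs named character vector / `DNAStringSet`, or a FASTA path.
#' @param depth depth table (either dialect, see [fragment_coverage()]) or a
#'   TSV path.
#' @param config a [pipeline_config()].
#' @param truth optional truth data.frame (`contig_id`, `genome`) or TSV path.
#' @param out_dir optional output directory.
#' @return list with `fragments`, `features`, `embedding`, `labels`, `bins`,
#'   `stats` (per-bin assembly statistics), `metrics` (when truth given) and
#'   `manifest`.
#' @export
run_pipeline <- function(contigs, depth, config = pipeline_config(),
                         truth = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(contigs) && length(contigs) == 1L) contigs <- read_contigs(contigs)
  if (is.character(depth) && length(depth) == 1L) depth <- read_depth(depth)
  if (is.character(truth) && length(truth) == 1L)
    truth <- read.table(truth, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  contigs <- as_dna_stringset(contigs)
  fragments <- fragment_contigs(contigs, config$fragment_len, config$min_contig)
  if (nrow(fragments) == 0L) stop("no fragments: all contigs below min_contig?")
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(fragments)), function(i)
    Biostrings::subseq(contigs[[fragments$contig_id[i]]],
                       fragments$start[i] + 1L, fragments$end[i])))
  tet <- t(vapply(seq_along(seqs), function(i) tetramer_frequencies(seqs[[i]]),
                  numeric(256L)))
  rownames(tet) <- fragments$fragment_id
  cov <- fragment_coverage(depth, fragments)
  features <- build_feature_matrix(tet, cov, config$scaling)
  embedding <- embed_fragments(features, config$perplexity, config$seed,
                               config$max_iter)
  mcs <- if (is.null(config$min_cluster_size))
    max(15L, ceiling(0.005 * nrow(fragments))) else config$min_cluster_size
  labels <- cluster_fragments(embedding, mcs)
  bins <- assemble_bins(labels, fragments)
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  stats <- lapply(split(bins$contig_id[!is.na(bins$bin)], bins$bin[!is.na(bins$bin)]),
                  function(ids) assembly_stats(contigs[ids]))
  metrics <- if (!is.null(truth)) score_binning(bins, truth, lens) else NULL
  manifest <- list(
    tool = "magbdi", version = as.character(utils::packageVersion("magbdi")),
    parameters = unclass(config), min_cluster_size_used = mcs,
    n_contigs = length(contigs), n_fragments = nrow(fragments),
    input_checksum = contig_checksum(contigs))
  res <- list(fragments = fragments, features = features, embedding = embedding,
              labels = labels, bins = bins, stats = stats, metrics = metrics,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, contigs, out_dir)
  res
}

contig_checksum <- function(contigs) {
  # order-invariant content digest without extra dependencies
  sums <- vapply(seq_along(contigs), function(i)
    sum(as.integer(charToRaw(as.character(contigs[[i]])))), numeric(1))
  sprintf("%.0f", sum(sums * Biostrings::width(contigs)))
}

write_pipeline_outputs <- function(res, contigs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fr <- res$fragments
  fr$label <- res$labels[fr$fragment_id]
  fr$x <- res$embedding[fr$fragment_id, 1L]
  fr$y <- res$embedding[fr$fragment_id, 2L]
  write.table(fr, file.path(out_dir, "fragments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$bins, file.path(out_dir, "bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (b in names(res$stats)) {
    ids <- res$bins$contig_id[!is.na(res$bins$bin) & res$bins$bin == as.integer(b)]
    write_contigs(contigs[ids], file.path(out_dir, sprintf("bin%s.fasta", b)))
  }
  if (!is.null(res$metrics))
    jsonlite::write_json(res$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write an ancestral reconstruction to TSV/JSON files
#'
#' Emits `ancestral_posteriors.tsv` (node x family x state probabilities,
#' long format), `branch_events.tsv`, `node_totals.tsv` and `model.json`.
#'
#' @param recon an [node_posteriors()] reconstruction.
#' @param events result of [call_branch_events()].
#' @param out_dir output directory.
#' @export
write_reconstruction <- function(recon, events, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recon$posteriors), function(v) {
    pm <- recon$posteriors[[v]]
    data.frame(node = recon$node_names[v],
               family = rep(rownames(pm), ncol(pm)),
               state = rep(colnames(pm), each = nrow(pm)),
               probability = as.numeric(pm), stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows),
              file.path(out_dir, "ancestral_posteriors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(events$events, file.path(out_dir, "branch_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(events$node_totals, file.path(out_dir, "node_totals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  m <- recon$model
  jsonlite::write_json(
    list(kappa = m$kappa, lambda = m$lambda, mu = m$mu, C = m$C,
         root_prior = if (is.numeric(m$root_prior)) m$root_prior else m$root_prior,
         loglik = recon$loglik, threshold = events$threshold),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
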