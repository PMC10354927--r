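#' Specification of a mock metagenomic community
#'
#' Each source genome gets its own order-`markov_order` Markov transition
#' table, built as a convex mixture of one shared base table and a
#' genome-specific random table with weight `signature_divergence` — a single
#' knob for how compositionally separable the community is.  Contigs are
#' drawn directly from the genome's chain with log-uniform lengths; each
#' contig's mean depth is the genome's mean coverage times a multiplicative
#' Gamma noise with coefficient of variation `coverage_noise_cv` (one draw
#' per contig, matching how mean contig coverage is estimated downstream).
#'
#' @param n_genomes number of source genomes (>= 2).
#' @param genome_length bp of contig sequence per genome.
#' @param markov_order order of the generating Markov chain (default 3).
#' @param signature_divergence mixture weight in (0, 1] of the
#'   genome-specific table.
#' @param mean_coverages positive mean depth per genome (recycled if scalar).
#' @param coverage_noise_cv coefficient of variation of per-contig depth
#'   noise (0 = noiseless).
#' @param contig_length_range c(min, max) bp; lengths are log-uniform.
#' @param seed integer seed; the simulation is deterministic given the spec.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 5L,
                           genome_length = 750000L,
                           markov_order = 3L,
                           signature_divergence = 0.3,
                           mean_coverages = c(12, 30, 75, 150, 250),
                           coverage_noise_cv = 0.2,
                           contig_length_range = c(1500L, 40000L),
                           seed = 1L) {
  mean_coverages <- rep_len(as.numeric(mean_coverages), n_genomes)
  spec <- list(n_genomes = as.integer(n_genomes),
               genome_length = as.integer(genome_length),
               markov_order = as.integer(markov_order),
               signature_divergence = signature_divergence,
               mean_coverages = mean_coverages,
               coverage_noise_cv = coverage_noise_cv,
               contig_length_range = as.integer(contig_length_range),
               seed = as.integer(seed))
  if (spec$n_genomes < 2L) stop("need at least 2 genomes")
  if (any(mean_coverages <= 0)) stop("coverages must be positive")
  if (spec$markov_order < 1L) stop("markov_order must be >= 1")
  if (!(signature_divergence > 0 && signature_divergence <= 1))
    stop("signature_divergence must be in (0, 1]")
  if (coverage_noise_cv < 0) stop("coverage_noise_cv must be >= 0")
  if (length(spec$contig_length_range) != 2L ||
      spec$contig_length_range[1L] < 1L ||
      spec$contig_length_range[2L] < spec$contig_length_range[1L])
    stop("contig_length_range must be c(min, max) with 1 <= min <= max")
  if (spec$genome_length < spec$contig_length_range[1L])
    stop("genome_length smaller than the minimum contig length")
  structure(spec, class = "community_spec")
}

#' Simulate a mock community with known truth
#'
#' @param spec a [community_spec()].
#' @return a list with elements
#'   `contigs` (a `DNAStringSet`), `depth` (data.frame `contig_id`,
#'   `mean_depth`) and `truth` (data.frame `contig_id`, `genome`,
#'   `true_depth`); every contig carries exactly one truth label.
#' @examples
#' com <- simulate_community(community_spec(n_genomes = 2,
#'   genome_length = 30000, mean_coverages = c(10, 100), seed = 7))
#' head(com$truth)
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  k <- spec$markov_order
  ncontext <- 4L^k
  # shared base table: moderately even Dirichlet rows; genome tables mix in
  # a genome-specific random table with weight = signature_divergence
  base <- rdirichlet_rows(ncontext, alpha = 5)
  d <- spec$signature_divergence
  bases <- c("A", "C", "G", "T")
  contigs <- character(0); contig_ids <- character(0)
  genome_of <- character(0); true_depth <- numeric(0)
  for (g in seq_len(spec$n_genomes)) {
    own <- rdirichlet_rows(ncontext, alpha = 1)
    trans <- (1 - d) * base + d * own
    cum <- t(apply(trans, 1L, cumsum))
    lens <- draw_contig_lengths(spec$genome_length, spec$contig_length_range)
    noise <- if (spec$coverage_noise_cv > 0) {
      shape <- 1 / spec$coverage_noise_cv^2
      rgamma(length(lens), shape = shape, rate = shape)
    } else rep(1, length(lens))
    for (j in seq_along(lens)) {
      codes <- .markov_sequence(lens[j], cum, k)
      contigs <- c(contigs, paste(bases[codes + 1L], collapse = ""))
    }
    ids <- sprintf("g%d_c%d", g, seq_along(lens))
    contig_ids <- c(contig_ids, ids)
    genome_of <- c(genome_of, rep(sprintf("genome%d", g), length(lens)))
    true_depth <- c(true_depth, spec$mean_coverages[g] * noise)
  }
  names(contigs) <- contig_ids
  list(contigs = Biostrings::DNAStringSet(contigs),
       depth = data.frame(contig_id = contig_ids, mean_depth = true_depth,
                          stringsAsFactors = FALSE),
       truth = data.frame(contig_id = contig_ids, genome = genome_of,
                          true_depth = true_depth, stringsAsFactors = FALSE))
}

# log-uniform contig lengths until the genome budget is spent; the final
# contig is truncated to the remainder and dropped if below the minimum
draw_contig_lengths <- function(total, range) {
  lo <- range[1L]; hi <- range[2L]
  lens <- integer(0); used <- 0L
  while (used < total) {
    L <- as.integer(round(exp(runif(1L, log(lo), log(hi)))))
    L <- min(L, total - used)
    if (L >= lo) lens <- c(lens, L)
    used <- used + L
    if (L < lo) break  # remainder too short to keep
  }
  lens
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(rgamma(n * 4L, shape = alpha), nrow = n)
  g / rowSums(g)
}
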