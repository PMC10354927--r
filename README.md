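# magbdi

Composition-and-coverage metagenomic binning, and birth-death-innovation
models of gene-family evolution, in one R package.

## What problem this solves, and for whom

Microbiologists working on environmental communities face two recurring
computational tasks once an assembly and a set of genomes are in hand:

1. **MAG recovery.** Assemblies of low-diversity communities (acid-mine
   drainage streams, bioreactors, enrichment cultures) can be separated
   into genome bins using only two intrinsic signals: each genome's
   tetranucleotide composition and its read coverage. `magbdi` implements
   the fragment-based workflow: contigs are tiled into 10 kb fragments
   (contigs < 1 kb dropped), each fragment becomes a 257-dimensional vector
   (256 tetramer frequencies + mean depth), the matrix is embedded in 2-D
   with t-SNE and density-clustered with HDBSCAN, and fragment clusters are
   merged back into contig bins. Assembly statistics (size, G+C, contig
   count, N50) summarise each bin.

2. **Gene-content history.** Given gene-family copy counts across the
   genomes of a clade and a rooted phylogeny, the package models family
   size as a capped birth-death-innovation (BDI) continuous-time Markov
   chain — upward rate `i·λ + κ` (per-copy duplication λ plus innovation
   κ), downward rate `i·μ` (per-copy loss) on states `{0, …, C}` — fits
   (κ, λ, μ) by maximum likelihood (Felsenstein pruning, conditioned on
   family observability), decodes marginal ancestral copy-number posteriors
   at every node (up-down recursion), and calls per-branch **gains**,
   **losses**, **expansions** and **reductions** from the posteriors.
   Wagner parsimony (Sankoff DP) is included as a model-free baseline.

Seeded simulators for mock communities (order-3 Markov-chain genomes with
tunable signature divergence and coverage structure) and for gene-family
profiles (exact Gillespie simulation with recorded per-node and per-branch
truth) make every stage testable without any external data.

## Worked example: recover genomes from a mock community

```r
library(magbdi)

com <- simulate_community(community_spec(seed = 1))   # 5 genomes, ~3.75 Mb
length(com$contigs)
#> [1] 325

res <- run_pipeline(com$contigs, com$depth, pipeline_config(),
                    truth = com$truth)
res$metrics$per_bin
#>   bin size_bp majority_genome precision
#> 1   1  750000         genome1         1
#> 2   2  750000         genome5         1
#> 3   3  750000         genome3         1
#> 4   4  750000         genome4         1
#> 5   5  750000         genome2         1
res$metrics$ari
#> [1] 1
```

Every bin contains exactly the 750 kb of one source genome (precision 1),
and the length-weighted adjusted Rand index over contigs is 1: the five
genomes, whose compositional signatures differ by a mixture weight of 0.3
and whose coverages span 12–250×, are fully separated. Per-bin assembly
statistics come from `assembly_stats()`:

```r
str(res$stats[["1"]])
#> List of 5
#>  $ total_size: num 750000
#>  $ gc_percent: num 50.2
#>  $ n_contigs : int 61
#>  $ n50       : num 23670
#>  $ largest   : num 37994
```

## Worked example: ancestral gene content

```r
set.seed(1)
tree <- ape::rtree(8)
sim <- simulate_profiles(profile_sim_spec(tree, kappa = 0.3, lambda = 0.1,
                                          mu = 0.6, C = 5,
                                          n_families = 400, seed = 2))
fit <- fit_model(sim$profile, tree, C = 5, seed = 3)
sprintf("kappa = %.3f  lambda = %.3f  mu = %.3f", fit$kappa, fit$lambda, fit$mu)
#> [1] "kappa = 0.325  lambda = 0.113  mu = 0.619"

rec <- node_posteriors(sim$profile, tree, fit)
ev  <- call_branch_events(rec)          # threshold 0.5 on P(present)
head(ev$node_totals)
#>    node families_present gains losses expansions reductions
#> t5   t5              186    39     28         37          7
#> t7   t7              189    11      7         20          3
#> t3   t3              188    52     71         32         34
#> t2   t2              204     0      3          6          0
#> t6   t6              187    32     23         24          5
#> t4   t4              208    34     24         21         23
```

The fitted rates sit close to the generating values (0.3, 0.1, 0.6); each
row of `node_totals` gives the number of families inferred present at that
node and the event counts on the branch leading to it — the data layer
behind gain/loss maps drawn on a phylogeny.

A command-line wrapper with subcommands (`simulate-community`, `bin-run`,
`bin-stats`, `profile-build`, `profile-core`, `evolve-fit`,
`evolve-ancestral`, `evolve-parsimony`) is installed at
`system.file("scripts", "magbdi", package = "magbdi")`.

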