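---
title: "Composition/coverage binning and birth-death-innovation gene-content evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition/coverage binning and birth-death-innovation gene-content evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`magbdi` implements two analysis tracks that are routinely chained in
environmental microbiology: recovering metagenome-assembled genomes (MAGs)
from an assembly by composition-and-coverage clustering, and reconstructing
the history of gene-family gains, losses, expansions and reductions on a
phylogeny of the recovered genomes. This vignette explains the models, the
parameters that matter, the simulators used to validate everything, and the
numerical choices — in enough detail that a user can judge what the passing
test suite does and does not demonstrate.

## 1. The binning workflow

### Model

Genomes leave two signals in their contigs: a compositional signature (the
distribution of short oligonucleotides is genome-specific and roughly
homogeneous along a chromosome) and a coverage signal (all contigs of one
organism are sequenced to a similar depth, proportional to its abundance).
The workflow turns both into a clustering problem:

1. **Fragmentation.** Contigs are cut left-to-right into 10,000 bp
   fragments; contigs shorter than 1,000 bp are excluded. Cutting long
   contigs ensures each point in the feature space represents a comparable
   amount of sequence, so dense clusters correspond to genomes rather than
   to contig-length artefacts. A trailing remainder shorter than 1,000 bp is
   merged into the preceding fragment; a longer remainder stands alone. The
   merge direction is our choice: it guarantees that no fragment used for
   composition estimation falls below the same 1,000 bp floor that motivates
   excluding short contigs in the first place.
2. **Features.** Each fragment is described by its 256 tetranucleotide
   frequencies plus its mean read depth — a 257-dimensional vector. Tetramers
   are counted on the given strand only (256 columns, which is what the
   257-dimensional total forces; reverse-complement-collapsed counting would
   give 136). Windows containing any non-ACGT code are skipped and the
   denominator shrinks accordingly, so N-rich fragments are not biased
   toward zero frequencies.
3. **Scaling.** Raw depth is unbounded while frequencies are at most 1; in
   any distance-based embedding the coverage column would otherwise dominate
   or vanish depending on sequencing depth. Default scaling is
   `log10(1 + depth)` followed by z-scoring of all 257 columns
   (zero-variance columns are left at 0). The scaling is recorded in the
   feature-matrix metadata.
4. **Embedding and clustering.** The matrix is embedded in 2-D with
   Barnes-Hut t-SNE (perplexity 30, PCA initialisation, fixed seed 42 by
   default — reproducibility is prioritised; all settings are recorded) and
   clustered with HDBSCAN, minimum cluster size `max(15, 0.5 %)` of the
   fragments. HDBSCAN labels low-density fragments as noise instead of
   forcing them into a bin.
5. **Re-merging.** Fragments vote for their contig: length-weighted majority
   over non-noise labels; all-noise contigs and exact ties stay unbinned.
   The conservative tie policy substitutes for the manual curation step a
   human would otherwise perform on marginal contigs.

No installed R package provides HDBSCAN, so the package carries a complete
implementation (core distances, mutual reachability, minimum spanning tree,
condensed tree, excess-of-mass selection). It is validated against blob
fixtures with known structure and cross-checked against the scikit-learn
implementation in the test suite.

### Scoring

With known truth (simulations), `score_binning()` reports base-pair-weighted
per-bin precision, per-genome recall/F1, and a length-weighted adjusted Rand
index over the binned contigs. Unbinned contigs are excluded from the ARI
(standard in binning benchmarks) but show up as lost recall and in
`unbinned_bp`. A genome counts as "recovered at high precision" when its
best bin has precision at or above 0.95 and captures at least half of the
genome's binnable base pairs.

## 2. The community simulator

`simulate_community()` generates the ground-truth communities used to
validate the workflow end to end:

* **Composition.** Each genome's sequence is an order-3 Markov chain. The
  per-genome transition table is a convex mixture
  `(1 - d) * shared + d * genome-specific` with `d = signature_divergence`
  — a single knob for how compositionally separable the community is. The
  default `d = 0.3` produces clearly distinct but not caricatured
  signatures.
* **Coverage.** Each contig's mean depth is the genome's mean coverage times
  one multiplicative Gamma draw with coefficient of variation
  `coverage_noise_cv` (default 0.2, a typical between-contig spread for an
  isolate-dominated metagenome; real dispersion varies and the default is a
  modelling choice, not a measured value). One draw per contig matches how
  mean contig coverage is estimated downstream.
* **Scale.** Defaults: 5 genomes, 750 kb of contig sequence each, contig
  lengths log-uniform on 1.5–40 kb (about 300–360 contigs and 3.75 Mb in
  total), mean coverages 12–250× (a > 10× span). This desk-scale community
  runs through the whole pipeline in seconds while leaving each genome
  ~60–70 contigs, enough for per-genome recall to be meaningful.

What the simulator does **not** emulate: sequencing errors, strain-level
heterogeneity, repeats or sequence shared between genomes, chimeric contigs,
GC-dependent coverage bias, and within-genome compositional heterogeneity
(e.g. recently transferred islands). Passing the recovery test therefore
shows that the implementation is correct and that the workflow separates
genomes whose signatures and abundances differ as specified — it does not
certify performance on any real community, where curation against reference
genomes remains necessary.

## 3. Assembly statistics

`assembly_stats()` reports total size, G+C, contig count, N50 and largest
contig. G+C excludes ambiguity codes from numerator and denominator, so N
runs do not deflate the estimate. N50 is the largest `L` such that contigs
of length ≥ `L` sum to at least half the assembly; a property test checks
this against the brute-force definition on random length multisets.

## 4. Phyletic profiles and the core genome

`build_profile()` digests external ortholog-clustering output into a dense
family × genome count matrix; `core_families()` applies the strict rule that
a core family is present (count ≥ 1) in **every** genome — no soft-core
threshold. Copy counts (not just presence) are retained because the
evolutionary analysis distinguishes expansions and reductions. Note that any
published core-genome census depends on the upstream clustering tool and its
settings; this package reproduces the rule, not any particular number.

## 5. The birth-death-innovation model

### Chain

Family copy number evolves on `{0, ..., C}` as a continuous-time Markov
chain with

* upward rate `i λ + κ` (per-copy duplication plus innovation, `i < C`),
* downward rate `i μ` (per-copy loss, `i > 0`).

`κ` (innovation) lets absent families appear (0 → 1, e.g. by transfer or
origination); `λ` and `μ` act per copy. The cap `C` (default 10) truncates
the state space; observed counts above `C` are truncated with a warning.
Ten copies is beyond the realistic range for almost all families in compact
archaeal genomes, so the truncation is inert in practice while keeping every
matrix 11 × 11.

### Likelihood and fitting

Branch transition matrices are `expm(Q t)`. For fitting, one spectral
decomposition per likelihood evaluation serves all branches: the chain is
reversible, so `D^{1/2} Q D^{-1/2}` (with `D = diag(π)`) is symmetric and
its eigendecomposition gives `expm(Q t)` for every `t` at once; the code
falls back to the matrix exponential when the similarity transform is
ill-conditioned. Per-family likelihoods use Felsenstein pruning, vectorised
across families, with per-node rescaling to avoid underflow.

The root prior defaults to the chain's stationary distribution (solved from
the generator's null space), keeping simulation and inference
self-consistent; uniform and user-supplied priors are available. Because a
real profile can never contain a family absent from every genome, the
likelihood is conditioned on observability by default:
`log L − log(1 − P(all leaves 0))`. This conditioning rescales every family
by a constant and therefore does not change the node posteriors.

`fit_model()` maximises the summed conditioned log-likelihood over
`(κ, λ, μ)` in log space with BFGS from five seeded starts (relative
tolerance 1e-10, identical profile rows collapsed with weights). Only
global, tree-wide rates are fitted: with ~20 genomes there is too little
information to identify per-branch rates, and the rate-time product is the
only identifiable quantity anyway (doubling branch lengths while halving
rates leaves the likelihood unchanged — a property the tests assert).

### Posteriors and event calls

`node_posteriors()` runs the up-down (inside-outside) recursion, yielding
the exact marginal posterior over copy numbers at every node for every
family; leaf posteriors are degenerate at the observations. Event calls
discretise these posteriors with threshold 0.5 on the presence probability
`P(count ≥ 1)`: a branch gets a *gain* when the family crosses from absent
(parent) to present (child), a *loss* for the reverse, and when present at
both ends an *expansion*/*reduction* if the posterior-mode copy number
strictly increases/decreases (mode ties resolve toward fewer copies).
Per-node totals are sums of the per-family calls, and the tests assert that
identity. The 0.5/mode rule is a deliberate, simple discretisation; the
recorded posteriors allow any stricter rule downstream.

The reconstruction requires a rooted tree; an unrooted input is an error,
and `read_phylogeny()` offers outgroup and midpoint rooting as explicit
choices. We deliberately refuse to guess a rooting: ancestral content at
the root depends on it strongly.

`wagner_parsimony()` (Sankoff dynamic programming on presence/absence with
asymmetric gain/loss penalties, ties resolved toward absence) is included as
an independent, model-free baseline and as the oracle for cross-checks.

### Profile simulator and validation scale

`simulate_profiles()` runs exact Gillespie simulation of the same chain
along every branch, records the true state at every node and the true event
on every branch, and (by default) rejects families absent from all leaves
(capped at 10,000 redraws; exceeding the cap signals a pathological
specification rather than looping forever).

Validation problem sizes, chosen to mirror a typical order-level analysis
while keeping the whole suite fast: rate recovery uses 5,000 families on a
22-leaf tree with rates (κ, λ, μ) = (0.5, 0.2, 1.0) — recovered within a
few percent, asserted within ±20 % — and event decoding is checked in the
low-rate regime (< 0.3 events per family per tree), where posterior calls
recover over 95 % of true events with a few percent false calls. Decoding
accuracy necessarily degrades at high rates, where multiple events per
branch make the endpoint-based truth itself ambiguous.

## 6. Numerical choices and degenerate inputs

* Matrix exponentials clip tiny negative entries and renormalise rows.
* Pruning rescales partial likelihoods by row sums; scales are accumulated
  in log space (stable down to profiles on deep trees).
* `stationary_distribution()` solves the null space with a sum-to-one
  constraint; an all-zero generator returns a point mass at state 0.
* HDBSCAN: coincident points (zero mutual-reachability spread) collapse to
  a single cluster with a warning; `1/0` density levels from duplicate
  points are capped.
* Bin votes: exact ties → unbinned; posterior mode ties → fewer copies;
  parsimony ties → absence. All tie-breaks are deterministic and documented.
* Both simulators and the embedding are deterministic given their seeds;
  manifests (`run.json`) record every parameter and seed.

## 7. Known limitations

* The binning score is computed against simulated truth; no marker-gene
  completeness/contamination estimate is provided (use CheckM-class tools
  on real bins).
* The BDI model assumes independent families, global rates and a single
  tree; lateral transfer between lineages is folded into `κ`.
* t-SNE is used for faithfulness to the established workflow; its local
  structure is trusted only through the downstream density clustering, and
  hyperparameters are recorded rather than tuned per dataset.
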