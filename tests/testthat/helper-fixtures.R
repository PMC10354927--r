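# Shared fixture builders; everything is generated in code under fixed seeds.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force N50: try every length as the cut point
brute_n50 <- function(lens) {
  total <- sum(lens)
  max(Filter(function(L) sum(lens[lens >= L]) >= total / 2, sort(unique(lens))))
}

# enumeration likelihood of one profile row: sum over all internal-state
# assignments of prior x branch transition products
brute_loglik <- function(row, tree, model) {
  C <- model$C
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(model, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(0:C), length(internal))))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[internal] <- grid[r, ]
    st[seq_len(n_tip)] <- row[tree$tip.label]
    p <- model$prior[st[n_tip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Ps[[e]][st[tree$edge[e, 1L]] + 1L, st[tree$edge[e, 2L]] + 1L]
    tot <- tot + p
  }
  log(tot)
}

# enumeration posteriors: Bayes over all internal assignments
brute_posteriors <- function(row, tree, model) {
  C <- model$C
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(model, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(0:C), length(internal))))
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[internal] <- grid[r, ]
    st[seq_len(n_tip)] <- row[tree$tip.label]
    p <- model$prior[st[n_tip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Ps[[e]][st[tree$edge[e, 1L]] + 1L, st[tree$edge[e, 2L]] + 1L]
    w[r] <- p
  }
  w <- w / sum(w)
  post <- matrix(0, length(internal), C + 1L,
                 dimnames = list(internal, 0:C))
  for (j in seq_along(internal))
    for (s in 0:C) post[j, s + 1L] <- sum(w[grid[, j] == s])
  post
}

# exhaustive Wagner parsimony over all 2^(n internal) labelings
brute_parsimony <- function(states, tree, gain_penalty, loss_penalty) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  s_leaf <- as.integer(states[tree$tip.label] > 0)
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[internal] <- grid[r, ]
    st[seq_len(n_tip)] <- s_leaf
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[e, 1L]]; b <- st[tree$edge[e, 2L]]
      cost <- cost + if (a == 0 && b == 1) gain_penalty
                     else if (a == 1 && b == 0) loss_penalty else 0
    }
    best <- min(best, cost)
  }
  best
}

# a small community spec used across binning tests (fast, still separable)
small_community_spec <- function(seed = 21) {
  community_spec(n_genomes = 3L, genome_length = 150000L,
                 signature_divergence = 0.4,
                 mean_coverages = c(10, 60, 300),
                 contig_length_range = c(1500L, 20000L), seed = seed)
}
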