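#' Marginal ancestral posteriors for every node and family
#'
#' Posterior decoding by the up-down (inside-outside) recursion: the upward
#' pass is Felsenstein pruning; the downward pass propagates the information
#' outside each subtree, so that at every node the two combine into the exact
#' marginal posterior over copy-number states given all leaf counts.  Leaf
#' posteriors are degenerate at the observed (cap-truncated) counts.
#' Conditioning the likelihood on observability rescales every family by the
#' same constant and therefore leaves these posteriors unchanged.
#'
#' @param profile integer matrix families x genomes (or one named row).
#' @param tree rooted `phylo` whose tips match the profile columns.
#' @param model a fitted or hand-specified [gain_loss_model()].
#' @return an object of class `ancestral_reconstruction`: a list with
#'   `posteriors` (list over nodes of families x states matrices),
#'   `presence` (families x nodes matrix of `P(count >= 1)`),
#'   `expected_count` and `mode_count` (families x nodes), `node_names`,
#'   `tree`, `model`, `loglik`.
#' @export
node_posteriors <- function(profile, tree, model) {
  check_tree(tree)
  m <- align_profile(profile, tree, model$C)
  C <- model$C
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_fam <- nrow(m)
  up <- prune_inside(m, tree, model)
  Ps <- up$Ps
  inside <- up$inside
  S <- vector("list", nrow(tree$edge))  # per-edge upward message at parent
  for (e in seq_len(nrow(tree$edge)))
    S[[e]] <- inside[[tree$edge[e, 2L]]] %*% t(Ps[[e]])
  outside <- vector("list", n_node)
  outside[[up$root]] <- matrix(model$prior, n_fam, C + 1L, byrow = TRUE)
  edges_by_parent <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  for (e in rev(ape::postorder(tree))) {  # parents before children
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    acc <- outside[[p]]
    for (sib in edges_by_parent[[as.character(p)]])
      if (sib != e) acc <- acc * S[[sib]]
    o <- acc %*% Ps[[e]]
    s <- pmax(rowSums(o), .Machine$double.xmin)
    outside[[ch]] <- o / s
  }
  posts <- vector("list", n_node)
  presence <- expected <- mode <- matrix(NA_real_, n_fam, n_node,
                                         dimnames = list(rownames(m), node_names(tree)))
  states <- 0:C
  for (v in seq_len(n_node)) {
    pm <- inside[[v]] * outside[[v]]
    pm <- pm / rowSums(pm)
    dimnames(pm) <- list(rownames(m), states)
    posts[[v]] <- pm
    presence[, v] <- 1 - pm[, 1L]
    expected[, v] <- as.numeric(pm %*% states)
    mode[, v] <- states[max.col(pm, ties.method = "first")]  # ties -> fewer copies
  }
  structure(list(posteriors = posts, presence = presence,
                 expected_count = expected, mode_count = mode,
                 node_names = node_names(tree), tree = tree, model = model,
                 loglik = sum(up$loglik)),
            class = "ancestral_reconstruction")
}

#' Call per-branch gene gains, losses, expansions and reductions
#'
#' Discretises the posteriors: a family is *present* at a node when its
#' presence probability is at least `threshold`.  On a branch parent -> child
#' the call is *gain* when the family is absent at the parent and present at
#' the child, *loss* for the reverse; when present at both ends, *expansion*
#' if the posterior-mode copy number strictly increases and *reduction* if it
#' strictly decreases; otherwise *none*.  Node totals (families present,
#' gains, losses, expansions, reductions on the branch leading to the node)
#' are sums of the per-family calls.
#'
#' @param recon an [node_posteriors()] reconstruction.
#' @param threshold presence-probability cut-off (default 0.5).
#' @return a list with `events` (data.frame branch x family calls, calls
#'   other than `"none"` only) and `node_totals` (data.frame with one row
#'   per node).
#' @export
call_branch_events <- function(recon, threshold = 0.5) {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  tree <- recon$tree
  nm <- recon$node_names
  pres <- recon$presence >= threshold
  mode <- recon$mode_count
  n_node <- length(nm)
  totals <- data.frame(node = nm,
                       families_present = colSums(pres),
                       gains = 0L, losses = 0L, expansions = 0L,
                       reductions = 0L, stringsAsFactors = FALSE)
  ev <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    call <- rep("none", nrow(pres))
    call[!pres[, p] & pres[, ch]] <- "gain"
    call[pres[, p] & !pres[, ch]] <- "loss"
    both <- pres[, p] & pres[, ch]
    call[both & mode[, ch] > mode[, p]] <- "expansion"
    call[both & mode[, ch] < mode[, p]] <- "reduction"
    keep <- call != "none"
    if (any(keep))
      ev[[length(ev) + 1L]] <- data.frame(
        parent = nm[p], child = nm[ch],
        family = rownames(pres)[keep], event = call[keep],
        stringsAsFactors = FALSE)
    totals$gains[ch] <- sum(call == "gain")
    totals$losses[ch] <- sum(call == "loss")
    totals$expansions[ch] <- sum(call == "expansion")
    totals$reductions[ch] <- sum(call == "reduction")
  }
  events <- if (length(ev) > 0L) do.call(rbind, ev)
            else data.frame(parent = character(), child = character(),
                            family = character(), event = character(),
                            stringsAsFactors = FALSE)
  list(events = events, node_totals = totals, threshold = threshold)
}

#' Wagner parsimony on a presence/absence character
#'
#' Sankoff dynamic programming over states \{0, 1\} with asymmetric gain and
#' loss penalties.  Returns the minimum total penalty and one optimal
#' ancestral labelling; ties are broken deterministically in favour of
#' absence.
#'
#' @param states named 0/1 vector over the tree's leaves (copy counts are
#'   binarised as `> 0`).
#' @param tree rooted `phylo`.
#' @param gain_penalty,loss_penalty positive penalties for a 0 -> 1 and a
#'   1 -> 0 change on a branch.
#' @return list with `cost` and `labeling` (named 0/1 vector over all nodes).
#' @export
wagner_parsimony <- function(states, tree, gain_penalty = 2, loss_penalty = 1) {
  check_tree(tree)
  if (gain_penalty <= 0 || loss_penalty <= 0) stop("penalties must be > 0")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0L)
    stop("leaves missing from states: ", paste(missing, collapse = ", "))
  s <- as.integer(states[tree$tip.label] > 0)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # step cost from parent state (row) to child state (col): 0->1 is a gain
  step <- matrix(c(0, gain_penalty, loss_penalty, 0), 2L, 2L, byrow = TRUE)
  cost <- matrix(Inf, n_node, 2L)
  cost[seq_len(n_tip), ] <- cbind(ifelse(s == 0L, 0, Inf),
                                  ifelse(s == 1L, 0, Inf))
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    # min over child state of (step cost + child subtree cost), per parent state
    msg <- vapply(1:2, function(ps) min(step[ps, ] + cost[ch, ]), numeric(1))
    if (all(!is.finite(cost[p, ]))) cost[p, ] <- msg else cost[p, ] <- cost[p, ] + msg
  }
  root <- n_tip + 1L
  lab <- integer(n_node)
  lab[root] <- which(cost[root, ] == min(cost[root, ]))[1L] - 1L  # tie -> absence
  for (e in rev(po)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    opts <- step[lab[p] + 1L, ] + cost[ch, ]
    lab[ch] <- which(opts == min(opts))[1L] - 1L
  }
  list(cost = min(cost[root, ]),
       labeling = setNames(lab, node_names(tree)))
}
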