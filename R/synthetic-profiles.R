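#' Specification of a gene-family profile simulation
#'
#' Families evolve independently on a rooted tree under the capped
#' birth-death-innovation chain of [gain_loss_model()]: upward rate
#' `i*lambda + kappa`, downward rate `i*mu`, cap `C`.  The root state is
#' drawn from the model's root prior (stationary by default, keeping the
#' simulator self-consistent with inference).  With
#' `condition_on_observed = TRUE`, families absent from every leaf are
#' rejected and redrawn (at most 10000 redraws per family), emulating the
#' fact that unobservable families never enter a real profile.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param kappa,lambda,mu,C,root_prior as in [gain_loss_model()].
#' @param n_families number of families to simulate.
#' @param condition_on_observed reject all-absent families (default `TRUE`).
#' @param seed integer seed.
#' @return an object of class `profile_sim_spec`.
#' @export
profile_sim_spec <- function(tree, kappa = 0.5, lambda = 0.2, mu = 1.0,
                             C = 10L, n_families = 1000L,
                             condition_on_observed = TRUE,
                             root_prior = "stationary", seed = 1L) {
  check_tree(tree)
  if (n_families < 1L) stop("n_families must be >= 1")
  model <- gain_loss_model(kappa, lambda, mu, C, root_prior)
  structure(list(tree = tree, model = model,
                 n_families = as.integer(n_families),
                 condition_on_observed = isTRUE(condition_on_observed),
                 seed = as.integer(seed)),
            class = "profile_sim_spec")
}

#' Simulate gene-family profiles with recorded truth
#'
#' @param spec a [profile_sim_spec()].
#' @return a list with `profile` (families x leaves integer matrix),
#'   `node_states` (families x all-nodes true copy counts) and
#'   `branch_events` (data.frame: parent, child, family, event in
#'   gain/loss/expansion/reduction, derived from the true endpoint states of
#'   each branch).
#' @examples
#' tr <- ape::rtree(4)
#' sim <- simulate_profiles(profile_sim_spec(tr, n_families = 10, seed = 3))
#' sim$profile
#' @export
simulate_profiles <- function(spec) {
  stopifnot(inherits(spec, "profile_sim_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  model <- spec$model
  C <- model$C
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  edges_pre <- rev(ape::postorder(tree))  # parents before children
  nm <- node_names(tree)
  states <- matrix(NA_integer_, spec$n_families, n_node,
                   dimnames = list(sprintf("fam%d", seq_len(spec$n_families)), nm))
  for (f in seq_len(spec$n_families)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("condition_on_observed: family rejected 10000 times; ",
             "spec is pathological (families almost never observable)")
      st <- integer(n_node)
      st[root] <- sample.int(C + 1L, 1L, prob = model$prior) - 1L
      for (e in edges_pre) {
        st[tree$edge[e, 2L]] <- sim_bdi_branch(st[tree$edge[e, 1L]],
                                               tree$edge.length[e], model)
      }
      if (!spec$condition_on_observed || any(st[seq_len(n_tip)] > 0L)) break
    }
    states[f, ] <- st
  }
  profile <- states[, seq_len(n_tip), drop = FALSE]
  list(profile = profile, node_states = states,
       branch_events = true_branch_events(states, tree, nm))
}

# exact Gillespie simulation of the capped BDI chain along one branch
sim_bdi_branch <- function(state, t, model) {
  time <- 0
  repeat {
    up <- if (state < model$C) state * model$lambda + model$kappa else 0
    down <- state * model$mu
    total <- up + down
    if (total <= 0) return(state)
    time <- time + stats::rexp(1L, total)
    if (time > t) return(state)
    state <- if (runif(1L) < up / total) state + 1L else state - 1L
  }
}

# event labels from true endpoint states of each branch, one row per
# non-"none" (family, branch) pair
true_branch_events <- function(states, tree, nm) {
  ev <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sp <- states[, p]; sc <- states[, ch]
    call <- rep("none", nrow(states))
    call[sp == 0L & sc > 0L] <- "gain"
    call[sp > 0L & sc == 0L] <- "loss"
    call[sp > 0L & sc > sp] <- "expansion"
    call[sp > 0L & sc > 0L & sc < sp] <- "reduction"
    keep <- call != "none"
    if (any(keep))
      ev[[length(ev) + 1L]] <- data.frame(
        parent = nm[p], child = nm[ch], family = rownames(states)[keep],
        event = call[keep], stringsAsFactors = FALSE)
  }
  if (length(ev) > 0L) do.call(rbind, ev)
  else data.frame(parent = character(), child = character(),
                  family = character(), event = character(),
                  stringsAsFactors = FALSE)
}
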