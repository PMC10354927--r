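# Tree bookkeeping shared by likelihood, posteriors and simulation: postorder
# edge traversal, per-edge transition matrices (cached by unique branch
# length), and the profile aligned to leaf order.

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it first (see read_phylogeny)")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

# transition matrix per edge.  The BDI chain is reversible with respect to
# its stationary law, so D^{1/2} Q D^{-1/2} is symmetric (D = diag(pi)) and
# one eigendecomposition yields expm(Q t) for every branch at once; when the
# similarity transform is ill-conditioned (rates at the optimiser's edge)
# each branch falls back to the matrix exponential.
edge_transitions <- function(tree, model) {
  bl <- tree$edge.length
  ub <- unique(bl)
  Ps <- transition_probability_set(model, ub)
  Ps[match(bl, ub)]
}

transition_probability_set <- function(model, times) {
  Q <- build_generator(model)
  pi_ <- stationary_distribution(model)
  fallback <- function() lapply(times, function(t) transition_probabilities(model, t))
  if (any(pi_ <= 0) || any(!is.finite(pi_))) return(fallback())
  s <- sqrt(pi_)
  if (max(s) / min(s) > 1e7) return(fallback())
  Sym <- (s * Q) %*% diag(1 / s)
  Sym <- (Sym + t(Sym)) / 2
  eg <- eigen(Sym, symmetric = TRUE)
  V <- diag(1 / s) %*% eg$vectors
  W <- t(eg$vectors) %*% diag(s)
  lapply(times, function(t) {
    if (t == 0) return(diag(length(pi_)))
    P <- V %*% (exp(eg$values * t) * W)
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

align_profile <- function(profile, tree, C) {
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1L,
                                               dimnames = list("f1", names(profile)))
  missing <- setdiff(tree$tip.label, colnames(profile))
  if (length(missing) > 0L)
    stop("leaves missing from profile: ", paste(missing, collapse = ", "))
  m <- profile[, tree$tip.label, drop = FALSE]
  if (any(m > C)) {
    warning("counts above the cap C = ", C, " truncated")
    m[m > C] <- C
  }
  storage.mode(m) <- "integer"
  m
}

# Felsenstein pruning vectorised across families.  Returns, per node, the
# partial (inside) likelihood matrix (families x states) rescaled per family,
# plus the accumulated log scale per family and the per-family log-likelihood.
prune_inside <- function(profile, tree, model, Ps = NULL) {
  C <- model$C
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_fam <- nrow(profile)
  if (is.null(Ps)) Ps <- edge_transitions(tree, model)
  inside <- vector("list", n_node)
  logscale <- matrix(0, n_fam, n_node)
  for (v in seq_len(n_tip)) {
    L <- matrix(0, n_fam, C + 1L)
    L[cbind(seq_len(n_fam), profile[, v] + 1L)] <- 1
    inside[[v]] <- L
  }
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    msg <- inside[[child]] %*% t(Ps[[e]])      # families x parent-states
    if (is.null(inside[[parent]])) {
      inside[[parent]] <- msg
      logscale[, parent] <- logscale[, child]
    } else {
      inside[[parent]] <- inside[[parent]] * msg
      logscale[, parent] <- logscale[, parent] + logscale[, child]
    }
    # rescale to dodge underflow on deep trees
    s <- pmax(rowSums(inside[[parent]]), .Machine$double.xmin)
    inside[[parent]] <- inside[[parent]] / s
    logscale[, parent] <- logscale[, parent] + log(s)
  }
  root <- n_tip + 1L
  lik <- as.numeric(inside[[root]] %*% model$prior)
  list(inside = inside, logscale = logscale,
       loglik = log(lik) + logscale[, root], Ps = Ps, root = root)
}

# probability that a family is absent from every leaf (used to condition the
# likelihood on observability): the pruning likelihood of the all-zero row
prob_all_absent <- function(tree, model, Ps = NULL) {
  zero <- matrix(0L, 1L, length(tree$tip.label),
                 dimnames = list("z", tree$tip.label))
  exp(prune_inside(zero, tree, model, Ps)$loglik)
}

#' Log-likelihood of gene-family profiles under the BDI model
#'
#' Computes the Felsenstein-pruning log-likelihood of each family's copy
#' counts at the leaves, optionally conditioned on the family being
#' observable (present in at least one leaf): `log L - log(1 - P(all leaves
#' absent))`.  Counts above the cap are truncated with a warning.
#'
#' @param profile integer matrix families x genomes (or one named row).
#' @param tree rooted `phylo` whose tips match the profile columns.
#' @param model a [gain_loss_model()].
#' @param condition condition on observability (default `TRUE`).
#' @return numeric vector of per-family log-likelihoods.
#' @export
family_loglikelihood <- function(profile, tree, model, condition = TRUE) {
  check_tree(tree)
  m <- align_profile(profile, tree, model$C)
  Ps <- edge_transitions(tree, model)
  ll <- prune_inside(m, tree, model, Ps)$loglik
  if (condition) ll <- ll - log(1 - prob_all_absent(tree, model, Ps))
  setNames(ll, rownames(m))
}

#' Fit BDI rates to a phyletic profile by maximum likelihood
#'
#' Maximises the summed (optionally observability-conditioned) family
#' log-likelihood over `(kappa, lambda, mu)` in log-rate space, with
#' multiple seeded quasi-Newton starts.  Identical profile rows are collapsed
#' to unique rows with weights before optimisation.
#'
#' @param profile integer matrix families x genomes.
#' @param tree rooted `phylo`.
#' @param C copy-number cap (default 10).
#' @param condition condition on observability; `TRUE` by default because
#'   real profiles cannot contain families absent everywhere.
#' @param n_starts number of optimiser starts (>= 1; default 5).
#' @param seed seed controlling the start points.
#' @param root_prior as in [gain_loss_model()].
#' @return the fitted [gain_loss_model()] with extra fields `loglik`,
#'   `convergence` (per-start optim codes) and `n_families`.
#' @export
fit_model <- function(profile, tree, C = 10L, condition = TRUE,
                      n_starts = 5L, seed = 1L, root_prior = "stationary") {
  check_tree(tree)
  if (sum(tree$edge.length) <= 0) stop("tree has zero total branch length")
  m <- align_profile(profile, tree, C)
  if (nrow(m) < 1L) stop("need at least one family")
  key <- apply(m, 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  w <- as.numeric(table(key)[key[uniq]])
  mu_rows <- m[uniq, , drop = FALSE]

  negll <- function(logrates) {
    model <- try(gain_loss_model(exp(logrates[1L]), exp(logrates[2L]),
                                 exp(logrates[3L]), C, root_prior),
                 silent = TRUE)
    if (inherits(model, "try-error")) return(1e12)
    Ps <- edge_transitions(tree, model)
    ll <- prune_inside(mu_rows, tree, model, Ps)$loglik
    if (condition) {
      p0 <- prob_all_absent(tree, model, Ps)
      if (!is.finite(p0) || p0 >= 1) return(1e12)
      ll <- ll - log(1 - p0)
    }
    v <- -sum(w * ll)
    if (!is.finite(v)) 1e12 else v
  }

  set.seed(seed)
  starts <- matrix(runif(3L * n_starts, log(0.05), log(3)), ncol = 3L)
  starts[1L, ] <- log(c(0.5, 0.2, 1.0))  # a generic mid-range start
  best <- NULL; codes <- integer(0)
  for (s in seq_len(n_starts)) {
    fit <- try(optim(starts[s, ], negll, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimisation failed in every start")
  r <- exp(best$par)
  out <- gain_loss_model(r[1L], r[2L], r[3L], C, root_prior)
  out$loglik <- -best$value
  out$convergence <- codes
  out$n_families <- nrow(m)
  out$condition <- condition
  out
}
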