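test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(7)
  for (i in 1:25) {
    nl <- sample(3:5, 1)
    tr <- ape::rtree(nl)
    C <- sample(1:2, 1)
    m <- gain_loss_model(runif(1, 0.1, 1), runif(1, 0, 0.5),
                         runif(1, 0.2, 1.5), C)
    row <- setNames(sample(0:C, nl, replace = TRUE), tr$tip.label)
    prof <- matrix(row, 1, dimnames = list("f", names(row)))
    expect_lt(abs(family_loglikelihood(prof, tr, m, condition = FALSE) -
                    brute_loglik(row, tr, m)), 1e-8)
  }
})

test_that("conditioning subtracts the log-probability of observability", {
  tr <- ape::rtree(4)
  m <- gain_loss_model(0.4, 0.1, 0.9, 2)
  row <- setNames(c(1L, 0L, 2L, 0L), tr$tip.label)
  prof <- matrix(row, 1, dimnames = list("f", names(row)))
  zero <- matrix(setNames(rep(0L, 4), tr$tip.label), 1,
                 dimnames = list("z", tr$tip.label))
  p0 <- unname(exp(family_loglikelihood(zero, tr, m, condition = FALSE)))
  expect_equal(unname(family_loglikelihood(prof, tr, m, condition = TRUE)),
               unname(family_loglikelihood(prof, tr, m, condition = FALSE)) -
                 log(1 - p0), tolerance = 1e-12)
})

test_that("likelihood is invariant to child order and to rate-time rescaling", {
  set.seed(9)
  tr <- ape::rtree(6)
  m <- gain_loss_model(0.5, 0.2, 1.0, 3)
  prof <- matrix(sample(0:3, 6, replace = TRUE), 1,
                 dimnames = list("f", tr$tip.label))
  ll <- family_loglikelihood(prof, tr, m, condition = FALSE)
  rot <- ape::rotate(tr, node = length(tr$tip.label) + 1L)
  expect_equal(family_loglikelihood(prof, rot, m, condition = FALSE), ll)
  # doubling branch lengths while halving all rates changes nothing
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  m2 <- gain_loss_model(0.25, 0.1, 0.5, 3)
  expect_equal(family_loglikelihood(prof, tr2, m2, condition = FALSE), ll,
               tolerance = 1e-10)
})

test_that("counts above the cap are truncated with a warning", {
  tr <- ape::rtree(3)
  m <- gain_loss_model(0.3, 0.1, 0.6, 2)
  prof <- matrix(c(5L, 0L, 1L), 1, dimnames = list("f", tr$tip.label))
  expect_warning(ll <- family_loglikelihood(prof, tr, m), "truncated")
  expect_true(is.finite(ll))
  prof2 <- matrix(c(2L, 0L, 1L), 1, dimnames = list("f", tr$tip.label))
  expect_equal(suppressWarnings(family_loglikelihood(prof, tr, m)),
               family_loglikelihood(prof2, tr, m))
})

test_that("unrooted trees and missing leaves are rejected", {
  tru <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  m <- gain_loss_model(0.3, 0.1, 0.6, 2)
  prof <- matrix(c(1L, 0L, 1L, 0L), 1,
                 dimnames = list("f", c("a", "b", "c", "d")))
  expect_error(family_loglikelihood(prof, tru, m), "unrooted")
  tr <- ape::rtree(4)
  bad <- matrix(1L, 1, 3, dimnames = list("f", tr$tip.label[1:3]))
  expect_error(family_loglikelihood(bad, tr, m), "missing")
})

test_that("node posteriors are normalised, leaf-degenerate and match enumeration", {
  set.seed(31)
  for (i in 1:10) {
    nl <- sample(3:4, 1)
    tr <- ape::rtree(nl)
    C <- sample(1:2, 1)
    m <- gain_loss_model(runif(1, 0.2, 1), runif(1, 0, 0.4),
                         runif(1, 0.3, 1.2), C)
    row <- setNames(sample(0:C, nl, replace = TRUE), tr$tip.label)
    prof <- matrix(row, 1, dimnames = list("f", names(row)))
    rec <- node_posteriors(prof, tr, m)
    for (v in seq_along(rec$posteriors))
      expect_equal(sum(rec$posteriors[[v]]), 1, tolerance = 1e-9)
    for (leaf in seq_len(nl))
      expect_equal(unname(rec$posteriors[[leaf]][1, row[tr$tip.label[leaf]] + 1L]), 1)
    bp <- brute_posteriors(row, tr, m)
    for (j in seq_len(tr$Nnode)) {
      v <- nl + j
      expect_lt(max(abs(bp[as.character(v), ] - rec$posteriors[[v]][1, ])), 1e-8)
    }
  }
})

test_that("a zero-length terminal branch pins the parent to the leaf state", {
  tr <- ape::read.tree(text = "((a:0,b:0.5):0.4,c:0.9);")
  m <- gain_loss_model(0.5, 0.2, 1.0, 2)
  prof <- matrix(c(2L, 0L, 1L), 1, dimnames = list("f", c("a", "b", "c")))
  rec <- node_posteriors(prof, tr, m)
  parent_of_a <- tr$edge[tr$edge[, 2] == which(tr$tip.label == "a"), 1]
  expect_equal(unname(rec$posteriors[[parent_of_a]][1, "2"]), 1, tolerance = 1e-12)
})

test_that("without innovation an absent root cannot spawn presence", {
  tr <- ape::rtree(4)
  m <- gain_loss_model(0, 0.3, 0.8, 2, root_prior = c(1, 0, 0))
  prof <- matrix(setNames(rep(0L, 4), tr$tip.label), 1,
                 dimnames = list("f", tr$tip.label))
  rec <- node_posteriors(prof, tr, m)
  for (v in seq_along(rec$posteriors))
    expect_equal(unname(rec$posteriors[[v]][1, "0"]), 1)
  ev <- call_branch_events(rec)
  expect_equal(nrow(ev$events), 0L)
})

test_that("event calls follow the presence-threshold and mode rules", {
  # hand-built reconstruction over a single branch pair root -> (a, b)
  tr <- ape::read.tree(text = "(a:1,b:1);")
  fake <- structure(list(
    presence = matrix(c(0.1, 0.90, 0.9,
                        0.2, 0.95, 0.9,
                        0.9, 0.85, 0.9,
                        0.6, 0.10, 0.2),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(paste0("f", 1:4), c("a", "b", "node3"))),
    mode_count = matrix(c(0, 3, 1,
                          0, 1, 1,
                          3, 1, 2,
                          1, 0, 0),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(paste0("f", 1:4), c("a", "b", "node3"))),
    node_names = c("a", "b", "node3"), tree = tr),
    class = "ancestral_reconstruction")
  ev <- call_branch_events(fake, threshold = 0.5)$events
  lookup <- function(f, child) ev$event[ev$family == f & ev$child == child]
  expect_equal(lookup("f1", "a"), "loss")        # present 0.9 -> absent 0.1
  expect_equal(lookup("f1", "b"), "expansion")   # mode 1 -> 3, both present
  expect_equal(lookup("f2", "a"), "loss")
  expect_equal(length(lookup("f2", "b")), 0L)    # same mode: none
  expect_equal(lookup("f3", "a"), "expansion")   # mode 2 -> 3
  expect_equal(lookup("f3", "b"), "reduction")   # mode 2 -> 1, both present
  expect_equal(lookup("f4", "a"), "gain")        # absent parent, present child
  expect_equal(length(lookup("f4", "b")), 0L)    # absent -> absent
})

test_that("node totals equal the column sums of per-family calls", {
  set.seed(8)
  tree <- ape::rtree(10)
  tree$edge.length <- tree$edge.length * 0.5
  m <- gain_loss_model(0.05, 0.05, 0.3, 5)
  sim <- simulate_profiles(profile_sim_spec(tree, 0.05, 0.05, 0.3, C = 5,
    n_families = 300, seed = 21))
  rec <- node_posteriors(sim$profile, tree, m)
  ev <- call_branch_events(rec)
  cols <- c(gain = "gains", loss = "losses", expansion = "expansions",
            reduction = "reductions")
  for (kind in names(cols)) {
    per_node <- table(ev$events$child[ev$events$event == kind])
    col <- cols[[kind]]
    for (nd in names(per_node))
      expect_equal(ev$node_totals[[col]][ev$node_totals$node == nd],
                   as.integer(per_node[[nd]]))
    expect_equal(sum(ev$node_totals[[col]]), sum(ev$events$event == kind))
  }
  expect_equal(unname(colSums(rec$presence >= 0.5)),
               ev$node_totals$families_present)
})

test_that("posterior decoding recovers most true events at low rates", {
  set.seed(8)
  tree <- ape::rtree(10)
  tree$edge.length <- tree$edge.length * 0.3
  m <- gain_loss_model(0.005, 0.005, 0.04, C = 5)
  sim <- simulate_profiles(profile_sim_spec(tree, 0.005, 0.005, 0.04, C = 5,
    n_families = 1500, condition_on_observed = TRUE, seed = 14))
  expect_lt(nrow(sim$branch_events) / 1500, 0.3)  # the low-rate regime
  rec <- node_posteriors(sim$profile, tree, m)
  ev <- call_branch_events(rec)
  key <- function(d) paste(d$parent, d$child, d$family, d$event)
  truth <- key(sim$branch_events); called <- key(ev$events)
  expect_gte(mean(truth %in% called), 0.85)
  expect_lte(mean(!(called %in% truth)), 0.10)
})

test_that("fitting returns a converged model beating the truth on its own data", {
  set.seed(40)
  tree <- ape::rtree(8)
  truth <- gain_loss_model(0.5, 0.2, 1.0, 5)
  sim <- simulate_profiles(profile_sim_spec(tree, 0.5, 0.2, 1.0, C = 5,
    n_families = 400, seed = 3))
  fit <- fit_model(sim$profile, tree, C = 5, n_starts = 2, seed = 2)
  expect_true(all(fit$convergence == 0L))
  expect_true(is.finite(fit$loglik))
  ll_truth <- sum(family_loglikelihood(sim$profile, tree, truth))
  expect_gte(fit$loglik, ll_truth - 1e-6)  # MLE dominates the generating model
})
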