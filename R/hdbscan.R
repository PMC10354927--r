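#' HDBSCAN density-based clustering
#'
#' Hierarchical density-based clustering with noise, following the standard
#' construction: (1) core distances (distance to the `min_samples`-th
#' nearest point, the point itself included); (2) mutual reachability
#' distance `max(core_i, core_j, d_ij)`; (3) a minimum spanning tree of the
#' mutual reachability graph, whose ascending edges give the single-linkage
#' hierarchy; (4) the hierarchy is condensed with minimum cluster size
#' `min_cluster_size`; (5) clusters are selected by excess-of-mass stability
#' and remaining points are labelled noise.
#'
#' @param x numeric matrix of points (rows = observations).
#' @param min_cluster_size smallest cluster size considered real (>= 2).
#' @param min_samples smoothing parameter for core distances; defaults to
#'   `min_cluster_size`.
#' @return integer vector of labels, one per row of `x`: `0` marks noise,
#'   clusters are numbered from 1.  Labels are arbitrary but stable for a
#'   fixed input.
#' @examples
#' pts <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
#' table(hdbscan_clusters(pts, min_cluster_size = 10))
#' @export
hdbscan_clusters <- function(x, min_cluster_size, min_samples = min_cluster_size) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- as.integer(min_cluster_size)
  if (m < 2L) stop("min_cluster_size must be >= 2")
  if (n < 1L) return(integer(0))
  if (n < m) return(rep(0L, n))
  d <- as.matrix(stats::dist(x))
  ms <- min(as.integer(min_samples), n)
  core <- apply(d, 1L, function(r) sort(r, partial = ms)[ms])
  mreach <- pmax(d, outer(core, core, pmax))
  mst <- prim_mst(mreach)
  if (max(mst$weight) == 0) {
    warning("all points coincide under mutual reachability: one cluster")
    return(rep(1L, n))
  }
  hier <- single_linkage(mst, n)
  condensed <- condense_hierarchy(hier, n, m)
  select_and_label(condensed, n)
}

# Prim's algorithm on a dense distance matrix; returns the n-1 MST edges
prim_mst <- function(d) {
  n <- nrow(d)
  in_tree <- logical(n); in_tree[1L] <- TRUE
  best <- d[1L, ]; from <- rep(1L, n)
  eg <- matrix(0L, n - 1L, 2L); w <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    eg[k, ] <- c(from[v], v); w[k] <- best[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best
    best[upd] <- d[v, upd]; from[upd] <- v
  }
  list(edges = eg, weight = w)
}

# merge the MST edges in ascending order into a binary merge tree
# (union-find); internal nodes n+1 .. 2n-1 carry heights and two children
single_linkage <- function(mst, n) {
  ord <- order(mst$weight)
  parent <- seq_len(2L * n - 1L)      # union-find with path halving
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  active <- seq_len(n)                # component representative -> tree node
  children <- matrix(0L, 2L * n - 1L, 2L)
  height <- numeric(2L * n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  nxt <- n
  for (k in ord) {
    a <- find(mst$edges[k, 1L]); b <- find(mst$edges[k, 2L])
    nxt <- nxt + 1L
    children[nxt, ] <- c(active[a], active[b])
    height[nxt] <- mst$weight[k]
    size[nxt] <- size[active[a]] + size[active[b]]
    parent[a] <- nxt; parent[b] <- nxt; parent[nxt] <- nxt
    active[nxt] <- nxt
  }
  list(children = children, height = height, size = size, root = 2L * n - 1L)
}

# condense the single-linkage tree: clusters persist until they split into
# two components of at least m points; smaller side-components "fall out".
# Tracks per-cluster stability sum((lambda_leave - lambda_birth)) and each
# point's deepest cluster membership.
condense_hierarchy <- function(hier, n, m) {
  minpos <- min(hier$height[hier$height > 0])
  lam <- function(h) if (h <= 0) 1 / (minpos * 1e-3) else 1 / h
  n_cl <- 1L
  cl_parent <- c(NA_integer_)
  cl_birth <- c(0)
  stability <- c(0)
  membership <- rep(1L, n)
  # iterative DFS over (tree node, cluster) pairs
  stack_node <- hier$root; stack_cl <- 1L
  while (length(stack_node) > 0L) {
    v <- stack_node[[1L]]; cl <- stack_cl[[1L]]
    stack_node <- stack_node[-1L]; stack_cl <- stack_cl[-1L]
    l <- lam(hier$height[v])
    a <- hier$children[v, 1L]; b <- hier$children[v, 2L]
    sa <- hier$size[a]; sb <- hier$size[b]
    if (sa >= m && sb >= m) {
      # true split: both sides become new clusters born at l
      stability[cl] <- stability[cl] + (sa + sb) * (l - cl_birth[cl])
      for (side in c(a, b)) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cl; cl_birth[n_cl] <- l; stability[n_cl] <- 0
        membership[subtree_points(hier, side, n)] <- n_cl
        stack_node <- c(stack_node, side); stack_cl <- c(stack_cl, n_cl)
      }
    } else if (sa >= m || sb >= m) {
      small <- if (sa < m) a else b
      big <- if (sa < m) b else a
      stability[cl] <- stability[cl] + hier$size[small] * (l - cl_birth[cl])
      stack_node <- c(stack_node, big); stack_cl <- c(stack_cl, cl)
    } else {
      # cluster dies: everything left falls out at l
      stability[cl] <- stability[cl] + (sa + sb) * (l - cl_birth[cl])
    }
  }
  list(parent = cl_parent, birth = cl_birth, stability = stability,
       membership = membership, n_clusters = n_cl)
}

subtree_points <- function(hier, v, n) {
  out <- integer(0); stack <- v
  while (length(stack) > 0L) {
    u <- stack[[1L]]; stack <- stack[-1L]
    if (u <= n) out <- c(out, u)
    else stack <- c(stack, hier$children[u, ])
  }
  out
}

# excess-of-mass selection (root excluded, i.e. no single-cluster solution),
# then label points through their cluster chain; unselected chains are noise
select_and_label <- function(condensed, n) {
  k <- condensed$n_clusters
  st <- condensed$stability
  sub <- st; selected <- rep(FALSE, k)
  kids <- split(seq_len(k)[-1L], condensed$parent[-1L])
  for (c in k:1) {                      # children have larger ids than parents
    ch <- kids[[as.character(c)]]
    if (is.null(ch)) { selected[c] <- TRUE; next }
    s_ch <- sum(sub[ch])
    if (s_ch > st[c]) { sub[c] <- s_ch } else { selected[c] <- TRUE }
  }
  selected[1L] <- FALSE
  # a cluster is final iff selected and no ancestor is selected
  final <- logical(k)
  for (c in seq_len(k)) {
    if (!selected[c]) next
    anc <- condensed$parent[c]; blocked <- FALSE
    while (!is.na(anc)) {
      if (selected[anc]) { blocked <- TRUE; break }
      anc <- condensed$parent[anc]
    }
    final[c] <- !blocked
  }
  lab_of_cluster <- integer(k)
  lab_of_cluster[final] <- seq_len(sum(final))
  labels <- integer(n)
  for (p in seq_len(n)) {
    c <- condensed$membership[p]
    while (!is.na(c)) {
      if (final[c]) { labels[p] <- lab_of_cluster[c]; break }
      c <- condensed$parent[c]
    }
  }
  labels
}
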