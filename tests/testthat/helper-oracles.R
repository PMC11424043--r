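# Independent oracles used across the suite. These deliberately avoid the
# package's own machinery: components via igraph, spanning trees by exhaustive
# enumeration, smoothing by dense algebra, permutation p-values by direct
# enumeration.

# Component labeling of `nodes` under the induced subgraph of an edge list,
# via igraph. Returns per-node component ids (1..k) parallel to `nodes`.
oracle_components <- function(nodes, edges_i, edges_j) {
  if (length(nodes) == 0L) return(integer(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges_i), to = as.character(edges_j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(nodes)])
}

# Canonical partition signature: sorted list of sorted member sets, so two
# labelings can be compared independently of label order.
partition_signature <- function(nodes, comp) {
  sets <- split(sort(nodes), comp[order(nodes)])
  sets <- lapply(unname(sets), sort)
  sets[order(vapply(sets, min, integer(1)))]
}

# Max-extent cluster statistic computed the slow, obvious way from a stat
# vector: igraph components within each sign's suprathreshold set.
oracle_max_extent <- function(stat, thr, edges_i, edges_j) {
  best <- 0L
  for (s in c(1, -1)) {
    nodes <- if (s > 0) which(!is.na(stat) & stat >= thr) else
      which(!is.na(stat) & stat <= -thr)
    if (length(nodes) == 0L) next
    keep <- edges_i %in% nodes & edges_j %in% nodes
    comp <- oracle_components(nodes, edges_i[keep], edges_j[keep])
    best <- max(best, max(tabulate(comp)))
  }
  best
}

# Plain one-sample t per node, written independently of the package.
oracle_t <- function(X) {
  apply(X, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) NA_real_ else mean(v) / (s / sqrt(length(v)))
  })
}

# All spanning trees of a small connected graph by brute force over edge
# subsets; returns the maximum total weight.
oracle_max_spanning_weight <- function(edges) {
  n <- max(edges$a, edges$b)
  k <- n - 1L
  if (nrow(edges) < k) return(NA_real_)
  best <- -Inf
  for (sel in utils::combn(nrow(edges), k, simplify = FALSE)) {
    sub <- edges[sel, ]
    comp <- oracle_components(seq_len(n), sub$a, sub$b)
    if (length(unique(comp)) == 1L) best <- max(best, sum(sub$weight))
  }
  best
}

# Random sparse symmetric weighted matrix.
random_conn <- function(n, n_edges, seed, distinct = FALSE) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  w <- if (distinct) sample(seq_len(length(pick))) / length(pick) else
    stats::runif(length(pick))
  conn_matrix(pairs[pick, 1], pairs[pick, 2], w, n_nodes = n)
}

# Independent spatial-only cluster-extent inference: base-R statistics,
# igraph components, direct p counting. Takes the sign-flip matrix so it can
# share permutations with the package run it is compared against.
reference_spatial_inference <- function(X, S, cdt, alpha, signs) {
  n <- nrow(X)
  t_thr <- stats::qt(stats::pnorm(cdt, lower.tail = FALSE, log.p = TRUE),
                     df = n - 1, lower.tail = FALSE, log.p = TRUE)
  ei <- S$i; ej <- S$j
  null_max <- integer(nrow(signs))
  for (p in seq_len(nrow(signs))) {
    tp <- oracle_t(signs[p, ] * X)
    null_max[p] <- oracle_max_extent(tp, t_thr, ei, ej)
  }
  t_obs <- oracle_t(X)
  node_extent <- integer(ncol(X))
  node_p <- rep(NA_real_, ncol(X))
  node_sig <- logical(ncol(X))
  for (s in c(1, -1)) {
    nodes <- if (s > 0) which(!is.na(t_obs) & t_obs >= t_thr) else
      which(!is.na(t_obs) & t_obs <= -t_thr)
    if (length(nodes) == 0L) next
    keep <- ei %in% nodes & ej %in% nodes
    comp <- oracle_components(nodes, ei[keep], ej[keep])
    for (k in unique(comp)) {
      members <- nodes[comp == k]
      ext <- length(members)
      pv <- mean(null_max >= ext)
      node_extent[members] <- ext
      node_p[members] <- pv
      node_sig[members] <- pv < alpha
    }
  }
  list(extent = node_extent, p = node_p, significant = node_sig,
       null_max = null_max)
}

# Regular icosahedron face list (1-based vertex indices); every vertex has
# five incident faces, hence mesh degree five.
icosahedron_faces <- function() {
  matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12,
           2,6,10, 6,12,5, 12,11,3, 11,8,7, 8,2,9,
           4,10,5, 4,5,3, 4,3,7, 4,7,9, 4,9,10,
           5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
         ncol = 3, byrow = TRUE)
}
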