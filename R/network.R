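#' Atlas labeling of nodes
#'
#' @param region_id Integer per-node region membership in `1..R`.
#' @param region_name Optional per-region names (default `region1..regionR`).
#' @return An object of class `atlas_labeling`.
#' @export
atlas_labeling <- function(region_id, region_name = NULL) {
  region_id <- as.integer(region_id)
  if (anyNA(region_id) || any(region_id < 1L))
    stop("every node needs a region id >= 1", call. = FALSE)
  R <- max(region_id)
  if (R < 2L) stop("at least 2 regions are required", call. = FALSE)
  if (is.null(region_name)) region_name <- paste0("region", seq_len(R))
  if (length(region_name) != R)
    stop("one name per region is required", call. = FALSE)
  structure(list(region_id = region_id, region_name = as.character(region_name),
                 n_regions = R),
            class = "atlas_labeling")
}

#' Filter a connectome to connections between significant nodes
#'
#' Keeps only the edges whose two endpoints both survive correction; all other
#' connections are deemed not directly involved in the effect and are removed.
#'
#' @param C A [conn_matrix] (typically the binary anatomical structure).
#' @param significant Logical per-node significance mask.
#' @return A [conn_matrix] with the restricted edge set.
#' @export
filter_connectome_to_significant <- function(C, significant) {
  stopifnot(inherits(C, "conn_matrix"))
  significant <- as.logical(significant)
  if (length(significant) != C$n_nodes)
    stop("mask length does not match the connectome", call. = FALSE)
  keep <- significant[C$i] & significant[C$j]
  conn_matrix(C$i[keep], C$j[keep], C$w[keep], n_nodes = C$n_nodes,
              binary = C$binary)
}

#' Downsample a high-resolution connectome to atlas regions
#'
#' The region-by-region edge weight is one if any high-resolution edge
#' connects the two regions (invariant to edge multiplicity). Intra-region
#' connections are suppressed (zero diagonal).
#'
#' @param C A [conn_matrix] over nodes.
#' @param atlas An [atlas_labeling] covering all nodes.
#' @return A binary [conn_matrix] over regions.
#' @export
downsample_to_atlas <- function(C, atlas) {
  stopifnot(inherits(C, "conn_matrix"), inherits(atlas, "atlas_labeling"))
  if (length(atlas$region_id) != C$n_nodes)
    stop("atlas does not cover all nodes", call. = FALSE)
  ri <- atlas$region_id[C$i]
  rj <- atlas$region_id[C$j]
  keep <- ri != rj
  conn_matrix(ri[keep], rj[keep], 1, n_nodes = atlas$n_regions, binary = TRUE)
}

#' Major spatially contiguous clusters of significant nodes
#'
#' Connected components of the significant node set under the spatial
#' structure alone; components smaller than `min_fraction` of the largest
#' component are discarded, masking spatially minuscule effects.
#'
#' @param significant Logical per-node mask.
#' @param S Binary spatial [conn_matrix].
#' @param min_fraction Minimum size relative to the largest cluster (default
#'   0.01).
#' @return List of integer node-index vectors, largest first; empty list when
#'   nothing is significant.
#' @export
major_spatial_clusters <- function(significant, S, min_fraction = 0.01) {
  stopifnot(inherits(S, "conn_matrix"))
  significant <- as.logical(significant)
  if (length(significant) != S$n_nodes)
    stop("mask length does not match the spatial structure", call. = FALSE)
  nodes <- which(significant)
  if (length(nodes) == 0L) return(list())
  inset <- logical(S$n_nodes); inset[nodes] <- TRUE
  keep <- inset[S$i] & inset[S$j]
  comp <- uf_components(nodes, S$i[keep], S$j[keep])
  sizes <- tabulate(comp)
  cutoff <- min_fraction * max(sizes)
  ids <- order(-sizes)
  ids <- ids[sizes[ids] >= cutoff]
  lapply(ids, function(k) nodes[comp == k])
}

#' Graph of anatomical connections between major clusters
#'
#' Two clusters are joined when at least one filtered anatomical edge connects
#' them; the edge weight is the product of the maximum absolute effect size
#' observed in each of the two clusters.
#'
#' @param filtered A [filter_connectome_to_significant()] result.
#' @param clusters Disjoint list of node sets (see [major_spatial_clusters()]).
#' @param d Numeric per-node effect sizes.
#' @param use_abs Use `|d|` for cluster peak effects (default TRUE).
#' @return An object of class `cluster_graph`: `clusters`, `peak_effect`
#'   (per-cluster), `edges` (data frame `a`, `b`, `weight`), and `tree_edges`
#'   (filled by [maximum_spanning_tree()]).
#' @export
cluster_graph <- function(filtered, clusters, d, use_abs = TRUE) {
  stopifnot(inherits(filtered, "conn_matrix"))
  all_nodes <- unlist(clusters)
  if (anyDuplicated(all_nodes))
    stop("clusters must be disjoint", call. = FALSE)
  member <- integer(filtered$n_nodes)
  for (k in seq_along(clusters)) member[clusters[[k]]] <- k
  peak <- vapply(clusters, function(nodes) {
    v <- d[nodes]
    if (use_abs) max(abs(v)) else max(v)
  }, numeric(1))
  ca <- member[filtered$i]
  cb <- member[filtered$j]
  keep <- ca > 0L & cb > 0L & ca != cb
  a <- pmin(ca[keep], cb[keep])
  b <- pmax(ca[keep], cb[keep])
  pair <- unique(cbind(a, b))
  edges <- if (nrow(pair) > 0L)
    data.frame(a = pair[, 1], b = pair[, 2],
               weight = peak[pair[, 1]] * peak[pair[, 2]])
  else data.frame(a = integer(0), b = integer(0), weight = numeric(0))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(clusters = clusters, peak_effect = peak, edges = edges,
                 tree_edges = NULL),
            class = "cluster_graph")
}

#' Maximum spanning tree (forest) of a cluster graph
#'
#' Kruskal's algorithm on descending weights, with deterministic tie-breaking
#' by weight then by node-id pair. On a disconnected graph a maximum spanning
#' forest is returned (one tree per connected component). The result keeps the
#' anatomical connections most strongly implicated in the effect.
#'
#' @param graph A [cluster_graph()] result, or a data frame with columns `a`,
#'   `b`, `weight`.
#' @return The input with `tree_edges` set (a data frame subset of `edges`);
#'   when given a bare data frame, the tree edge data frame itself.
#' @export
maximum_spanning_tree <- function(graph) {
  edges <- if (inherits(graph, "cluster_graph")) graph$edges else as.data.frame(graph)
  stopifnot(all(c("a", "b", "weight") %in% names(edges)))
  if (nrow(edges) > 0L && any(edges$weight <= 0))
    stop("edge weights must be positive", call. = FALSE)
  ord <- order(-edges$weight, edges$a, edges$b)
  n <- if (nrow(edges) > 0L) max(edges$a, edges$b) else 0L
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(edges))
  for (e in ord) {
    ra <- find(edges$a[e]); rb <- find(edges$b[e])
    if (ra != rb) {
      parent[max(ra, rb)] <- min(ra, rb)
      keep[e] <- TRUE
    }
  }
  tree <- edges[keep, , drop = FALSE]
  rownames(tree) <- NULL
  if (inherits(graph, "cluster_graph")) {
    graph$tree_edges <- tree
    graph
  } else tree
}

#' Summarize the anatomical network implicated by an inference result
#'
#' Convenience pipeline: filter the anatomical structure to significant nodes,
#' downsample to an atlas, find major spatial clusters, build the weighted
#' cluster graph and extract its maximum spanning tree.
#'
#' @param result A [run_inference()] result.
#' @param C_dist Binary anatomical [conn_matrix].
#' @param S Binary spatial [conn_matrix].
#' @param atlas An [atlas_labeling].
#' @param min_fraction Cluster-size cutoff (see [major_spatial_clusters()]).
#' @return List with `filtered`, `region_matrix`, `clusters`, `graph`.
#' @export
summarize_network <- function(result, C_dist, S, atlas, min_fraction = 0.01) {
  stopifnot(inherits(result, "inference_result"))
  filtered <- filter_connectome_to_significant(C_dist, result$significant)
  region_matrix <- downsample_to_atlas(filtered, atlas)
  clusters <- major_spatial_clusters(result$significant, S, min_fraction)
  graph <- if (length(clusters) > 0L)
    maximum_spanning_tree(cluster_graph(filtered, clusters, result$stat$d))
  else NULL
  list(filtered = filtered, region_matrix = region_matrix,
       clusters = clusters, graph = graph)
}
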