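test_that("connectome filtering keeps edges between significant endpoints", {
  C <- conn_matrix(c(1, 1, 2, 4), c(2, 3, 5, 6), c(1, 2, 3, 4), n_nodes = 6)
  none <- filter_connectome_to_significant(C, rep(FALSE, 6))
  expect_equal(conn_n_edges(none), 0L)
  all_kept <- filter_connectome_to_significant(C, rep(TRUE, 6))
  expect_equal(all_kept[c("i", "j", "w")], C[c("i", "j", "w")])
  sig <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  f <- filter_connectome_to_significant(C, sig)
  # brute-force endpoint check
  keep <- sig[C$i] & sig[C$j]
  expect_equal(cbind(f$i, f$j), cbind(C$i[keep], C$j[keep]))
  expect_error(filter_connectome_to_significant(C, TRUE), "mask length")
})

test_that("atlas downsampling is binary and multiplicity-invariant", {
  atlas <- atlas_labeling(c(3, 3, 7, 7, 1, 1), paste0("r", 1:7))
  one_edge <- conn_matrix(1, 3, n_nodes = 6, binary = TRUE)
  r1 <- downsample_to_atlas(one_edge, atlas)
  expect_equal(cbind(r1$i, r1$j), cbind(3L, 7L))
  # many hi-res edges between the same pair still give weight one
  many <- conn_matrix(c(1, 1, 2, 2), c(3, 4, 3, 4), n_nodes = 6, binary = TRUE)
  r2 <- downsample_to_atlas(many, atlas)
  expect_equal(cbind(r2$i, r2$j), cbind(3L, 7L))
  expect_identical(r2$w, 1)
  # intra-region connections are suppressed
  intra <- conn_matrix(c(1, 3), c(2, 4), n_nodes = 6, binary = TRUE)
  expect_equal(conn_n_edges(downsample_to_atlas(intra, atlas)), 0L)
  expect_error(atlas_labeling(rep(1L, 5)), "at least 2")
})

test_that("filter-then-downsample commutes with downsampling a filtered set", {
  set.seed(15)
  C <- random_conn(20, 60, seed = 15)
  Cb <- conn_matrix(C$i, C$j, 1, n_nodes = 20, binary = TRUE)
  atlas <- atlas_labeling(sample(1:5, 20, replace = TRUE))
  sig <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  a <- downsample_to_atlas(filter_connectome_to_significant(Cb, sig), atlas)
  # oracle route: restrict the region matrix to region pairs that have at
  # least one surviving hi-res edge (set-level identity)
  keep <- sig[Cb$i] & sig[Cb$j]
  ri <- atlas$region_id[Cb$i[keep]]; rj <- atlas$region_id[Cb$j[keep]]
  ok <- ri != rj
  b <- conn_matrix(ri[ok], rj[ok], 1, n_nodes = 5, binary = TRUE)
  expect_equal(a[c("i", "j", "w")], b[c("i", "j", "w")])
})

test_that("major spatial clusters apply the relative size cutoff", {
  # three chains of sizes 200, 10, 1 on a path-structured S
  n <- 211
  S <- conn_matrix(c(1:199, 201:209), c(2:200, 202:210), n_nodes = n,
                   binary = TRUE)
  sig <- rep(TRUE, n)
  cl <- major_spatial_clusters(sig, S, min_fraction = 0.01)
  expect_equal(lengths(cl), c(200L, 10L)) # 1 < 1% of 200 = 2, discarded
  expect_equal(cl[[1]], 1:200)
  # single cluster is returned as itself
  single <- major_spatial_clusters(c(rep(TRUE, 5), rep(FALSE, n - 5)), S)
  expect_equal(single, list(1:5))
  expect_equal(major_spatial_clusters(rep(FALSE, n), S), list())
  # components match the igraph oracle on random instances
  for (seed in 1:10) {
    set.seed(seed)
    m <- random_conn(40, 50, seed + 300)
    Sb <- conn_matrix(m$i, m$j, 1, n_nodes = 40, binary = TRUE)
    mask <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    got <- major_spatial_clusters(mask, Sb, min_fraction = 0)
    nodes <- which(mask)
    keep <- Sb$i %in% nodes & Sb$j %in% nodes
    oc <- oracle_components(nodes, Sb$i[keep], Sb$j[keep])
    want <- partition_signature(nodes, oc)
    expect_setequal(lapply(got, sort), want)
  }
})

test_that("cluster graph weights are products of peak effects", {
  # 6 nodes, two clusters, effects with known maxima
  filtered <- conn_matrix(c(1, 2), c(4, 5), n_nodes = 6, binary = TRUE)
  clusters <- list(c(1L, 2L, 3L), c(4L, 5L))
  d <- c(0.1, -0.5, 0.2, 0.8, 0.3, 0.9)
  g <- cluster_graph(filtered, clusters, d)
  expect_equal(g$peak_effect, c(0.5, 0.8))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 0.4)
  # no anatomical edge between a pair -> no graph edge
  g2 <- cluster_graph(conn_matrix(1, 2, n_nodes = 6, binary = TRUE),
                      clusters, d)
  expect_equal(nrow(g2$edges), 0L)
  expect_error(cluster_graph(filtered, list(1:3, 3:5), d), "disjoint")
  # 4-cluster toy: adjacency equals a brute-force pairwise edge scan
  set.seed(16)
  f4 <- conn_matrix(c(1, 3, 5, 7, 1), c(4, 6, 8, 2, 6), n_nodes = 8,
                    binary = TRUE)
  cl4 <- list(1:2, 3:4, 5:6, 7:8)
  d4 <- stats::runif(8)
  g4 <- cluster_graph(f4, cl4, d4)
  member <- rep(1:4, each = 2)
  oracle <- unique(t(apply(cbind(member[f4$i], member[f4$j]), 1, sort)))
  oracle <- oracle[oracle[, 1] != oracle[, 2], , drop = FALSE]
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(cbind(g4$edges$a, g4$edges$b), oracle, ignore_attr = TRUE)
})

test_that("maximum spanning tree matches exhaustive enumeration", {
  # triangle with weights 3, 2, 1: tree keeps the 3- and 2-edges
  tri <- data.frame(a = c(1L, 1L, 2L), b = c(2L, 3L, 3L), weight = c(3, 2, 1))
  tree <- maximum_spanning_tree(tri)
  expect_equal(sort(tree$weight), c(2, 3))
  # a tree input comes back unchanged
  path <- data.frame(a = 1:3, b = 2:4, weight = c(1, 5, 2))
  expect_equal(maximum_spanning_tree(path), path)
  # random 5-node graphs vs. brute force over all spanning trees
  for (seed in 1:8) {
    set.seed(seed)
    pairs <- t(utils::combn(5, 2))
    pick <- sort(sample(10, 8))
    edges <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                        weight = stats::runif(8, 0.1, 1))
    comp <- oracle_components(1:5, edges$a, edges$b)
    if (length(unique(comp)) > 1) next
    tree <- maximum_spanning_tree(edges)
    expect_equal(nrow(tree), 4L)
    expect_equal(sum(tree$weight), oracle_max_spanning_weight(edges),
                 tolerance = 1e-12)
    # acyclic and spanning: 5 nodes, 4 edges, one component
    expect_equal(length(unique(oracle_components(1:5, tree$a, tree$b))), 1L)
  }
  # disconnected graph: a spanning forest, one tree per component
  forest <- maximum_spanning_tree(data.frame(a = c(1L, 3L), b = c(2L, 4L),
                                             weight = c(1, 2)))
  expect_equal(nrow(forest), 2L)
  expect_error(maximum_spanning_tree(data.frame(a = 1L, b = 2L, weight = 0)),
               "positive")
})

test_that("network summary pipeline runs end to end on a phantom", {
  ph <- make_ribbon_phantom(grid_shape = c(40, 40))
  topo <- make_phantom_topology(ph)
  samp <- simulate_subject_sample(ph, 20, effect_scale = 2, seed = 41)
  res <- run_inference(samp, topo$T, cdt = 2, n_perm = 200, seed = 42)
  fibers <- conn_matrix(ph$fiber_edges$i, ph$fiber_edges$j, 1,
                        n_nodes = ph$n_nodes, binary = TRUE)
  atlas <- atlas_labeling(ph$region_label)
  net <- summarize_network(res, fibers, topo$S, atlas)
  expect_s3_class(net$region_matrix, "conn_matrix")
  expect_equal(net$region_matrix$n_nodes, 11L)
  if (length(net$clusters) > 1) {
    expect_true(all(lengths(net$clusters) >=
                      0.01 * max(lengths(net$clusters))))
    expect_true(is.null(net$graph$tree_edges) ||
                  nrow(net$graph$tree_edges) <= length(net$clusters) - 1)
  }
})
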