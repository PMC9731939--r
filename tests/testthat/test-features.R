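test_that("structural features match hand-derived barbell values", {
  b <- fixture_barbell(5)
  f <- structural_node_features(b)
  # non-portal clique node: neighbours form K4
  expect_equal(f$clustering_coefficient[2], 1)
  # portal a1: 6 triangles among 5 neighbours -> 2*6/(5*4)
  expect_equal(f$clustering_coefficient[1], 0.6)
  # all cross-clique shortest paths route through the portals
  expect_true(all(f$betweenness[1] > f$betweenness[2:5]))
  expect_equal(f$degree, c(5, rep(4, 4), 5, rep(4, 4)))
  # path graph a-b-c: closeness(b) = (3-1)/2
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(structural_node_features(path3)$closeness[2], 1)
})

test_that("community features match the barbell fixture exactly", {
  b <- fixture_barbell(5)
  e <- make_ensemble(matrix(b$ground_truth$label, ncol = 1))
  f <- community_node_features(b, e)
  # non-portal node a2: fully internal
  expect_equal(f$e_in[2], 4)
  expect_equal(f$e_out[2], 0)
  expect_equal(f$odf[2], 0)
  expect_equal(f$conductance[2], 0)
  # portal a1: one external edge, w = 4 companions, |V| = 10
  expect_equal(f$conductance[1], 1 / 9)
  expect_equal(f$odf[1], 1 / 5)
  expect_equal(f$expansion[1], 1 / 4)
  expect_equal(f$cut_ratio[1], 1 / 6)
  # run-mean contract: runs with E_out 1 and 0 average to 0.5
  e2 <- make_ensemble(cbind(b$ground_truth$label, rep(1L, 10)))
  f2 <- community_node_features(b, e2)
  expect_equal(f2$e_out[1], 0.5)
})

test_that("features equal brute-force recomputation on planted graphs", {
  g <- generate_planted_partition(4, 12, p_in = 0.5, p_out = 0.06, seed = 11)
  gg <- g$graph
  f <- structural_node_features(gg)
  D <- oracle_distances(gg)
  n <- igraph::vcount(gg)
  expect_equal(f$avg_shortest_path, rowSums(D) / (n - 1))
  expect_equal(f$closeness, (n - 1) / rowSums(D))
  expect_equal(f$clustering_coefficient, oracle_clustering(gg))
  bt <- oracle_betweenness(gg)
  expect_equal(f$betweenness, bt$node, tolerance = 1e-9)
  # eigenvector centrality solves Ax = lambda x after unit normalization
  A <- as.matrix(igraph::as_adjacency_matrix(gg))
  x <- f$eigenvector_centrality / sqrt(sum(f$eigenvector_centrality^2))
  lambda <- as.numeric(t(x) %*% A %*% x)
  expect_lt(sqrt(sum((A %*% x - lambda * x)^2)), 1e-8)
  # community-dependent features against per-definition oracle, two runs
  e <- run_ensemble(gg, "louvain", n_runs = 2, base_seed = 5)
  fc <- community_node_features(gg, e)
  o <- (oracle_community_features(gg, e$memberships[, 1]) +
          oracle_community_features(gg, e$memberships[, 2])) / 2
  for (col in colnames(o)) {
    expect_equal(fc[[col]], unname(o[, col]), tolerance = 1e-12, label = col)
  }
})

test_that("triangle-participation witness location is switchable", {
  # triangle 1-2-3 with node 3 outside the community of 1 and 2: the only
  # common neighbour of the pair (1,2) is the outside node 3
  tri <- igraph::make_graph(c(1, 2, 2, 3, 3, 1), directed = FALSE)
  e <- make_ensemble(matrix(c(1L, 1L, 2L), ncol = 1))
  strict <- community_node_features(tri, e)
  loose <- community_node_features(tri, e, witness = "any")
  expect_equal(strict$triangle_participation[1:2], c(0, 0))
  expect_equal(loose$triangle_participation[1:2], c(1, 1))
  # inside a clique community both readings coincide
  b <- fixture_barbell(5)
  eb <- make_ensemble(matrix(b$ground_truth$label, ncol = 1))
  expect_equal(community_node_features(b, eb)$triangle_participation,
               community_node_features(b, eb, witness = "any")$triangle_participation)
})

test_that("E_in + E_out equals degree for every node in every run", {
  g <- generate_planted_partition(3, 15, p_in = 0.4, p_out = 0.05, seed = 2)
  deg <- igraph::degree(g$graph)
  e <- run_ensemble(g, "lpa", n_runs = 20, base_seed = 3)
  for (r in c(1, 7, 20)) {
    o <- oracle_community_features(g$graph, e$memberships[, r])
    expect_equal(unname(o[, "e_in"] + o[, "e_out"]), unname(as.numeric(deg)))
  }
  # and therefore for run means too
  f <- community_node_features(g, e)
  expect_equal(f$e_in + f$e_out, unname(as.numeric(deg)))
})

test_that("bounded features stay in [0, 1]", {
  g <- generate_planted_partition(3, 20, p_in = 0.35, p_out = 0.05, seed = 6)
  e <- run_ensemble(g, "louvain", n_runs = 10, base_seed = 1)
  f <- node_features(g, e)
  for (col in c("odf", "cut_ratio", "conductance", "triangle_participation",
                "clustering_coefficient")) {
    expect_true(all(f[[col]] >= 0 & f[[col]] <= 1), label = col)
  }
})

test_that("pair features match the barbell fixture", {
  b <- fixture_barbell(5)
  pairs <- tibble::tibble(i = c(2L, 1L, 2L), j = c(3L, 6L, 7L))
  f <- pair_features(b, pairs)
  # (a2, a3): common neighbours a1, a4, a5
  expect_equal(f$common_neighbours[1], 3)
  expect_equal(f$cosine_similarity[1], 0.75)  # 3 / sqrt(16)
  expect_equal(f$jaccard[1], 0.6)             # 3 / 5
  # portals share no neighbours
  expect_equal(f$common_neighbours[2], 0)
  expect_equal(f$cosine_similarity[2], 0)
  # (a2, b2): three hops, and the geodesic crosses the bridge, the most
  # central edge in the graph
  expect_equal(f$shortest_path_length[3], 3)
  eb <- igraph::edge_betweenness(b$graph, directed = FALSE)
  expect_equal(f$max_edge_centrality[3], max(eb))
  expect_error(pair_features(b, tibble::tibble(i = 1L, j = 1L)), "distinct")
})

test_that("pair features agree with neighbourhood-set oracles", {
  g <- generate_planted_partition(3, 12, p_in = 0.5, p_out = 0.08, seed = 21)
  gg <- g$graph
  set.seed(3)
  pairs <- tibble::tibble(i = sample(1:36, 25, replace = TRUE),
                          j = sample(1:36, 25, replace = TRUE))
  pairs <- pairs[pairs$i != pairs$j, ]
  f <- pair_features(gg, pairs)
  D <- oracle_distances(gg)
  bt <- oracle_betweenness(gg)
  ends <- igraph::as_edgelist(gg, names = FALSE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    gi <- as.integer(igraph::neighbors(gg, i))
    gj <- as.integer(igraph::neighbors(gg, j))
    expect_equal(f$common_neighbours[k], length(intersect(gi, gj)))
    expect_equal(f$jaccard[k],
                 length(intersect(gi, gj)) / length(union(gi, gj)))
    expect_equal(f$shortest_path_length[k], D[i, j])
    # union-of-geodesics max edge centrality straight from distances
    on_geo <- (D[i, ends[, 1]] + 1 + D[j, ends[, 2]] == D[i, j]) |
      (D[i, ends[, 2]] + 1 + D[j, ends[, 1]] == D[i, j])
    expect_equal(f$max_edge_centrality[k], max(bt$edge[on_geo]),
                 tolerance = 1e-9)
  }
  # identical neighbourhoods give jaccard 1: opposite corners of a 4-cycle
  c4 <- igraph::make_ring(4)
  expect_equal(pair_features(c4, tibble::tibble(i = 1L, j = 3L))$jaccard, 1)
})

test_that("cosine and jaccard order pairs identically on regular graphs", {
  set.seed(8)
  g <- igraph::sample_k_regular(30, 6)
  while (!igraph::is_connected(g)) g <- igraph::sample_k_regular(30, 6)
  pairs <- all_pairs_30 <- tibble::tibble(
    i = rep(1:29, 29:1),
    j = sequence(29:1, from = 2:30)
  )
  f <- pair_features(g, pairs)
  expect_equal(order(f$cosine_similarity, f$i, f$j),
               order(f$jaccard, f$i, f$j))
})

test_that("feature tables have the canonical shape", {
  b <- fixture_barbell(5)
  e <- run_ensemble(b, "louvain", n_runs = 10, base_seed = 2)
  feats <- node_features(b, e)
  labels <- tibble::tibble(
    node = 1:10,
    label = factor(rep(c("easy", "hard"), c(6, 4)), levels = c("easy", "hard")),
    selected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  tab <- assemble_feature_table(feats, labels)
  expect_equal(nrow(tab), 7)
  expect_equal(ncol(tab), 16)  # node + 14 features + label
  expect_false(anyNA(tab))
  # row content independent of label row order
  tab2 <- assemble_feature_table(feats, labels[sample(1:10), ])
  expect_equal(dplyr::arrange(tab, node), dplyr::arrange(tab2, node))
  expect_error(assemble_feature_table(feats[1:5, ], labels), "missing")
})
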