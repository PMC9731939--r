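# Interpretable graph features. Node-level features split into
# community-independent structural features (computed once per graph) and
# community-dependent features (computed against each run's partition and
# averaged over the ensemble). Pair-level features are community-free and
# computed only for a requested pair subset.

node_feature_names <- c(
  "degree", "e_in", "e_out", "e_in_over_e_out", "odf", "expansion",
  "cut_ratio", "conductance", "avg_shortest_path", "triangle_participation",
  "clustering_coefficient", "betweenness", "eigenvector_centrality",
  "closeness"
)

pair_feature_names <- c(
  "shortest_path_length", "common_neighbours", "max_edge_centrality",
  "cosine_similarity", "jaccard"
)

#' Community-independent node features
#'
#' Degree, mean shortest-path length to all other nodes, local clustering
#' coefficient (`2 T_i / (deg (deg - 1))`, defined as 0 for degree <= 1),
#' betweenness centrality (Brandes, unordered pairs, endpoints excluded,
#' unnormalized), eigenvector centrality (principal adjacency eigenvector,
#' nonnegative, unit Euclidean norm) and closeness centrality
#' (`(|V|-1) / sum_j d(j,i)`).
#'
#' @param graph An igraph object or `cd_graph`; connected, >= 3 nodes.
#' @return A tibble `node` plus the six structural feature columns.
#' @export
structural_node_features <- function(graph) {
  g <- as_cd_igraph(graph)
  assert_graph(g, connected = TRUE)
  n <- igraph::vcount(g)
  if (n < 3) abort("graph must have at least 3 nodes")
  D <- igraph::distances(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  ev <- igraph::eigen_centrality(g)$vector
  ev <- abs(ev) / sqrt(sum(ev^2))
  tibble(
    node = seq_len(n),
    degree = unname(as.numeric(igraph::degree(g))),
    avg_shortest_path = unname(rowSums(D) / (n - 1)),
    clustering_coefficient = unname(cc),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = FALSE)),
    eigenvector_centrality = unname(ev),
    closeness = unname((n - 1) / rowSums(D))
  )
}

# per-run community-dependent node features for one membership vector;
# A is the (dense logical) adjacency, only consulted when the triangle
# witness may lie outside the community
community_features_one_run <- function(ends, deg, n, m, witness, A = NULL) {
  same <- m[ends[, 1]] == m[ends[, 2]]
  e_in <- tabulate(c(ends[same, 1], ends[same, 2]), nbins = n)
  e_out_direct <- tabulate(c(ends[!same, 1], ends[!same, 2]), nbins = n)
  stopifnot(all(e_in + e_out_direct == deg))  # E_in + E_out = deg(i)
  e_out <- deg - e_in
  csize <- tabulate(m)
  w <- csize[m] - 1  # community companions, node itself excluded

  # triangle participation: nodes j != i in i's community sharing a common
  # neighbour k that also lies in the community
  c_i <- integer(n)
  if (witness == "within_community") {
    intra_by_comm <- split(which(same), m[ends[same, 1]])
    for (lab_chr in names(intra_by_comm)) {
      S <- which(m == as.integer(lab_chr))
      es <- ends[intra_by_comm[[lab_chr]], , drop = FALSE]
      B <- matrix(0L, length(S), length(S))
      li <- match(es[, 1], S)
      lj <- match(es[, 2], S)
      B[cbind(li, lj)] <- 1L
      B[cbind(lj, li)] <- 1L
      M2 <- B %*% B
      c_i[S] <- rowSums(M2 > 0L) - as.integer(diag(M2) > 0L)
    }
  } else {
    # witness node may lie anywhere in the graph
    for (lab in unique(m)) {
      S <- which(m == lab)
      if (length(S) < 2L) next
      P <- A[S, , drop = FALSE]
      M2 <- tcrossprod(P * 1L)
      c_i[S] <- rowSums(M2 > 0L) - as.integer(diag(M2) > 0L)
    }
  }

  cbind(
    e_in = e_in,
    e_out = e_out,
    e_in_over_e_out = e_in / pmax(e_out, 1),
    odf = e_out / deg,
    expansion = e_out / pmax(w, 1),
    cut_ratio = e_out / (n - w),
    conductance = e_out / (deg + e_in),
    triangle_participation = c_i / pmax(w, 1)
  )
}

#' Community-dependent node features, averaged over an ensemble
#'
#' For every run the features `E_in`, `E_out`, `E_in/E_out`, out-degree
#' fraction, expansion, cut ratio, conductance and triangle participation
#' are evaluated against that run's partition; the arithmetic mean over
#' runs is reported. Degenerate denominators are floored at 1 (`E_out = 0`
#' for the ratio; singleton communities for expansion and triangle
#' participation), keeping every feature finite.
#'
#' @param graph An igraph object or `cd_graph`.
#' @param ensemble A `cd_ensemble` on the same graph.
#' @param witness Where the common neighbour counted by triangle
#'   participation must lie: `"within_community"` (default; the witness
#'   itself belongs to the node's community) or `"any"` (anywhere in the
#'   graph).
#' @return A tibble `node` plus the eight community-dependent columns.
#' @export
community_node_features <- function(graph, ensemble,
                                    witness = c("within_community", "any")) {
  witness <- match.arg(witness)
  g <- as_cd_igraph(graph)
  stopifnot(inherits(ensemble, "cd_ensemble"))
  n <- igraph::vcount(g)
  stopifnot(nrow(ensemble$memberships) == n)
  ends <- igraph::as_edgelist(g, names = FALSE)
  deg <- as.numeric(igraph::degree(g))
  A <- if (witness == "any") {
    as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE)) > 0
  }
  acc <- NULL
  for (r in seq_len(ensemble$n_runs)) {
    f <- community_features_one_run(ends, deg, n, ensemble$memberships[, r],
                                    witness, A)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- as_tibble(as.data.frame(acc / ensemble$n_runs))
  dplyr::bind_cols(tibble(node = seq_len(n)), out)
}

#' All 14 node features for an ensemble
#'
#' Joins [structural_node_features()] and [community_node_features()] in
#' the canonical column order.
#'
#' @inheritParams community_node_features
#' @return A tibble `node` plus the 14 node feature columns.
#' @export
node_features <- function(graph, ensemble) {
  out <- dplyr::left_join(structural_node_features(graph),
                          community_node_features(graph, ensemble),
                          by = "node")
  dplyr::select(out, "node", dplyr::all_of(node_feature_names))
}

#' Node-pair features
#'
#' Shortest-path length, common-neighbour count, maximum edge betweenness
#' along the shortest path(s), cosine similarity
#' (`n_ij / sqrt(deg_i deg_j)`) and Jaccard coefficient of the two
#' neighbourhoods. With several geodesics between a pair, the edge
#' centrality maximum is taken over the union of edges lying on any
#' geodesic (`geodesic_mode = "union"`, deterministic) or over one
#' canonical shortest path (`"single"`).
#'
#' @param graph An igraph object or `cd_graph`; connected.
#' @param pairs Tibble or data frame with columns `i`, `j` of distinct
#'   node indices.
#' @param geodesic_mode `"union"` (default) or `"single"`.
#' @return `pairs` with the five feature columns appended.
#' @export
pair_features <- function(graph, pairs, geodesic_mode = c("union", "single")) {
  geodesic_mode <- match.arg(geodesic_mode)
  g <- as_cd_igraph(graph)
  assert_graph(g, connected = TRUE)
  if (any(pairs$i == pairs$j)) abort("pairs must consist of distinct nodes")
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE)) > 0
  deg <- as.numeric(igraph::degree(g))
  D <- igraph::distances(g)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)

  np <- nrow(pairs)
  spl <- D[cbind(pairs$i, pairs$j)]
  nij <- numeric(np)
  mec <- numeric(np)
  for (p in seq_len(np)) {
    i <- pairs$i[p]
    j <- pairs$j[p]
    nij[p] <- sum(A[, i] & A[, j])
    if (geodesic_mode == "union") {
      d <- spl[p]
      on_geo <- (D[i, ends[, 1]] + 1 + D[j, ends[, 2]] == d) |
        (D[i, ends[, 2]] + 1 + D[j, ends[, 1]] == d)
      mec[p] <- max(eb[on_geo])
    } else {
      sp <- igraph::shortest_paths(g, from = i, to = j, output = "epath")
      mec[p] <- max(eb[as.integer(sp$epath[[1]])])
    }
  }
  dplyr::bind_cols(
    as_tibble(pairs[, c("i", "j")]),
    tibble(
      shortest_path_length = spl,
      common_neighbours = nij,
      max_edge_centrality = mec,
      cosine_similarity = nij / sqrt(deg[pairs$i] * deg[pairs$j]),
      jaccard = nij / (deg[pairs$i] + deg[pairs$j] - nij)
    )
  )
}

#' Assemble a labelled feature table
#'
#' Combines a feature tibble with a labelling (node or pair) restricted to
#' the selected training subset; this is the input to
#' [train_and_importances()]. Column order is canonical; the binary label
#' column is named `label`.
#'
#' @param features Output of [node_features()] or [pair_features()].
#' @param labels Labelling tibble with a `selected` column (from
#'   [strategic_undersample()] or [undersample_pairs()]).
#' @return A `cd_feature_table` tibble (id columns, feature columns,
#'   `label`), with the feature names in attribute `"features"`.
#' @export
assemble_feature_table <- function(features, labels) {
  key <- if ("node" %in% names(labels)) "node" else c("i", "j")
  feat_cols <- intersect(c(node_feature_names, pair_feature_names),
                         names(features))
  sel <- labels[labels$selected, c(key, "label")]
  out <- dplyr::inner_join(sel, features, by = key)
  if (nrow(out) != nrow(sel)) abort("missing features for selected keys")
  out <- dplyr::select(out, dplyr::all_of(key), dplyr::all_of(feat_cols), "label")
  if (anyNA(out)) abort("feature table contains missing values")
  attr(out, "features") <- feat_cols
  class(out) <- c("cd_feature_table", class(out))
  out
}
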