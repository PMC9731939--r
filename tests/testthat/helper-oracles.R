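# Brute-force oracles, deliberately naive and independent of the package's
# computation paths, plus small constructors for synthetic ensembles.

# adjacency list of an igraph
oracle_adj <- function(g) {
  n <- igraph::vcount(g)
  lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
}

# all-pairs BFS distances by hand
oracle_distances <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# local clustering coefficient by triangle enumeration
oracle_clustering <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  A <- matrix(FALSE, n, n)
  for (v in seq_len(n)) A[v, adj[[v]]] <- TRUE
  sapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    d <- length(nb)
    if (d < 2) return(0)
    t <- 0
    for (a in seq_len(d - 1)) {
      for (b in (a + 1):d) {
        if (A[nb[a], nb[b]]) t <- t + 1
      }
    }
    2 * t / (d * (d - 1))
  })
}

# enumerate every shortest path between each unordered pair; accumulate
# node betweenness (endpoints excluded) and edge betweenness
oracle_betweenness <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  D <- oracle_distances(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  ekey <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  node_b <- rep(0, n)
  edge_b <- rep(0, nrow(ends))
  paths_between <- function(s, t) {
    # all geodesics s -> t via backward recursion on the BFS DAG
    if (s == t) return(list(s))
    res <- list()
    for (w in adj[[t]]) {
      if (D[s, w] == D[s, t] - 1) {
        for (p in paths_between(s, w)) res[[length(res) + 1]] <- c(p, t)
      }
    }
    res
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      npath <- length(ps)
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        node_b[inner] <- node_b[inner] + 1 / npath
        if (length(p) > 1) {
          for (k in seq_len(length(p) - 1)) {
            ei <- match(paste(min(p[k], p[k + 1]), max(p[k], p[k + 1])), ekey)
            edge_b[ei] <- edge_b[ei] + 1 / npath
          }
        }
      }
    }
  }
  list(node = node_b, edge = edge_b)
}

# community-dependent quantities for one partition, straight from the
# definitions, one node at a time
oracle_community_features <- function(g, m) {
  adj <- oracle_adj(g)
  n <- length(adj)
  t(sapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    e_in <- sum(m[nb] == m[v])
    e_out <- sum(m[nb] != m[v])
    w <- sum(m == m[v]) - 1
    mates <- setdiff(which(m == m[v]), v)
    c_i <- sum(sapply(mates, function(j) {
      any(m[intersect(nb, adj[[j]])] == m[v])
    }))
    c(e_in = e_in, e_out = e_out,
      e_in_over_e_out = e_in / max(e_out, 1),
      odf = e_out / length(nb),
      expansion = e_out / max(w, 1),
      cut_ratio = e_out / (n - w),
      conductance = e_out / (length(nb) + e_in),
      triangle_participation = c_i / max(w, 1))
  }))
}

# wrap a membership matrix (nodes x runs) as a cd_ensemble
make_ensemble <- function(memberships, algorithm = "louvain", base_seed = 0L) {
  structure(
    list(memberships = as.matrix(memberships), algorithm = algorithm,
         n_runs = ncol(as.matrix(memberships)), base_seed = base_seed),
    class = "cd_ensemble"
  )
}

# exhaustive 1-D two-cluster search: best threshold split by direct WSS
oracle_best_split_wss <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (i in 1:(n - 1)) {
    left <- xs[1:i]
    right <- xs[(i + 1):n]
    wss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (wss < best) best <- wss
  }
  best
}
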