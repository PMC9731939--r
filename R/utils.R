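# Internal helpers shared across modules.

# Evaluate `code` with R's RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded package functions never disturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# integer seed derived deterministically from a base seed and stream index,
# kept well below .Machine$integer.max
derive_seed <- function(seed, index) {
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_graph <- function(graph, connected = FALSE) {
  if (!igraph::is_igraph(graph)) {
    abort("`graph` must be an igraph object")
  }
  if (igraph::is_directed(graph)) {
    abort("`graph` must be undirected")
  }
  if (any(igraph::which_loop(graph)) || any(igraph::which_multiple(graph))) {
    abort("`graph` must be simple (no self-loops or parallel edges)")
  }
  if (connected && !igraph::is_connected(graph)) {
    abort("`graph` must be connected")
  }
  invisible(graph)
}

# all unordered node pairs i < j of a graph with n nodes
all_node_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  tibble(i = i, j = j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
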