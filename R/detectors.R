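# Stochastic community-finding runs. Three algorithms are supported:
# Infomap (two-level map equation, via igraph), Louvain (multilevel
# modularity, in-package implementation of the reference algorithm) and
# asynchronous label propagation (in-package). Labels returned by a run
# are run-local: they carry no meaning across runs, and all downstream
# consumers are invariant to relabelling.

cd_algorithms <- c("infomap", "louvain", "lpa")

as_cd_igraph <- function(graph) {
  if (inherits(graph, "cd_graph")) graph$graph else graph
}

#' Run a community-finding algorithm once
#'
#' @param graph An igraph object or a `cd_graph`; must be connected and
#'   simple.
#' @param algorithm One of `"infomap"`, `"louvain"`, `"lpa"`.
#' @param seed Integer seed for this single run.
#' @param resolution Louvain resolution parameter (default 1, the standard
#'   modularity objective). Ignored by the other algorithms.
#' @return An integer membership vector (one community label per node,
#'   labels `1..k` in order of first appearance).
#' @export
run_once <- function(graph, algorithm = cd_algorithms, seed = 1L,
                     resolution = 1) {
  algorithm <- match.arg(algorithm, cd_algorithms)
  g <- as_cd_igraph(graph)
  assert_graph(g, connected = TRUE)
  n <- igraph::vcount(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  m <- switch(algorithm,
    infomap = with_seed(seed, {
      as.integer(igraph::membership(igraph::cluster_infomap(g, nb.trials = 1)))
    }),
    louvain = louvain_cpp(n, ends[, 1] - 1L, ends[, 2] - 1L,
                          rep(1, nrow(ends)), resolution, as.double(seed)),
    lpa = lpa_cpp(n, ends[, 1] - 1L, ends[, 2] - 1L, as.double(seed),
                  max_sweeps = 1000L)
  )
  # canonical labels: 1..k in order of first appearance
  as.integer(match(m, unique(m)))
}

#' Run an ensemble of algorithm runs
#'
#' Executes `n_runs` seeded runs (seeds `base_seed + 1, ..., base_seed +
#' n_runs`), the raw material for coassociation matrices and
#' community-dependent features.
#'
#' @inheritParams run_once
#' @param n_runs Number of runs (>= 1).
#' @param base_seed Integer; run `r` uses seed `base_seed + r`.
#' @return A `cd_ensemble`: list with `memberships` (nodes x runs integer
#'   matrix), `algorithm`, `n_runs`, `base_seed`.
#' @export
run_ensemble <- function(graph, algorithm = cd_algorithms, n_runs = 1000L,
                         base_seed = 0L, resolution = 1) {
  algorithm <- match.arg(algorithm, cd_algorithms)
  assert_scalar_number(n_runs, "n_runs", lower = 1)
  g <- as_cd_igraph(graph)
  assert_graph(g, connected = TRUE)
  memberships <- vapply(
    seq_len(n_runs),
    function(r) run_once(g, algorithm, seed = base_seed + r, resolution),
    integer(igraph::vcount(g))
  )
  structure(
    list(memberships = memberships, algorithm = algorithm,
         n_runs = as.integer(n_runs), base_seed = as.integer(base_seed)),
    class = "cd_ensemble"
  )
}

#' @export
print.cd_ensemble <- function(x, ...) {
  cat(sprintf("<cd_ensemble> %s: %d runs on %d nodes (base seed %d)\n",
              x$algorithm, x$n_runs, nrow(x$memberships), x$base_seed))
  invisible(x)
}

#' Fraction of degenerate runs in an ensemble
#'
#' A run is degenerate when its largest community holds more than half of
#' all nodes, the signature of an algorithm failing to detect structure
#' (e.g. label propagation at high mixing). Experiment cells whose graphs
#' are mostly degenerate are excluded from the grid.
#'
#' @param ensemble A `cd_ensemble`.
#' @return Fraction of runs in `[0, 1]`.
#' @export
degenerate_fraction <- function(ensemble) {
  stopifnot(inherits(ensemble, "cd_ensemble"))
  n <- nrow(ensemble$memberships)
  mean(apply(ensemble$memberships, 2, function(m) max(tabulate(m)) > n / 2))
}

#' Write / read an ensemble as CSV plus metadata JSON
#'
#' Rows are nodes, columns are runs, cells are run-local community labels.
#' Metadata (algorithm, run count, base seed, graph hash) is stored next to
#' the CSV in a `.json` file of the same stem.
#'
#' @param ensemble A `cd_ensemble`.
#' @param path CSV file path.
#' @param graph Optional graph the ensemble came from, recorded as a hash.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, graph = NULL) {
  stopifnot(inherits(ensemble, "cd_ensemble"))
  df <- as.data.frame(ensemble$memberships)
  names(df) <- paste0("run", seq_len(ensemble$n_runs))
  write.csv(df, path, row.names = FALSE)
  meta <- list(algorithm = ensemble$algorithm, n_runs = ensemble$n_runs,
               base_seed = ensemble$base_seed,
               graph_hash = if (!is.null(graph)) graph_hash(graph))
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(sub("\\.csv$", "", path), ".json")
  meta <- jsonlite::read_json(meta_path)
  structure(
    list(memberships = as.matrix(df), algorithm = meta$algorithm,
         n_runs = as.integer(meta$n_runs),
         base_seed = as.integer(meta$base_seed)),
    class = "cd_ensemble"
  )
}

# order-invariant hash of an undirected graph's edge set
graph_hash <- function(graph) {
  g <- as_cd_igraph(graph)
  ends <- igraph::as_edgelist(g, names = FALSE)
  key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]), sep = "-")
  paste0(igraph::vcount(g), ":", sum(as.double(utf8ToInt(paste(sort(key), collapse = ",")))))
}
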