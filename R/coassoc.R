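# Coassociation analysis of a run ensemble: co-membership frequencies,
# per-node entropy, the two binary labelings (easy/hard nodes,
# same/different pairs) and their undersampled training subsets.

#' Build the coassociation matrix of an ensemble
#'
#' Entry (i, j) is the fraction of runs in which nodes i and j share a
#' community label: `C_ij = r_ij / R`. The matrix is symmetric with unit
#' diagonal, and is invariant to relabelling communities within any run.
#'
#' @param ensemble A `cd_ensemble`.
#' @return A `cd_coassoc`: list with `C` (dense symmetric matrix) and
#'   `n_runs`.
#' @export
build_coassociation <- function(ensemble) {
  stopifnot(inherits(ensemble, "cd_ensemble"))
  M <- ensemble$memberships
  n <- nrow(M)
  R <- ncol(M)
  counts <- matrix(0L, n, n)
  for (r in seq_len(R)) {
    m <- M[, r]
    for (lab in unique(m)) {
      idx <- which(m == lab)
      if (length(idx) > 1L) counts[idx, idx] <- counts[idx, idx] + 1L
    }
  }
  diag(counts) <- R
  structure(list(C = counts / R, n_runs = R), class = "cd_coassoc")
}

#' @export
print.cd_coassoc <- function(x, ...) {
  cat(sprintf("<cd_coassoc> %d nodes over %d runs (mean off-diagonal C = %.3f)\n",
              nrow(x$C), x$n_runs,
              mean(x$C[upper.tri(x$C)])))
  invisible(x)
}

#' Per-node coassociation entropy
#'
#' For each node i, the mean over all nodes j of the per-pair entropy term
#' `p_ij = -C_ij log2(C_ij)` (0 when `C_ij <= 0`; the diagonal contributes
#' 0 since `C_ii = 1`): `E_i = sum_j p_ij / N`. Nodes that always co-occur
#' with the same companions have entropy 0; nodes that oscillate between
#' communities across runs have high entropy. Each term is maximised at
#' `C = 1/e` (value `log2(e)/e ~ 0.531`), which bounds `E_i`.
#'
#' @param coassoc A `cd_coassoc` (or a plain symmetric matrix in `[0,1]`).
#' @return A tibble with columns `node`, `entropy`.
#' @export
node_entropy <- function(coassoc) {
  C <- if (inherits(coassoc, "cd_coassoc")) coassoc$C else as.matrix(coassoc)
  n <- nrow(C)
  P <- matrix(0, n, n)
  nz <- C > 0
  P[nz] <- -C[nz] * log2(C[nz])
  tibble(node = seq_len(n), entropy = rowSums(P) / n)
}

# exact 1-D 2-means: scan all threshold splits of the sorted values and
# keep the one minimizing within-cluster sum of squares (optimal in 1-D,
# no initialization sensitivity)
kmeans2_threshold <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  css <- cumsum(xs^2)
  i <- seq_len(n - 1)
  wss_left <- css[i] - cs[i]^2 / i
  wss_right <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  best <- which.min(wss_left + wss_right)
  (xs[best] + xs[best + 1]) / 2
}

#' Label nodes easy/hard to cluster
#'
#' Two-cluster 1-D k-means on the entropy values; the cluster with the
#' lower centroid is "easy", the higher "hard". The 1-D problem is solved
#' exactly by scanning all threshold splits, so the result is deterministic;
#' `seed` is accepted for API symmetry only.
#'
#' @param entropies Tibble with columns `node`, `entropy` (from
#'   [node_entropy()]).
#' @param seed Unused; retained for interface stability.
#' @return A tibble `node`, `entropy`, `label` (factor easy/hard) with the
#'   split threshold in attribute `"threshold"`.
#' @export
label_easy_hard <- function(entropies, seed = NULL) {
  x <- entropies$entropy
  if (length(unique(x)) < 2L) {
    abort("all entropies identical: no easy/hard split exists (degenerate labeling)")
  }
  thr <- kmeans2_threshold(x)
  out <- dplyr::mutate(
    entropies,
    label = factor(ifelse(.data$entropy > thr, "hard", "easy"),
                   levels = c("easy", "hard"))
  )
  attr(out, "threshold") <- thr
  out
}

#' Strategic undersampling of easy nodes
#'
#' Keeps every hard node, and only the lowest-entropy easy nodes, until the
#' number of hard nodes is 75% of the number of kept easy nodes (the
#' retained easy count is `ceiling(n_hard / 0.75)`). If the easy class is
#' already at or below that size, all easy nodes are kept. Entropy ties at
#' the cutoff are broken by node identifier.
#'
#' @param labels Output of [label_easy_hard()].
#' @param ratio Target hard/easy ratio (default 0.75).
#' @return `labels` with a logical `selected` column marking the training
#'   subset.
#' @export
strategic_undersample <- function(labels, ratio = 0.75) {
  n_hard <- sum(labels$label == "hard")
  n_easy <- sum(labels$label == "easy")
  if (n_hard == 0L || n_easy == 0L) {
    abort("both classes must be nonempty (degenerate labeling)")
  }
  keep_easy <- min(n_easy, ceiling(n_hard / ratio))
  easy_idx <- which(labels$label == "easy")
  ord <- easy_idx[order(labels$entropy[easy_idx], labels$node[easy_idx])]
  selected <- rep(FALSE, nrow(labels))
  selected[labels$label == "hard"] <- TRUE
  selected[ord[seq_len(keep_easy)]] <- TRUE
  dplyr::mutate(labels, selected = selected)
}

#' Label node pairs same/different community
#'
#' Pair (i, j), i < j, is labelled "same" when `C_ij >= 0.5` (the boundary
#' case `C_ij = 0.5` is deliberately labelled "same") and "different"
#' otherwise.
#'
#' @param coassoc A `cd_coassoc`.
#' @return A tibble `i`, `j`, `cij`, `label` over all unordered pairs.
#' @export
label_pairs <- function(coassoc) {
  C <- if (inherits(coassoc, "cd_coassoc")) coassoc$C else as.matrix(coassoc)
  pairs <- all_node_pairs(nrow(C))
  cij <- C[cbind(pairs$i, pairs$j)]
  dplyr::mutate(pairs, cij = cij,
                label = factor(ifelse(cij >= 0.5, "same", "different"),
                               levels = c("different", "same")))
}

#' Balanced random undersampling of labelled pairs
#'
#' Uniform sample without replacement of `n_per_class` pairs from each
#' class; when one class is smaller than `n_per_class`, both classes are
#' sampled at the smaller size to preserve balance.
#'
#' @param pair_labels Output of [label_pairs()].
#' @param n_per_class Target training examples per class.
#' @param seed Integer seed.
#' @return `pair_labels` with a logical `selected` column.
#' @export
undersample_pairs <- function(pair_labels, n_per_class = 1000L, seed = 1L) {
  idx_same <- which(pair_labels$label == "same")
  idx_diff <- which(pair_labels$label == "different")
  if (length(idx_same) == 0L || length(idx_diff) == 0L) {
    abort("both pair classes must be nonempty (degenerate labeling)")
  }
  take <- min(n_per_class, length(idx_same), length(idx_diff))
  selected <- rep(FALSE, nrow(pair_labels))
  with_seed(seed, {
    selected[sample(idx_same, take)] <- TRUE
    selected[sample(idx_diff, take)] <- TRUE
  })
  dplyr::mutate(pair_labels, selected = selected)
}
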