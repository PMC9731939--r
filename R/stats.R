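# Statistical methodology: power analysis for the number of graphs,
# normality screening, pairwise Wilcoxon signed-rank comparisons of
# feature-importance distributions with Bonferroni-Holm correction,
# normalized mutual information between partitions, and the summary
# tables of the experiment grid.

#' Required number of graphs from a power analysis
#'
#' Smallest sample size n such that a two-sided one-sample (paired) t-test
#' at significance level `alpha` attains the requested `power` against a
#' standardized (Cohen's d) effect `d`, solved iteratively over the
#' noncentral t distribution. With the conventional d = 0.3, alpha = 0.05,
#' power = 0.9 this gives n = 119.
#'
#' @param d Cohen's effect size (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power (> alpha).
#' @return Integer sample size.
#' @export
required_sample_size <- function(d = 0.3, alpha = 0.05, power = 0.9) {
  assert_scalar_number(d, "d")
  if (d <= 0) abort("`d` must be positive")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  assert_scalar_number(power, "power", lower = 0, upper = 1)
  if (power <= alpha) abort("unattainable: `power` must exceed `alpha`")
  power_at <- function(n) {
    q <- qt(1 - alpha / 2, df = n - 1)
    ncp <- d * sqrt(n)
    pt(q, df = n - 1, ncp = ncp, lower.tail = FALSE) +
      pt(-q, df = n - 1, ncp = ncp)
  }
  n <- 2L
  while (power_at(n) < power) {
    n <- n + 1L
    if (n > 1e7) abort("sample size solve did not converge")
  }
  n
}

#' Shapiro-Wilk screening of importance distributions
#'
#' One Shapiro-Wilk test per feature over its per-graph importance values.
#' Constant vectors are undefined for the test and flagged degenerate
#' (counted as not normal).
#'
#' @param distributions Long tibble `feature`, `importance` (e.g. from
#'   [collect_distributions()]).
#' @param alpha Normality threshold on the p-value.
#' @return Tibble `feature`, `n`, `p_value`, `degenerate`, `normal`; the
#'   fraction of normal features is in attribute `"fraction_normal"`.
#' @export
shapiro_suite <- function(distributions, alpha = 0.05) {
  out <- distributions |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n = dplyr::n(),
      degenerate = var(.data$importance) == 0,
      p_value = if (var(.data$importance) == 0) NA_real_ else
        shapiro.test(.data$importance)$p.value,
      .groups = "drop"
    ) |>
    dplyr::mutate(normal = !.data$degenerate & .data$p_value > alpha) |>
    dplyr::select("feature", "n", "p_value", "degenerate", "normal")
  attr(out, "fraction_normal") <- mean(out$normal)
  out
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Two-sided paired test on `x - y`. Zero differences are included when
#' ranking the absolute differences and then dropped from the signed sums
#' (Pratt's method). The exact conditional sign-flip distribution is used
#' for up to 25 nonzero differences (ties handled by the conditional
#' distribution over doubled midranks); beyond that, the normal
#' approximation with tie-corrected variance and continuity correction.
#' All-zero differences give p = 1 by convention.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest number of nonzero differences for which the
#'   exact distribution is enumerated.
#' @return List with `statistic` (sum of positive-difference ranks),
#'   `p_value`, `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 1L) abort("need at least one pair")
  rk <- rank(abs(d))
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "all differences zero"))
  }
  r <- rk[nz]
  w_pos <- sum(r[d[nz] > 0])
  n_nz <- sum(nz)
  if (n_nz <= exact_max) {
    # conditional sign-flip distribution of W+ over the observed ranks;
    # double the (mid)ranks so sums are integers even under ties
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dp <- numeric(total + 1)
    dp[1] <- 1
    for (ri in r2) {
      dp[(ri + 1):(total + 1)] <- dp[(ri + 1):(total + 1)] + dp[1:(total + 1 - ri)]
    }
    dp <- dp / sum(dp)
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(dp[1:(w2 + 1)])
    p_ge <- sum(dp[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (Pratt)"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (Pratt)"
  }
  list(statistic = w_pos, p_value = p, n_nonzero = n_nz, method = method)
}

#' Pairwise Wilcoxon comparisons with Bonferroni-Holm correction
#'
#' For every unordered pair of features, a two-sided Wilcoxon signed-rank
#' test on the per-graph paired differences of importances; Holm step-down
#' correction over all pairs jointly; significance flags at `alpha` on the
#' adjusted p-values; effect direction from the sign of the mean paired
#' difference.
#'
#' @param distributions Long tibble `graph`, `feature`, `importance`, all
#'   features observed on the same graphs.
#' @param alpha Family-wise significance level.
#' @return A `cd_statreport` tibble: `feature_a`, `feature_b`, `p_raw`,
#'   `p_holm`, `significant`, `direction` (name of the larger-importance
#'   feature, or `"none"`).
#' @export
pairwise_wilcoxon_holm <- function(distributions, alpha = 0.05) {
  wide <- tidyr::pivot_wider(distributions,
                             id_cols = "graph",
                             names_from = "feature",
                             values_from = "importance")
  feats <- setdiff(names(wide), "graph")
  if (anyNA(wide)) abort("every feature must be observed on every graph")
  if (nrow(wide) < 6) abort("need at least 6 paired observations per feature")
  combos <- utils::combn(feats, 2)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    ts <- wilcoxon_signed_rank(wide[[a]], wide[[b]])
    delta <- mean(wide[[a]] - wide[[b]])
    tibble(
      feature_a = a, feature_b = b, p_raw = ts$p_value,
      direction = if (delta > 0) a else if (delta < 0) b else "none"
    )
  })
  res <- dplyr::mutate(res,
                       p_holm = p.adjust(.data$p_raw, method = "holm"),
                       significant = .data$p_holm < alpha)
  out <- dplyr::select(res, "feature_a", "feature_b", "p_raw", "p_holm",
                       "significant", "direction")
  class(out) <- c("cd_statreport", class(out))
  out
}

#' Normalized mutual information between two partitions
#'
#' Label-permutation-invariant similarity in `[0, 1]`; 1 iff the partitions
#' are identical up to relabelling. The default normalization divides the
#' mutual information by the arithmetic mean of the marginal entropies;
#' min, max and geometric-mean normalizations are available.
#'
#' @param p,q Integer membership vectors over the same node set.
#' @param normalization One of `"arithmetic"`, `"min"`, `"max"`,
#'   `"geometric"`.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(p, q, normalization = c("arithmetic", "min", "max", "geometric")) {
  normalization <- match.arg(normalization)
  if (length(p) != length(q)) abort("partitions must cover the same node set")
  n <- length(p)
  joint <- table(p, q) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nzj <- joint > 0
  mi <- sum(joint[nzj] * log(joint[nzj] / outer(px, py)[nzj]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  denom <- switch(normalization,
    arithmetic = (hx + hy) / 2,
    min = min(hx, hy),
    max = max(hx, hy),
    geometric = sqrt(hx * hy)
  )
  if (denom == 0) {
    # both partitions trivial: identical iff both are the single community
    return(if (hx == 0 && hy == 0) 1 else 0)
  }
  if (mi <= 0) return(0)
  min(1, mi / denom)
}

#' Summary tables over a set of graphs
#'
#' Three summaries in the style of the experiment grid's reporting:
#' community counts per run (mean over runs per graph, then mean / median /
#' sd across graphs), NMI between uniformly sampled partition pairs of two
#' algorithms' ensembles (pooled over graphs), and the proportion of nodes
#' labelled hard to cluster (across graphs).
#'
#' @param ensembles List of `cd_ensemble` (one per graph).
#' @return `summarize_communities`: tibble `mean`, `median`, `sd` plus the
#'   per-graph means in attribute `"per_graph"`.
#' @export
summarize_communities <- function(ensembles) {
  per_graph <- purrr::map_dbl(ensembles, function(e) {
    mean(apply(e$memberships, 2, function(m) length(unique(m))))
  })
  out <- tibble(mean = mean(per_graph), median = median(per_graph),
                sd = sd(per_graph))
  attr(out, "per_graph") <- per_graph
  out
}

#' @rdname summarize_communities
#' @param ensembles_a,ensembles_b Per-graph ensembles of two algorithms on
#'   the same graphs.
#' @param n_pairs Partition pairs sampled uniformly (with replacement) per
#'   graph.
#' @param seed Integer seed.
#' @export
summarize_nmi <- function(ensembles_a, ensembles_b, n_pairs = 1000L, seed = 1L) {
  stopifnot(length(ensembles_a) == length(ensembles_b))
  vals <- with_seed(seed, {
    purrr::map2(ensembles_a, ensembles_b, function(ea, eb) {
      ra <- sample.int(ea$n_runs, n_pairs, replace = TRUE)
      rb <- sample.int(eb$n_runs, n_pairs, replace = TRUE)
      vapply(seq_len(n_pairs), function(k) {
        nmi(ea$memberships[, ra[k]], eb$memberships[, rb[k]])
      }, numeric(1))
    })
  })
  pooled <- unlist(vals)
  out <- tibble(mean = mean(pooled), median = median(pooled), sd = sd(pooled))
  attr(out, "per_graph") <- purrr::map_dbl(vals, mean)
  out
}

#' @rdname summarize_communities
#' @param labelings List of easy/hard labelling tibbles (one per graph,
#'   from [label_easy_hard()]).
#' @export
summarize_hard_nodes <- function(labelings) {
  per_graph <- purrr::map_dbl(labelings, function(l) mean(l$label == "hard"))
  out <- tibble(mean = mean(per_graph), median = median(per_graph),
                sd = sd(per_graph))
  attr(out, "per_graph") <- per_graph
  out
}
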