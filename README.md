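# cdexplain

Post-hoc explanation of **stochastic community-finding algorithms** with
interpretable graph features.

Algorithms like Infomap, Louvain and label propagation return different
partitions on different runs. Some nodes always land in the same community
(a stable core); others oscillate. `cdexplain` quantifies this behaviour
and explains it: which human-readable network metrics — clustering
coefficient, centralities, boundary measures, neighbourhood similarities —
predict whether a node is *easy or hard to cluster*, and whether a pair of
nodes ends up in the *same or different communities*? The package is aimed
at network scientists and computational social scientists who want to
reason about community-detection output in the vocabulary of social
network analysis rather than in terms of an opaque optimizer.

## The method

For a graph and an algorithm, collect `R` seeded runs and form the
coassociation matrix `C_ij = r_ij / R` (fraction of runs in which nodes
`i`, `j` co-occur). Each node gets an instability score

    E_i = (1/N) * sum_j p_ij,   p_ij = -C_ij log2 C_ij  (0 if C_ij <= 0)

and exact 1-D 2-means on the `E_i` splits nodes into *easy* / *hard to
cluster* classes (pairs are labelled *same* / *different community* by
`C_ij` vs 0.5). After class balancing — keep all hard nodes plus the
lowest-entropy easy nodes until hard = 75% of easy; sample 1000 pairs per
class — a 100-tree random forest is trained under 10×5-fold stratified
cross-validation, and every feature's **permutation importance** (held-out
accuracy drop over 5 shuffles, averaged over the 50 fits) is recorded.
Importances collected across many graphs are screened with Shapiro–Wilk
tests and compared by pairwise Wilcoxon signed-rank tests (Pratt zero
handling, exact up to n = 25) with Bonferroni–Holm correction; a
noncentral-t power analysis sizes the graph sample (119 graphs at
d = 0.3, alpha = 0.05, power = 0.9).

Experiments run on LFR-style benchmark graphs generated in-package (1000
nodes, degree exponent 3, community-size exponent 2, average degree 20,
maximum degree 50, mixing parameter mu in {0.2, 0.3, 0.4}), emulating the
widely used reference construction — see the vignette for its realized
degree/mixing behaviour. Louvain and asynchronous LPA are implemented
in-package (Rcpp) for cross-platform determinism and fidelity to the
reference implementations; Infomap comes from igraph.

## Worked example

```r
library(cdexplain)

g   <- generate_lfr(lfr_config(n = 300, mu = 0.3, seed = 1))
ens <- run_ensemble(g, "louvain", n_runs = 100, base_seed = 1)
res <- explain_nodes(g, ens, classifier_config(seed = 1))

tidy(res$importance)
#> # A tibble: 14 × 2
#>   feature                importance
#>   <chr>                       <dbl>
#> 1 triangle_participation    0.222
#> 2 expansion                 0.0556
#> 3 e_out                     0.0155
#> 4 cut_ratio                 0.00756
#> 5 clustering_coefficient    0.00472
#> # ...

glance(res$importance)
#> # A tibble: 1 × 4
#>   n_evaluations n_features mean_accuracy top_feature
#>           <int>      <int>         <dbl> <chr>
#> 1            50         14         0.798 triangle_participation
```

Reading: on this 300-node benchmark graph at mu = 0.3, the forest predicts
easy-vs-hard with ~0.80 held-out accuracy, and shuffling *triangle
participation* costs it 22 accuracy points — nodes embedded in
within-community triangles are the stable ones, while boundary measures
(expansion, `E_out`) carry most of the remaining signal. `autoplot()`
methods display importances and coassociation heatmaps;
`plot_importance_distributions()` shows the across-graph distributions.

The full grid (mu × algorithm × node/pair) is one call:

```r
res <- run_grid(experiment_config(preset = "desk", seed = 1))
res$summaries$communities   # community counts per (algorithm, mu)
res$summaries$nmi           # between-algorithm NMI
res$summaries$hard_nodes    # hard-to-cluster proportions
```

`experiment_config(preset = "paper")` is the full-scale configuration
(120 graphs per mu, 1000 runs per graph). A thin command-line wrapper
lives in `inst/scripts/run_grid.R`.

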