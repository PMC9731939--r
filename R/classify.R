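# Random-forest classification of the labelled feature tables and
# permutation feature importance, evaluated on held-out folds of a
# repeated stratified cross-validation.

#' Classifier configuration
#'
#' @param n_trees Trees per forest (default 100).
#' @param n_folds Cross-validation folds (default 5).
#' @param n_repeats Cross-validation repeats with reshuffled folds
#'   (default 10), giving `n_folds * n_repeats` importance evaluations.
#' @param n_permutations Shuffles per feature per evaluation when measuring
#'   the held-out accuracy drop (default 5).
#' @param seed Integer seed governing fold shuffles, forest fitting and
#'   permutations.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_trees = 100L, n_folds = 5L, n_repeats = 10L,
                              n_permutations = 5L, seed = 1L) {
  assert_scalar_number(n_trees, "n_trees", lower = 1)
  assert_scalar_number(n_folds, "n_folds", lower = 2)
  assert_scalar_number(n_repeats, "n_repeats", lower = 1)
  assert_scalar_number(n_permutations, "n_permutations", lower = 1)
  structure(
    list(n_trees = as.integer(n_trees), n_folds = as.integer(n_folds),
         n_repeats = as.integer(n_repeats),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin, so class balance is preserved per fold
stratified_folds <- function(label, n_folds) {
  fold <- integer(length(label))
  for (cl in levels(label)) {
    idx <- sample(which(label == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Train a random forest and compute permutation importances
#'
#' Runs `n_repeats` stratified `n_folds`-fold cross-validations. For each
#' of the `n_folds * n_repeats` evaluations a forest is fitted on the
#' training folds, and every feature's permutation importance on the
#' held-out fold is the mean drop in accuracy over `n_permutations`
#' shuffles of that feature column. The final score per feature is the
#' mean over all evaluations; negative scores are reported as computed.
#'
#' @param table A `cd_feature_table` from [assemble_feature_table()] (or
#'   any data frame with feature columns and a two-level `label` column).
#' @param config A [classifier_config()].
#' @param features Character vector of feature column names; defaults to
#'   the table's `"features"` attribute.
#' @return A `cd_importance`: `importance` tibble (feature, mean
#'   importance), `raw` evaluations x features matrix, held-out
#'   `accuracy` per evaluation, `config`.
#' @export
train_and_importances <- function(table, config = classifier_config(),
                                  features = NULL) {
  features <- features %||% attr(table, "features")
  if (is.null(features)) {
    abort("`features` not given and `table` has no \"features\" attribute")
  }
  label <- factor(table$label)
  if (nlevels(label) != 2L) abort("`label` must have exactly two classes")
  if (min(table(label)) < config$n_folds) {
    abort("each class needs at least `n_folds` rows")
  }
  X <- as.data.frame(table[, features, drop = FALSE])
  n <- nrow(X)
  p <- length(features)
  n_eval <- config$n_folds * config$n_repeats
  raw <- matrix(NA_real_, n_eval, p, dimnames = list(NULL, features))
  accuracy <- numeric(n_eval)

  with_seed(config$seed, {
    eval_i <- 0L
    for (rep_i in seq_len(config$n_repeats)) {
      fold <- stratified_folds(label, config$n_folds)
      for (f in seq_len(config$n_folds)) {
        test <- fold == f
        fit <- ranger::ranger(
          x = X[!test, , drop = FALSE], y = label[!test],
          num.trees = config$n_trees, num.threads = 1L,
          seed = derive_seed(config$seed, eval_i + 1L),
          verbose = FALSE
        )
        Xte <- X[test, , drop = FALSE]
        yte <- label[test]
        base_acc <- mean(predict(fit, Xte, num.threads = 1L)$predictions == yte)
        # one stacked prediction over all feature x shuffle blocks
        n_te <- nrow(Xte)
        blocks <- vector("list", p * config$n_permutations)
        b <- 0L
        for (k in seq_len(p)) {
          for (s in seq_len(config$n_permutations)) {
            Xp <- Xte
            Xp[[k]] <- Xp[[k]][sample.int(n_te)]
            b <- b + 1L
            blocks[[b]] <- Xp
          }
        }
        big <- do.call(rbind, blocks)
        pred <- predict(fit, big, num.threads = 1L)$predictions
        acc_block <- colMeans(matrix(pred == rep(yte, times = b), nrow = n_te))
        drop_by_feature <- colMeans(matrix(base_acc - acc_block,
                                           nrow = config$n_permutations))
        eval_i <- eval_i + 1L
        raw[eval_i, ] <- drop_by_feature
        accuracy[eval_i] <- base_acc
      }
    }
  })

  structure(
    list(
      importance = tibble(feature = features,
                          importance = unname(colMeans(raw))),
      raw = raw,
      accuracy = accuracy,
      config = config
    ),
    class = "cd_importance"
  )
}

#' @export
print.cd_importance <- function(x, ...) {
  cat(sprintf("<cd_importance> %d features, %d evaluations, mean held-out accuracy %.3f\n",
              nrow(x$importance), nrow(x$raw), mean(x$accuracy)))
  top <- dplyr::arrange(x$importance, dplyr::desc(.data$importance))
  print(head(top, 5))
  invisible(x)
}

#' @rdname train_and_importances
#' @param x A `cd_importance`.
#' @param ... Unused.
#' @export
tidy.cd_importance <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$importance))
}

#' @rdname train_and_importances
#' @export
glance.cd_importance <- function(x, ...) {
  tibble(
    n_evaluations = nrow(x$raw),
    n_features = nrow(x$importance),
    mean_accuracy = mean(x$accuracy),
    top_feature = x$importance$feature[which.max(x$importance$importance)]
  )
}

#' Collect per-graph importance distributions
#'
#' Stacks the mean importances of several graphs' [train_and_importances()]
#' results into one long tibble, the unit of analysis for the statistics
#' module.
#'
#' @param results List of `cd_importance` objects (one per graph).
#' @param graph_ids Optional identifiers; defaults to list names or index.
#' @return A tibble `graph`, `feature`, `importance`.
#' @export
collect_distributions <- function(results, graph_ids = NULL) {
  stopifnot(length(results) > 0)
  feats <- results[[1]]$importance$feature
  for (r in results) {
    if (!identical(r$importance$feature, feats)) {
      abort("all results must share an identical feature set")
    }
  }
  ids <- graph_ids %||% names(results) %||% seq_along(results)
  purrr::map2_dfr(results, ids, function(r, id) {
    dplyr::mutate(r$importance, graph = id, .before = 1)
  })
}
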