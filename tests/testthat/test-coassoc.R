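test_that("coassociation entries are co-membership frequencies", {
  # nodes 1,2 together in 3 of 4 runs
  M <- cbind(c(1L, 1L, 2L), c(1L, 1L, 2L), c(1L, 1L, 1L), c(1L, 2L, 2L))
  C <- build_coassociation(make_ensemble(M))
  expect_equal(C$C[1, 2], 0.75)
  expect_equal(C$C, t(C$C))
  expect_equal(diag(C$C), rep(1, 3))
  expect_true(all(C$C * C$n_runs == round(C$C * C$n_runs)))  # counts
})

test_that("coassociation is invariant to run-local relabelling", {
  b <- fixture_barbell(5)
  e <- run_ensemble(b, "louvain", n_runs = 10, base_seed = 2)
  M2 <- e$memberships
  M2[, 4] <- max(M2[, 4]) + 1L - M2[, 4]  # bijective relabel of one run
  expect_equal(build_coassociation(make_ensemble(M2))$C,
               build_coassociation(e)$C)
})

test_that("identical partitions give a 0/1 matrix and zero entropy", {
  b <- fixture_barbell(5)
  M <- matrix(rep(b$ground_truth$label, 8), ncol = 8)
  C <- build_coassociation(make_ensemble(M))
  expect_true(all(C$C %in% c(0, 1)))
  expect_equal(node_entropy(C)$entropy, rep(0, 10))
})

test_that("node entropy matches the hand-computed example", {
  C <- rbind(c(1, 0.5, 0.5, 0),
             c(0.5, 1, 0, 0),
             c(0.5, 0, 1, 0),
             c(0, 0, 0, 1))
  E <- node_entropy(C)
  expect_equal(E$entropy[1], 0.25)  # (0 + 0.5 + 0.5 + 0) / 4
  # invariant under node reordering
  perm <- c(3, 1, 4, 2)
  E2 <- node_entropy(C[perm, perm])
  expect_equal(E2$entropy, E$entropy[perm])
  # entropies never exceed the per-term maximum log2(e)/e
  expect_true(all(E$entropy <= log2(exp(1)) / exp(1)))
})

test_that("entropy is zero iff co-membership is stable across runs", {
  b <- fixture_barbell(5)
  stable <- run_ensemble(b, "louvain", n_runs = 15, base_seed = 4)
  expect_true(all(node_entropy(build_coassociation(stable))$entropy == 0))
  M <- stable$memberships
  M[1, 7] <- 3L  # one deviating run breaks stability
  ent <- node_entropy(build_coassociation(make_ensemble(M)))$entropy
  expect_gt(max(ent), 0)
})

test_that("easy/hard split is the optimal 1-D two-means split", {
  lab <- label_easy_hard(tibble::tibble(node = 1:5,
                                        entropy = c(0, 0, 0, 0.4, 0.4)))
  expect_equal(as.character(lab$label), c("easy", "easy", "easy", "hard", "hard"))
  lab2 <- label_easy_hard(tibble::tibble(node = 1:4,
                                         entropy = c(0.1, 0.11, 0.12, 0.5)))
  expect_equal(which(lab2$label == "hard"), 4L)
  expect_error(label_easy_hard(tibble::tibble(node = 1:3, entropy = rep(0.2, 3))),
               "degenerate")
  # permutation of node order does not change per-node labels
  x <- c(0.05, 0.3, 0.01, 0.28, 0.02, 0.6)
  l1 <- label_easy_hard(tibble::tibble(node = 1:6, entropy = x))
  p <- c(4, 2, 6, 1, 3, 5)
  l2 <- label_easy_hard(tibble::tibble(node = 1:6, entropy = x[p]))
  expect_equal(as.character(l2$label), as.character(l1$label)[p])
})

test_that("threshold split minimises within-cluster sum of squares (property)", {
  set.seed(42)
  for (rep in 1:20) {
    x <- c(rnorm(30, 0, 0.05), rnorm(sample(2:20, 1), 0.4, 0.1))
    x <- pmax(x, 0)
    lab <- label_easy_hard(tibble::tibble(node = seq_along(x), entropy = x))
    thr <- attr(lab, "threshold")
    grp <- x > thr
    wss <- sum((x[!grp] - mean(x[!grp]))^2) + sum((x[grp] - mean(x[grp]))^2)
    expect_equal(wss, oracle_best_split_wss(x), tolerance = 1e-12)
  }
})

test_that("strategic undersampling hits the 75% ratio from above", {
  mk <- function(n_easy, n_hard) {
    tibble::tibble(node = seq_len(n_easy + n_hard),
                   entropy = c(seq(0, 0.1, length.out = n_easy),
                               seq(0.3, 0.4, length.out = n_hard)),
                   label = factor(rep(c("easy", "hard"), c(n_easy, n_hard)),
                                  levels = c("easy", "hard")))
  }
  s <- strategic_undersample(mk(100, 30))
  expect_equal(sum(s$selected & s$label == "easy"), 40)  # ceiling(30 / 0.75)
  expect_equal(sum(s$selected & s$label == "hard"), 30)
  # kept easy nodes are the lowest-entropy ones
  kept <- s$node[s$selected & s$label == "easy"]
  expect_equal(kept, 1:40)
  # small easy class: no oversampling, keep all
  s2 <- strategic_undersample(mk(10, 30))
  expect_equal(sum(s2$selected), 40)
  # ratio bound property over many shapes
  for (ne in c(37, 80, 211)) {
    for (nh in c(9, 33, 61)) {
      sk <- strategic_undersample(mk(ne, nh))
      easy_kept <- sum(sk$selected & sk$label == "easy")
      r <- nh / easy_kept
      if (easy_kept < ne) {
        # ceiling in the kept-easy count means the hard:easy ratio never
        # exceeds 0.75, and falls below by at most one node's worth
        expect_lte(r, 0.75 + 1e-12)
        expect_gte(r + 1e-12, 0.75 - 1 / nh)
      } else {
        # easy class already small enough: keep everything
        expect_equal(r, nh / ne)
        expect_gte(r + 1e-12, 0.75)
      }
    }
  }
})

test_that("undersampling ties at the cutoff break by node id", {
  lab <- tibble::tibble(node = 1:6,
                        entropy = c(0.1, 0.1, 0.1, 0.1, 0.5, 0.5),
                        label = factor(rep(c("easy", "hard"), c(4, 2)),
                                       levels = c("easy", "hard")))
  s <- strategic_undersample(lab)  # keeps ceiling(2/0.75) = 3 easy
  expect_equal(s$node[s$selected & s$label == "easy"], 1:3)
})

test_that("pair labels follow the coassociation majority rule", {
  C <- rbind(c(1, 0.5, 0.49),
             c(0.5, 1, 0.8),
             c(0.49, 0.8, 1))
  pl <- label_pairs(structure(list(C = C, n_runs = 100), class = "cd_coassoc"))
  get <- function(i, j) as.character(pl$label[pl$i == i & pl$j == j])
  expect_equal(get(1, 2), "same")       # exactly half -> same, by convention
  expect_equal(get(1, 3), "different")
  expect_equal(get(2, 3), "same")
  # an all-identical ensemble reproduces that partition's co-membership
  b <- fixture_barbell(4)
  M <- matrix(rep(b$ground_truth$label, 5), ncol = 5)
  pl2 <- label_pairs(build_coassociation(make_ensemble(M)))
  lab <- b$ground_truth$label
  expect_equal(pl2$label == "same", lab[pl2$i] == lab[pl2$j])
})

test_that("pair undersampling is balanced and seeded", {
  b <- fixture_barbell(5)
  M <- matrix(rep(b$ground_truth$label, 5), ncol = 5)
  pl <- label_pairs(build_coassociation(make_ensemble(M)))
  # 2 * C(5,2) = 20 same pairs; the remaining 25 (incl. the bridge) differ
  u <- undersample_pairs(pl, n_per_class = 10, seed = 5)
  expect_equal(sum(u$selected & u$label == "same"), 10)
  expect_equal(sum(u$selected & u$label == "different"), 10)
  # class smaller than the request: both classes at the smaller size
  u2 <- undersample_pairs(pl, n_per_class = 1000, seed = 5)
  expect_equal(sum(u2$selected & u2$label == "same"),
               sum(u2$selected & u2$label == "different"))
  expect_identical(undersample_pairs(pl, 10, seed = 9)$selected,
                   undersample_pairs(pl, 10, seed = 9)$selected)
})
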