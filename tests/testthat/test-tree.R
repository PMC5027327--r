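test_that("entropy matches the closed form on canonical count vectors", {
  expect_equal(entropy(c(8, 8)), 1.0)
  expect_equal(entropy(c(16, 0)), 0.0)
  expect_equal(entropy(c(4, 4, 4, 4)), 2.0)
  expect_equal(entropy(c(1, 3)), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_error(entropy(c(0, 0)), "all-zero")
  expect_error(entropy(c(-1, 2)), "negative")
})

test_that("gain ratio matches a hand computation and handles degenerate splits", {
  # perfect binary separation: gain 1 bit / split info 1 bit
  expect_equal(gain_ratio(c(5, 5), c(5, 0), c(0, 5)), 1.0)
  # empty side: defined as 0
  expect_equal(gain_ratio(c(5, 5), c(5, 5), c(0, 0)), 0)
  # parent [3,3] split into [2,1] and [1,2]: hand-enumerated over 6 instances
  h21 <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(gain_ratio(c(3, 3), c(2, 1), c(1, 2)), (1 - h21) / 1)
  expect_error(gain_ratio(c(3, 3), c(2, 1), c(2, 2)), "partition")
})

test_that("best_split finds the midpoint of a perfect split and rejects constants", {
  tab <- data.frame(x = c(0, 0, 1, 1), Class = c("a", "a", "b", "b"))
  s <- best_split(tab, "x")
  expect_equal(s$threshold, 0.5)
  expect_equal(s$gain_ratio, 1.0)
  expect_null(best_split(data.frame(x = rep(2, 6),
                                    Class = rep(c("a", "b"), 3)), "x"))
  expect_error(best_split(tab, "nope"), "unknown attribute")
  # min leaf constraint can forbid the only informative cut
  tab2 <- data.frame(x = c(0, 1, 1, 1), Class = c("a", "b", "b", "b"))
  expect_null(best_split(tab2, "x", min_leaf_count = 2))
})

test_that("split selection equals exhaustive midpoint enumeration", {
  set.seed(77)
  for (case in 1:30) {
    n <- sample(4:12, 1)
    tab <- data.frame(
      u = sample(0:3, n, replace = TRUE) / 3,
      v = round(runif(n), 2),
      w = sample(c(0.1, 0.4, 0.9), n, replace = TRUE),
      Class = sample(c("a", "b", "c"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    oracle <- oracle_best_split(tab)
    fast <- NULL
    for (a in c("u", "v", "w")) {
      s <- best_split(tab, a)
      if (!is.null(s) && (is.null(fast) || s$gain_ratio > fast$ratio + 1e-9))
        fast <- list(attribute = a, threshold = s$threshold,
                     ratio = s$gain_ratio)
    }
    expect_equal(is.null(fast), is.null(oracle))
    if (!is.null(oracle)) {
      expect_equal(fast$attribute, oracle$attribute)
      expect_equal(fast$threshold, oracle$threshold)
      expect_equal(fast$ratio, oracle$ratio, tolerance = 1e-10)
    }
  }
})

test_that("induction handles separable, pure and degenerate tables", {
  toy <- data.frame(Time = 1:4, x = c(0, 0, 1, 1),
                    Class = c("a", "a", "b", "b"), stringsAsFactors = FALSE)
  m <- induce_tree(toy, tree_params(0.1))
  expect_equal(n_leaves(m), 2)
  expect_equal(predict(m, toy), toy$Class)

  pure <- data.frame(Time = 1:5, x = rnorm(5), Class = rep("a", 5),
                     stringsAsFactors = FALSE)
  mp <- induce_tree(pure, tree_params(0.1))
  expect_equal(n_leaves(mp), 1)
  expect_equal(predict(mp, pure), rep("a", 5))

  expect_error(induce_tree(pure[0, ], tree_params(0.1)), "no instances")
})

test_that("unpruned trees with minimum leaf 1 resubstitute conflict-free data perfectly", {
  set.seed(101)
  for (case in 1:10) {
    n <- sample(8:20, 1)
    tab <- data.frame(Time = seq_len(n),
                      p = round(rnorm(n), 3), q = round(rnorm(n), 3),
                      Class = sample(c("a", "b", "c"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    m <- induce_tree(tab, tree_params(1e-6, pruning = FALSE))
    expect_equal(mean(predict(m, tab) == tab$Class), 1)
  }
})

test_that("pruning never adds leaves or training accuracy", {
  set.seed(202)
  for (case in 1:8) {
    n <- 40
    tab <- data.frame(Time = seq_len(n),
                      p = rnorm(n), q = rnorm(n),
                      Class = sample(c("a", "b"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    up <- induce_tree(tab, tree_params(0.02, pruning = FALSE))
    pr <- induce_tree(tab, tree_params(0.02, pruning = TRUE))
    expect_lte(n_leaves(pr), n_leaves(up))
    expect_lte(mean(predict(pr, tab) == tab$Class),
               mean(predict(up, tab) == tab$Class))
  }
})

test_that("raising the minimum leaf fraction never increases leaf count", {
  ft <- simulate_subject_features("sighted", seed = 13)
  leaves <- vapply(c(0.01, 0.05, 0.10), function(f)
    n_leaves(induce_tree(ft, tree_params(f))), numeric(1))
  expect_true(all(diff(leaves) <= 0))
})

test_that("ties break toward the earlier attribute column and lower threshold", {
  # x and y carry the identical perfect split; x comes first; Time is
  # uninformative because the classes alternate along it
  tab <- data.frame(Time = 1:4, x = c(0, 1, 0, 1), y = c(0, 1, 0, 1),
                    Class = c("a", "b", "a", "b"), stringsAsFactors = FALSE)
  m <- induce_tree(tab, tree_params(0.1, pruning = FALSE))
  expect_equal(m$root$attribute, "x")
  # two equally good thresholds: choose the lower one
  tab2 <- data.frame(x = c(0, 1, 2, 3), Class = c("a", "a", "b", "b"),
                     stringsAsFactors = FALSE)
  s <- best_split(tab2, "x")
  expect_equal(s$threshold, 1.5)
})

test_that("prediction requires every tested attribute and follows thresholds", {
  m <- example_tree()
  expect_equal(predict(m, data.frame(Time = 10, CP1 = 0.5)), "cube")
  expect_equal(predict(m, data.frame(Time = 20, CP1 = 0.05)), "interval")
  expect_equal(predict(m, data.frame(Time = 20, CP1 = 0.09)), "ball")
  expect_equal(predict(m, data.frame(Time = 40, CP1 = 0)), "parallelogram")
  expect_error(predict(m, data.frame(Time = 10)), "CP1")
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(tree_params(0), "min_leaf_fraction")
  expect_error(tree_params(1.2), "min_leaf_fraction")
  expect_error(tree_params(0.01, 0.7), "confidence_factor")
})
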