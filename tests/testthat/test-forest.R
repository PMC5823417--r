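test_that("bootstrap sampling is with replacement, seeded, with OOB complement", {
  bs1 <- bootstrap_sample(1, seed = 3)
  expect_equal(bs1$sample, 1)
  expect_length(bs1$oob, 0)

  d <- toy_dataset(n = 50)
  bs <- bootstrap_sample(d, seed = 9)
  expect_length(bs$sample, 50)
  expect_setequal(union(bs$sample, bs$oob), 1:50)
  expect_length(intersect(bs$sample, bs$oob), 0)
  expect_identical(bootstrap_sample(d, seed = 9)$sample, bs$sample)
  expect_false(identical(bootstrap_sample(d, seed = 10)$sample, bs$sample))
})

test_that("gini impurity matches closed forms", {
  expect_equal(gini_impurity(c(10, 0, 0, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(1, 1, 1, 1)), 0.75)
  expect_error(gini_impurity(c(0, 0)), "zero total")
})

test_that("a single-class sample grows a single pure leaf", {
  d <- hb_dataset(data.frame(a = 1:5, b = 5:1), rep("u", 5),
                  class_names = c("u", "v"))
  tr <- grow_tree(d, mtry = 1, variant = "cart", seed = 1)
  expect_true(tr$root$leaf)
  expect_equal(tr$root$counts, c(5L, 0L))
})

test_that("a perfectly separable 1-D problem yields a depth-1 CART tree", {
  d <- separable_1d()
  tr <- grow_tree(d, mtry = 1, variant = "cart", seed = 4)
  expect_false(tr$root$leaf)
  expect_equal(tr$root$attr, 1)           # column b cannot split
  expect_gt(tr$root$threshold, 2)
  expect_lt(tr$root$threshold, 8)
  expect_true(tr$root$left$leaf && tr$root$right$leaf)
  p <- tree_predict(tr, d)
  expect_equal(as.character(colnames(p)[max.col(p)]),
               as.character(d$y))
})

test_that("mtry must be below the attribute count", {
  d <- separable_1d()
  expect_error(grow_tree(d, mtry = 2, variant = "cart"), "mtry")
  expect_error(fit_forest(d, n_trees = 2, mtry = 5), "mtry")
})

test_that("full-depth CART trees are pure on their own sample absent contradictions", {
  for (s in 1:50) {
    cfg <- generator_config(n = 40, separability = 0.3,
                            cluster_alignment = 0.5, seed = s)
    d <- generate_dataset(cfg)
    tr <- grow_tree(d, mtry = 3, variant = "cart", seed = s)
    p <- tree_predict(tr, d)
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    expect_equal(mean(pred == as.character(d$y)), 1)
  }
})

test_that("tree probabilities are leaf frequencies and sum to one", {
  d <- toy_dataset(n = 40, p = 3, K = 3, seed = 15)
  tr <- grow_tree(d, mtry = 2, variant = "random", seed = 2, max_depth = 2)
  q <- toy_dataset(n = 200, p = 3, K = 3, seed = 16)
  p <- tree_predict(tr, q)
  expect_equal(rowSums(p), rep(1, 200))
  expect_true(all(p >= 0))
})

test_that("prediction follows the hand-traced path on a 3-node toy tree", {
  leafL <- list(leaf = TRUE, counts = c(3L, 0L))
  leafR <- list(leaf = TRUE, counts = c(1L, 4L))
  tree <- structure(list(
    root = list(leaf = FALSE, attr = 1L, kind = "continuous", threshold = 2,
                left_levels = NULL, n_left = 3L, n_right = 5L,
                left = leafL, right = leafR),
    class_names = c("u", "v"), attr_names = c("a", "b"),
    columns = list(a = list(kind = "continuous"),
                   b = list(kind = "continuous")),
    variant = "cart", mtry = 1L, seed = 1L), class = "hb_tree")
  expect_equal(as.numeric(tree_predict(tree, c(a = 1, b = 9))), c(1, 0))
  expect_equal(as.numeric(tree_predict(tree, c(a = 5, b = 9))), c(0.2, 0.8))
  expect_equal(as.numeric(tree_predict(tree, c(a = 2, b = 0))), c(1, 0))  # <= goes left
})

test_that("forest probabilities are the exact mean of tree outputs", {
  d <- generate_dataset(small_gen_cfg(n = 60, seed = 18))
  f <- fit_forest(d, n_trees = 7, variant = "random", seed = 18)
  q <- generate_dataset(small_gen_cfg(n = 100, seed = 19))
  got <- forest_predict(f, q)$prob
  ref <- Reduce(`+`, lapply(f$trees, function(tr) tree_predict(tr, q))) / 7
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  expect_equal(rowSums(got), rep(1, 100))
})

test_that("majority vote reproduces the binary more-than-half rule", {
  # craft single-leaf trees voting deterministically
  mk_tree <- function(v) {
    counts <- if (v == 1) c(0L, 10L) else c(10L, 0L)
    structure(list(root = list(leaf = TRUE, counts = counts),
                   class_names = c("neg", "pos"), attr_names = "a",
                   columns = list(a = list(kind = "continuous")),
                   variant = "cart", mtry = 1L, seed = 1L),
              class = "hb_tree")
  }
  x <- data.frame(a = 0)
  for (F in c(1, 3, 5)) {
    votes <- expand.grid(rep(list(c(0, 1)), F))
    for (r in seq_len(nrow(votes))) {
      v <- as.numeric(votes[r, ])
      forest <- structure(list(trees = lapply(v, mk_tree),
                               bootstrap_indices = rep(list(1L), F),
                               n_trees = F, mtry = 1L, variant = "cart",
                               seed = 1L, max_depth = Inf,
                               class_names = c("neg", "pos"),
                               attr_names = "a"), class = "hb_forest")
      lab <- as.character(forest_predict(forest, x)$labels)
      expect_equal(lab, if (mean(v) > 0.5) "pos" else "neg",
                   info = sprintf("F=%d votes=%s", F, paste(v, collapse = "")))
    }
  }
})

test_that("a forest of identical trees equals the single tree", {
  d <- separable_1d()
  tr <- grow_tree(d, mtry = 1, variant = "cart", seed = 4)
  forest <- structure(list(trees = rep(list(tr), 5),
                           bootstrap_indices = rep(list(1:4), 5),
                           n_trees = 5, mtry = 1L, variant = "cart",
                           seed = 1L, max_depth = Inf,
                           class_names = d$class_names,
                           attr_names = names(d$x)), class = "hb_forest")
  expect_equal(unname(forest_predict(forest, d)$prob),
               unname(tree_predict(tr, d)))
})

test_that("forests are bit-reproducible for a fixed seed", {
  d <- generate_dataset(small_gen_cfg(n = 60, seed = 20))
  f1 <- fit_forest(d, n_trees = 5, variant = "random", seed = 99)
  f2 <- fit_forest(d, n_trees = 5, variant = "random", seed = 99)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$bootstrap_indices, f2$bootstrap_indices)
  f3 <- fit_forest(d, n_trees = 5, variant = "random", seed = 100)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("OOB error matches a brute-force per-record recount", {
  d <- generate_dataset(small_gen_cfg(n = 20, separability = 0.5, seed = 21))
  f <- fit_forest(d, n_trees = 5, variant = "cart", seed = 21)
  expect_equal(oob_error(f, d), oracle_oob(f, d))
  fr <- fit_forest(d, n_trees = 5, variant = "random", seed = 22)
  expect_equal(oob_error(fr, d), oracle_oob(fr, d))
})

test_that("OOB error is near zero on separable data and 0.75 on permuted labels", {
  d <- generate_dataset(generator_config(n = 240, separability = 2.5,
                                         cluster_alignment = 1, seed = 23))
  f <- fit_forest(d, n_trees = 60, variant = "random", seed = 23)
  expect_lte(oob_error(f, d), 0.02)

  # destroy the signal by permuting labels: error ~ 3/4 for 4 balanced classes
  errs <- vapply(1:5, function(s) {
    dp <- d
    set.seed(s)
    dp$y <- d$y[sample(n_records(d))]
    fp <- fit_forest(dp, n_trees = 40, variant = "random", seed = s,
                     max_depth = 6)
    oob_error(fp, dp)
  }, 0)
  expect_lt(abs(mean(errs) - 0.75), 0.05)
})

test_that("OOB error is undefined without coverage", {
  d <- separable_1d()
  f <- fit_forest(d, n_trees = 1, variant = "cart", seed = 5)
  f$bootstrap_indices <- list(1:4)  # full coverage: nothing is out of bag
  expect_warning(e <- oob_error(f, d), "coverage")
  expect_true(is.na(e))
})

test_that("forest probability variance shrinks as the forest grows", {
  d <- generate_dataset(small_gen_cfg(n = 80, separability = 0.4,
                                      alignment = 0.5, seed = 24))
  q <- dataset_subset(generate_dataset(small_gen_cfg(n = 81, separability = 0.4,
                                                     alignment = 0.5, seed = 25)), 1:20)
  spread <- vapply(c(1, 10, 100), function(F) {
    probs <- vapply(1:6, function(s) {
      f <- fit_forest(d, n_trees = F, variant = "random", seed = s,
                      max_depth = 6)
      forest_predict(f, q)$prob[, 1]
    }, numeric(20))
    mean(apply(probs, 1, var))
  }, 0)
  expect_true(all(diff(spread) < 0))
})

test_that("model files survive a save/load round trip and rewrite byte-identically", {
  d <- generate_dataset(small_gen_cfg(n = 50, seed = 26))
  f <- fit_forest(d, n_trees = 4, variant = "cart", seed = 26)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_model(f, p1)
  g <- load_model(p1)
  expect_equal(forest_predict(g, d)$prob, forest_predict(f, d)$prob,
               tolerance = 0)
  expect_identical(g$bootstrap_indices, f$bootstrap_indices)
  save_model(g, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
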