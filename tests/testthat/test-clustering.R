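line_points <- function() {
  hb_dataset(data.frame(a = c(0, 1, 10)), c("u", "u", "v"),
             class_names = c("u", "v"))
}

test_that("agglomeration of points on a line follows the hand trace", {
  pm <- proximity_matrix(line_points(), "euclidean")
  dg <- agglomerate(pm, "single")
  expect_equal(nrow(dg$merges), 2)
  expect_equal(dg$merges$left[1], 1)
  expect_equal(dg$merges$right[1], 2)
  expect_equal(dg$merges$height[1], 1)
  expect_equal(dg$merges$height[2], 9)
  expect_equal(dg$merges$new_id, c(4, 5))
})

test_that("all-identical points merge at height zero", {
  d <- hb_dataset(data.frame(a = rep(2, 5), b = rep(3, 5)),
                  rep(c("u", "v"), c(3, 2)), class_names = c("u", "v"))
  dg <- agglomerate(proximity_matrix(d, "euclidean"), "average")
  expect_equal(dg$merges$height, rep(0, 4))
  # exact ties resolve by smallest (left, right) id pair
  expect_equal(dg$merges$left, c(1, 3, 5, 7))
  expect_equal(dg$merges$right, c(2, 4, 6, 8))
  expect_equal(dg$merges$new_id, c(6, 7, 8, 9))
})

test_that("asymmetric proximity input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(agglomerate(m), "symmetric")
})

test_that("agglomerate matches the O(n^3) brute-force reference on random matrices", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    X <- matrix(runif(n * 4), n)
    D <- proximity_matrix(X, "euclidean")$entries
    for (lk in c("single", "complete", "average")) {
      got <- agglomerate(D, lk)$merges
      ref <- oracle_agglomerate(D, lk)
      expect_equal(got$left, ref$left, info = paste(lk, rep))
      expect_equal(got$right, ref$right, info = paste(lk, rep))
      expect_equal(got$height, ref$height, tolerance = 1e-12)
    }
  }
})

test_that("single and complete linkage merge heights are nondecreasing", {
  set.seed(5)
  for (rep in 1:20) {
    X <- matrix(runif(10 * 3), 10)
    D <- proximity_matrix(X, "euclidean")$entries
    for (lk in c("single", "complete")) {
      h <- agglomerate(D, lk)$merges$height
      expect_true(all(diff(h) >= -1e-12))
    }
  }
})

test_that("cutting the dendrogram yields k nested partitions", {
  pm <- proximity_matrix(line_points(), "euclidean")
  dg <- agglomerate(pm, "single")
  expect_equal(cut_dendrogram(dg, 1), c(1, 1, 1))
  expect_equal(cut_dendrogram(dg, 3), c(1, 2, 3))
  expect_equal(cut_dendrogram(dg, 2), c(1, 1, 2))  # {0,1} vs {10}
  expect_error(cut_dendrogram(dg, 4), "k must be")

  # refinement: clusters at k+1 refine clusters at k
  set.seed(6)
  X <- matrix(runif(14 * 3), 14)
  dg <- agglomerate(proximity_matrix(X, "euclidean")$entries, "average")
  for (k in 1:13) {
    a <- cut_dendrogram(dg, k)
    b <- cut_dendrogram(dg, k + 1)
    expect_equal(length(unique(a)), k)
    # each finer cluster sits wholly inside one coarser cluster
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
})

test_that("cluster model representatives are exact member means", {
  d <- hb_dataset(data.frame(a = c(0, 1, 0.5, 10, 11, 10.5),
                             b = c(0, 0, 1, 5, 5, 6)),
                  rep(c("u", "v"), each = 3), class_names = c("u", "v"))
  cm <- fit_cluster_model(d, "euclidean", "average", k = 2)
  expect_equal(sort(unique(cm$labels)), 1:2)
  for (g in 1:2) {
    expect_equal(cm$representatives[g, ],
                 colMeans(as_matrix(d)[cm$labels == g, , drop = FALSE]))
  }
  # k = 1: single representative is the grand mean
  cm1 <- fit_cluster_model(d, "euclidean", k = 1)
  expect_equal(as.numeric(cm1$representatives),
               as.numeric(colMeans(as_matrix(d))))
})

test_that("well-aligned synthetic clusters recover the class partition", {
  agree <- vapply(1:10, function(s) {
    cfg <- generator_config(n = 100, separability = 2.5,
                            cluster_alignment = 1, seed = s)
    d <- generate_dataset(cfg)
    cm <- fit_cluster_model(d, "euclidean", "average", k = 4)
    # adjusted agreement up to label permutation: best per-cluster majority
    tab <- table(cm$labels, d$y)
    sum(apply(tab, 1, max)) / n_records(d)
  }, 0)
  expect_gte(mean(agree), 0.99)
})

test_that("cluster assignment matches exhaustive distance comparison", {
  d <- toy_dataset(n = 25, p = 4, seed = 12)
  for (kind in c("euclidean", "weighted")) {
    cm <- fit_cluster_model(d, kind, "average", k = 3)
    # representative itself maps to its own index
    for (g in 1:3) {
      expect_equal(assign_cluster(cm, cm$representatives[g, ]), g)
    }
    set.seed(12)
    for (r in 1:300) {
      x <- runif(4, 0, 10)
      dists <- vapply(1:3, function(g) {
        if (kind == "euclidean") {
          oracle_euclidean(x, cm$representatives[g, ])
        } else {
          oracle_weighted(x, cm$representatives[g, ], "mean_variance")
        }
      }, 0)
      expect_equal(assign_cluster(cm, x), which.min(dists))
    }
  }
})

test_that("equidistant queries break ties to the lowest cluster index", {
  cm <- structure(list(k = 3, labels = c(1, 2, 3),
                       representatives = rbind(c(-1, 0), c(5, 5), c(1, 0)),
                       distance_kind = "euclidean",
                       symmetrization = "mean_variance",
                       linkage = "average", attr_names = c("a", "b")),
                  class = "hb_cluster_model")
  expect_equal(assign_cluster(cm, c(0, 0)), 1)  # ties rep 1 and rep 3
})

test_that("augment appends a nominal cluster attribute and uniquifies on repeat", {
  d <- toy_dataset(n = 10, p = 3, seed = 13)
  cm <- fit_cluster_model(d, "euclidean", k = 2)
  a1 <- augment(d, cm, labels = cm$labels)
  expect_equal(names(a1$x), c(names(d$x), "cluster"))
  expect_true(is.factor(a1$x$cluster))
  expect_equal(as.integer(a1$x$cluster), cm$labels)
  expect_equal(a1$schema$kind[ncol(a1$x)], "nominal")
  expect_warning(a2 <- augment(a1, cm), "already present")
  expect_equal(ncol(a2$x), ncol(d$x) + 2)
  # k = 1 gives a constant column
  cm1 <- fit_cluster_model(d, "euclidean", k = 1)
  expect_equal(length(unique(augment(d, cm1)$x$cluster)), 1)
})

test_that("on separated aligned data the cluster column nearly copies the class column", {
  cfg <- generator_config(n = 120, separability = 2.5, cluster_alignment = 1,
                          seed = 44)
  d <- generate_dataset(cfg)
  cm <- fit_cluster_model(d, "euclidean", k = 4)
  aug <- augment(d, cm)  # nearest-representative assignment
  tab <- table(aug$x$cluster, d$y)
  expect_gte(sum(apply(tab, 1, max)) / n_records(d), 0.98)
  # and assignment reproduces the fitted labels on the training data itself
  expect_gte(mean(assign_clusters(cm, d) == cm$labels), 0.98)
})

test_that("dendrogram exports are consistent", {
  dg <- agglomerate(proximity_matrix(line_points(), "euclidean"), "single")
  expect_equal(dendrogram_newick(dg), "(3,(1,2):1):9;")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dendrogram(dg, path)
  expect_equal(read.csv(path)$height, c(1, 9))
})
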