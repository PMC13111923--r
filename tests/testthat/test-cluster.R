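# helper: fabricate concepts with prescribed mean maps
fake_concept <- function(map, model_id, filter, class_y = 0L,
                         nb = 7L, C = 4L) {
  structure(list(model_id = model_id, layer_id = "pointwise_conv",
                 filter = as.integer(filter), class_y = as.integer(class_y),
                 sample_ids = 1:2, scores = c(1, 0.5), k = 2L,
                 mean_map = map,
                 mean_freq_rel = matrix(0.1, C, nb),
                 freqs = (0:(nb - 1)) * 2),
            class = "concept")
}

test_that("cosine UMAP separates two families of map directions", {
  set.seed(40)
  base1 <- rnorm(30); base2 <- rnorm(30)
  # near-parallel within family (cosine ~ 1), near-orthogonal across
  X <- rbind(t(sapply(1:20, function(i) base1 * runif(1, .5, 2) +
                        rnorm(30, 0, .02))),
             t(sapply(1:20, function(i) base2 * runif(1, .5, 2) +
                        rnorm(30, 0, .02))))
  co <- embed_concepts(X, seed = 5)
  expect_equal(dim(co), c(40L, 2L))
  d <- as.matrix(dist(co))
  within <- mean(d[1:20, 1:20])
  between <- mean(d[1:20, 21:40])
  expect_gt(between, within)
  # deterministic under the seed
  expect_identical(co, embed_concepts(X, seed = 5))
  # cosine metric: global scaling preserves the neighbour structure
  co5 <- embed_concepts(X * 5, seed = 5)
  d5 <- as.matrix(dist(co5))
  expect_gt(mean(d5[1:20, 21:40]), mean(d5[1:20, 1:20]))
})

test_that("DBSCAN labels follow the density contract", {
  # 30 coincident points with min_samples 15: one cluster, no noise
  co <- matrix(0, 30, 2)
  l1 <- cluster_embedding(co, eps = 0.4, min_samples = 15)
  expect_true(all(l1 == 1L))
  # 10 coincident points below the density threshold: all noise
  l2 <- cluster_embedding(matrix(0, 10, 2), eps = 0.4, min_samples = 15)
  expect_true(all(l2 == -1L))
  # two well-separated dense blobs: exactly two clusters
  set.seed(41)
  blob <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
                matrix(rnorm(40, 10, 0.05), 20, 2))
  l3 <- cluster_embedding(blob, eps = 0.4, min_samples = 15)
  expect_equal(sort(unique(l3[l3 != -1])), c(1L, 2L))
  expect_true(all(l3[1:20] == l3[1]))
})

test_that("min_samples auto-scales for small concept sets", {
  l <- cluster_embedding(matrix(rnorm(40), 20, 2), eps = 0.4)
  expect_equal(attr(l, "min_samples"), 5L)
  l2 <- cluster_embedding(matrix(rnorm(400), 200, 2), eps = 0.4)
  expect_equal(attr(l2, "min_samples"), 15L)
})

test_that("cluster composition counts filters per model and coverage", {
  labels <- c(1L, 1L, 2L, -1L, 1L, 2L)
  models <- c("mA", "mA", "mA", "mB", "mB", "mB")
  comp <- cluster_composition(labels, models)
  expect_equal(sum(comp$composition), sum(labels != -1L))
  expect_equal(comp$composition["mA", "cluster_1"], 2L)
  expect_equal(comp$composition["mB", "cluster_1"], 1L)
  # every model contributes to every cluster -> coverage 1
  expect_equal(unname(comp$coverage), c(1, 1))
  # missing contribution lowers coverage
  comp2 <- cluster_composition(c(1L, 1L, 2L), c("mA", "mA", "mB"))
  expect_equal(unname(comp2$coverage), c(0.5, 0.5))
})

test_that("per-class clustering ignores the other class's concepts", {
  set.seed(42)
  cps <- c(lapply(1:10, function(i)
    fake_concept(rnorm(20), "mA", i, class_y = 0L)),
    lapply(1:10, function(i)
      fake_concept(rnorm(20), "mA", i, class_y = 1L)))
  cm0 <- concept_matrix(cps, 0L)
  co0 <- embed_concepts(cm0$X, seed = 3)
  # permute class-1 concepts; class-0 embedding unchanged
  cps2 <- c(cps[1:10], cps[sample(11:20)])
  cm0b <- concept_matrix(cps2, 0L)
  expect_identical(cm0$X, cm0b$X)
  expect_identical(co0, embed_concepts(cm0b$X, seed = 3))
})
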